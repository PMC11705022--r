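# The study's statistical battery: paired Wilcoxon signed-rank comparisons,
# mixed-effects price-change models (retailer random intercept, container
# size and brand type as fixed covariates), Pearson chi-square association,
# Benjamini-Hochberg step-up adjustment, and descriptive price summaries.
#
# Because every model is fit to within-product price *changes*, a constant
# inflation shift added to all deltas moves only the intercept: all exposure
# coefficients (reformulation-group contrasts, FSANZ-change slopes) are
# invariant. That cancellation argument is asserted as a metamorphic test in
# the suite.

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on within-pair differences. Pairs with a missing value
#' and zero differences are dropped (standard convention); the exact null
#' distribution is used for n <= 25 when the absolute differences are
#' untied, otherwise a normal approximation with continuity and tie
#' correction.
#'
#' @param y1,y2 equal-length numeric vectors.
#' @return list: `statistic` (V, rank sum of positive differences),
#'   `p.value` (two-sided), `n` (nonzero differences used), `n_zero`,
#'   `method`, `degenerate` (TRUE when every difference is zero; p is then
#'   reported as 1).
#' @export
wilcoxon_paired <- function(y1, y2) {
  stopifnot(length(y1) == length(y2))
  d <- y2 - y1
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = 1, n = 0L, n_zero = n_zero,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = V, p.value = p, n = n, n_zero = n_zero,
       method = method, degenerate = FALSE)
}

#' Pearson chi-square test of independence
#'
#' @param tab r x c matrix of non-negative integer counts with positive
#'   margins.
#' @return list: `statistic` (sum (O-E)^2/E), `df` ((r-1)(c-1)), `p.value`,
#'   and `caution` (TRUE when any expected count is below 5).
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("chi-square requires positive row and column margins", call. = FALSE)
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p.value = pchisq(stat, df,
                                                   lower.tail = FALSE),
       caution = any(E < 5))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in [0, 1]; NA passes through.
#' @return adjusted p-values in the original order: sort ascending,
#'   adj_i = min over j >= i of m * p_j / j, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0L) {
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(m / seq_len(m) * p[o]))))
    out[ok] <- adj[order(o)]
  }
  out
}

std_or_zero <- function(x) {
  # standardize for conditioning; constant columns become 0, not NaN
  s <- sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

fit_price_model <- function(dat, exposure_term) {
  # delta_price ~ exposure + std(container) + brand_type, retailer random
  # intercept; falls back to a fixed-intercept OLS fit when there is a single
  # retailer or the random effect is singular.
  dat$cont_std <- std_or_zero(dat$container_size)
  dat$brand_type <- factor(dat$brand_type, levels = BRAND_TYPES)
  dat$brand_type <- droplevels(dat$brand_type)
  covs <- "cont_std"
  if (nlevels(dat$brand_type) > 1L) covs <- c(covs, "brand_type")
  fixed <- paste("delta_price ~", paste(c(exposure_term, covs),
                                        collapse = " + "))
  use_lmer <- length(unique(dat$retailer_id)) > 1L
  fallback <- FALSE
  if (use_lmer) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(paste(fixed, "+ (1 | retailer_id)")),
                 data = dat, REML = TRUE)))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      fallback <- TRUE
    } else {
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(vcov(fit))))
      # Wald t with residual-style df (n - fixed params - grouping levels):
      # the normal reference is anticonservative in small cells
      df <- max(1, nrow(dat) - length(cf) -
                  length(unique(dat$retailer_id)))
      return(list(coef = cf, se = se,
                  p = 2 * stats::pt(-abs(cf / se), df), df = df,
                  model = "lmer", singular_fallback = FALSE))
    }
  }
  fit <- lm(as.formula(fixed), data = dat)
  sm <- summary(fit)$coefficients
  list(coef = sm[, 1], se = sm[, 2], p = sm[, 4],
       df = fit$df.residual, model = "lm", singular_fallback = fallback)
}

effect_rows <- function(fit, terms, ns, outcome) {
  keep <- intersect(terms, names(fit$coef))
  crit <- stats::qt(0.975, max(1, fit$df))
  data.frame(outcome = outcome, term = keep,
             n = ns[keep],
             beta = unname(fit$coef[keep]),
             ci_low = unname(fit$coef[keep] - crit * fit$se[keep]),
             ci_high = unname(fit$coef[keep] + crit * fit$se[keep]),
             p_raw = unname(fit$p[keep]), p_adj = NA_real_,
             model = fit$model, stringsAsFactors = FALSE)
}

#' Mixed-effects model of price change on reformulation group
#'
#' Outcome: price change per 100 g (or ml). Exposure: the five-level
#' reformulation group for one nutrient with little_change as reference.
#' Covariates: container size (standardized) and brand type (multinational
#' reference); retailer enters as a random intercept. Non-reference groups
#' with fewer than `min_n` pairs are dropped before fitting and reported in
#' the `dropped` attribute; a singular random-effect fit falls back to a
#' fixed-intercept model with `model = "lm"` recorded.
#'
#' @param classified [classify_pairs()] output.
#' @param nutrient nutrient id.
#' @param min_n minimum group size retained (default 5).
#' @return data.frame of `EffectEstimate` rows (term, n, beta, ci_low,
#'   ci_high, p_raw, p_adj, model); empty (with attribute `dropped`) when no
#'   non-reference group survives.
#' @export
fit_reformulation_model <- function(classified, nutrient, min_n = 5) {
  d <- classified[classified$nutrient == nutrient &
                    !is.na(classified$group) &
                    !is.na(classified$delta_price), , drop = FALSE]
  empty <- data.frame(outcome = character(0), term = character(0),
                      n = integer(0), beta = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), model = character(0))
  counts <- table(factor(d$group, levels = REFORMULATION_GROUPS))
  keep_lv <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts)[counts > 0], keep_lv)
  if (!("little_change" %in% keep_lv) ||
      length(setdiff(keep_lv, "little_change")) == 0L) {
    attr(empty, "dropped") <- dropped
    return(empty)
  }
  d <- d[d$group %in% keep_lv, , drop = FALSE]
  d$group <- factor(as.character(d$group),
                    levels = c("little_change",
                               setdiff(REFORMULATION_GROUPS, "little_change")))
  d$group <- droplevels(d$group)
  fit <- fit_price_model(d, "group")
  terms <- paste0("group", setdiff(levels(d$group), "little_change"))
  ns <- setNames(as.integer(table(d$group)[setdiff(levels(d$group),
                                                   "little_change")]), terms)
  out <- effect_rows(fit, terms, ns, paste0("delta_price~", nutrient))
  out$term <- sub("^group", "", out$term)
  attr(out, "dropped") <- dropped
  attr(out, "singular_fallback") <- fit$singular_fallback
  out
}

#' Mixed-effects model of price change on FSANZ score change
#'
#' One continuous slope per grouping cell (overall or per TRA category), with
#' the same covariates and retailer random intercept as
#' [fit_reformulation_model()]. Cells below `min_n` pairs, or with a constant
#' predictor, are skipped and listed in the `skipped` attribute.
#'
#' @param scored pairs from [fsanz_score_pairs()] with `score_change` and
#'   `delta_price`.
#' @param by `"overall"` or `"tra_category"`.
#' @param min_n minimum cell size (default 10; the study's category models
#'   excluded a cell of n 9).
#' @return data.frame of EffectEstimate rows, one per retained cell.
#' @export
fit_fsanz_model <- function(scored, by = c("overall", "tra_category"),
                            min_n = 10) {
  by <- match.arg(by)
  d <- scored[!is.na(scored$score_change) & !is.na(scored$delta_price), ,
              drop = FALSE]
  cells <- if (by == "overall") list(overall = d) else
    split(d, d$tra_category, drop = TRUE)
  skipped <- character(0)
  rows <- lapply(names(cells), function(cell) {
    dc <- cells[[cell]]
    if (nrow(dc) < min_n || length(unique(dc$score_change)) < 2L) {
      skipped <<- c(skipped, cell)
      return(NULL)
    }
    fit <- fit_price_model(dc, "score_change")
    r <- effect_rows(fit, "score_change",
                     setNames(nrow(dc), "score_change"),
                     "delta_price~fsanz_score_change")
    r$cell <- cell
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(outcome = character(0), term = character(0),
                      n = integer(0), beta = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), model = character(0),
                      cell = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Descriptive price comparison by cell
#'
#' Per cell (overall, TRA category or retailer): n, mean/sd/median per-100
#' price in each year, the paired Wilcoxon p, and BH-adjusted p across the
#' cells of the same family.
#'
#' @param pairs matched pairs with per-100 prices.
#' @param by `"overall"`, `"tra_category"` or `"retailer_id"`.
#' @return data.frame, one row per non-empty cell; empty cells are listed in
#'   the `omitted` attribute.
#' @export
summarize_prices <- function(pairs,
                             by = c("overall", "tra_category",
                                    "retailer_id")) {
  by <- match.arg(by)
  d <- pairs[!is.na(pairs$price_per100_y1) & !is.na(pairs$price_per100_y2), ,
             drop = FALSE]
  cells <- if (by == "overall") list(overall = d) else
    split(d, d[[by]], drop = TRUE)
  omitted <- names(cells)[vapply(cells, nrow, 0L) == 0L]
  cells <- cells[vapply(cells, nrow, 0L) > 0L]
  rows <- lapply(names(cells), function(cell) {
    dc <- cells[[cell]]
    w <- wilcoxon_paired(dc$price_per100_y1, dc$price_per100_y2)
    data.frame(cell = cell, n = nrow(dc),
               mean_y1 = mean(dc$price_per100_y1),
               sd_y1 = sd(dc$price_per100_y1),
               median_y1 = median(dc$price_per100_y1),
               mean_y2 = mean(dc$price_per100_y2),
               sd_y2 = sd(dc$price_per100_y2),
               median_y2 = median(dc$price_per100_y2),
               statistic = w$statistic, p_raw = w$p.value,
               degenerate = w$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell = character(0), n = integer(0),
                      mean_y1 = numeric(0), sd_y1 = numeric(0),
                      median_y1 = numeric(0), mean_y2 = numeric(0),
                      sd_y2 = numeric(0), median_y2 = numeric(0),
                      statistic = numeric(0), p_raw = numeric(0),
                      degenerate = logical(0))
  out$p_adj <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}
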
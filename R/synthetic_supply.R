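# Synthetic two-year food-supply generator with known ground truth.
#
# The generator emulates the structure of a matched branded-food study:
# a year-1 snapshot from a few large retailers, a year-2 snapshot where a
# known subset of products has been reformulated (nutrient deltas drawn as a
# percentage of the Daily Value, so truth groups follow by construction),
# multiplicative price inflation, additive per-100 g injected price effects
# for chosen (category, nutrient, group) cells, retailer price offsets,
# shrinkflation, partial product overlap and missing fields.

lnorm_pars <- function(mean, sd) {
  # natural-scale mean/sd -> (meanlog, sdlog)
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

default_nutrient_baselines <- function() {
  # per-100 g (or ml) natural-scale mean and sd, right-skewed like label data
  data.frame(
    nutrient = NUTRIENT_COLS,
    mean = c(250, 9, 3, 30, 10, 2, 6, 400, 80),
    sd   = c(150, 8, 3, 20, 9, 1.8, 5, 350, 80),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic food supply
#'
#' Defaults state the emulated world: three large retailers, 22 analysed TRA
#' categories (plus a little mass in the excluded W and X), four brand types,
#' a per-100 g price distribution with mean $1.52 and sd $1.78, sodium as the
#' most-reformulated nutrient at prevalence 0.178 (47% of sodium events being
#' increases), low food inflation (1.5%), about 99% of records carrying a
#' valid price and enough nutrition missingness that roughly two-thirds of
#' matched pairs have complete nutrition in both years.
#'
#' @param n_products number of distinct products in the supply.
#' @param n_retailers number of retailers.
#' @param category_weights named probability vector over TRA letters.
#' @param brand_type_weights named probability vector over the four brand types.
#' @param nutrient_baselines data.frame (nutrient, mean, sd) of per-100
#'   lognormal baselines; optionally a tra_category column for per-category
#'   overrides.
#' @param price_baseline c(mean, sd) of per-100 g price (lognormal).
#' @param reformulation_prevalence named vector, probability a matched product
#'   changes in each core nutrient.
#' @param reformulation_direction_up named vector, probability an event is an
#'   increase.
#' @param reformulation_magnitude c(mean, sd) of |delta| as % of DV; draws are
#'   truncated just above the 5% "changed" threshold so an event always leaves
#'   the little-change band.
#' @param price_effect_beta data.frame (tra_category, nutrient, group, beta):
#'   currency per 100 g added to the year-2 price of products whose truth
#'   group matches; tra_category "*" applies to all categories.
#' @param inflation_rate multiplicative year-2 price drift.
#' @param retailer_price_offsets numeric vector (recycled over retailers)
#'   added to each retailer's year-2 per-100 price change.
#' @param price_noise_sd sd of the additive per-100 price-change noise.
#' @param shrinkflation_prob probability a matched product's container shrinks
#'   in year 2 (breaking the size-based match key).
#' @param unmatched_frac fraction of products present in only one year.
#' @param missing_price_frac,missing_nutrition_frac per record-year missing
#'   field probabilities.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   databases.
#' @return list of class `supply_config`.
#' @export
supply_config <- function(n_products = 1000,
                          n_retailers = 3,
                          category_weights = NULL,
                          brand_type_weights = c(multinational = 0.55,
                                                 private_label_premium = 0.10,
                                                 private_label_discount = 0.10,
                                                 domestic_or_other = 0.25),
                          nutrient_baselines = default_nutrient_baselines(),
                          price_baseline = c(mean = 1.52, sd = 1.78),
                          reformulation_prevalence = c(
                            energy_kcal = 0.12, fat_g = 0.10, satfat_g = 0.11,
                            carb_g = 0.13, sugars_g = 0.117, protein_g = 0.10,
                            sodium_mg = 0.178),
                          reformulation_direction_up = c(
                            energy_kcal = 0.5, fat_g = 0.5, satfat_g = 0.5,
                            carb_g = 0.5, sugars_g = 0.52, protein_g = 0.5,
                            sodium_mg = 0.47),
                          reformulation_magnitude = c(mean = 12, sd = 6),
                          price_effect_beta = NULL,
                          inflation_rate = 0.015,
                          retailer_price_offsets = c(-0.02, 0, 0.02),
                          price_noise_sd = 0.10,
                          shrinkflation_prob = 0.02,
                          unmatched_frac = 0.30,
                          missing_price_frac = 0.01,
                          missing_nutrition_frac = 0.17,
                          seed = 1L) {
  if (is.null(category_weights)) {
    category_weights <- c(setNames(rep(0.97 / 22, 22), TRA_ANALYSED),
                          W = 0.025, X = 0.005)
  }
  cfg <- list(n_products = n_products, n_retailers = n_retailers,
              category_weights = category_weights,
              brand_type_weights = brand_type_weights,
              nutrient_baselines = nutrient_baselines,
              price_baseline = price_baseline,
              reformulation_prevalence = reformulation_prevalence,
              reformulation_direction_up = reformulation_direction_up,
              reformulation_magnitude = reformulation_magnitude,
              price_effect_beta = price_effect_beta,
              inflation_rate = inflation_rate,
              retailer_price_offsets = retailer_price_offsets,
              price_noise_sd = price_noise_sd,
              shrinkflation_prob = shrinkflation_prob,
              unmatched_frac = unmatched_frac,
              missing_price_frac = missing_price_frac,
              missing_nutrition_frac = missing_nutrition_frac,
              seed = as.integer(seed))
  class(cfg) <- "supply_config"
  validate_supply_config(cfg)
  cfg
}

validate_supply_config <- function(cfg) {
  stopifnot(inherits(cfg, "supply_config"))
  with(cfg, {
    if (!(is.numeric(n_products) && n_products >= 1))
      stop("n_products must be >= 1", call. = FALSE)
    if (!(is.numeric(n_retailers) && n_retailers >= 1))
      stop("n_retailers must be >= 1", call. = FALSE)
    probs <- c(reformulation_prevalence, reformulation_direction_up,
               shrinkflation_prob, unmatched_frac,
               missing_price_frac, missing_nutrition_frac)
    if (any(probs < 0 | probs > 1))
      stop("all probabilities must lie in [0, 1]", call. = FALSE)
    for (w in list(category_weights, brand_type_weights)) {
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        stop("weights must be nonnegative and sum to 1", call. = FALSE)
    }
    if (!all(names(reformulation_prevalence) %in% CORE_NUTRIENTS))
      stop("reformulation_prevalence keys must be core nutrients",
           call. = FALSE)
  })
  invisible(cfg)
}

with_seed <- function(seed, code) {
  # evaluate `code` under a fixed RNG state without clobbering the caller's
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a paired synthetic food supply
#'
#' @param config a [supply_config()].
#' @return list with elements `db1` and `db2` ([food_db()] objects labelled
#'   "Y1" and "Y2"), and `truth` (class `supply_truth`): per-product,
#'   per-nutrient ground-truth deltas and reformulation groups, injected price
#'   effects, and the realized inflation multiplier. Truth groups are derived
#'   from the realized per-100 deltas with the default DV table, so the
#'   classifier reproduces them exactly.
#' @export
generate_supply <- function(config) {
  validate_supply_config(config)
  dv <- default_dv_table()
  with_seed(config$seed, {
    n <- config$n_products
    retailers <- paste0("R", seq_len(config$n_retailers))
    offsets <- rep_len(config$retailer_price_offsets, config$n_retailers)

    cat_lets <- names(config$category_weights)
    prod <- data.frame(
      product_code = sprintf("UPC%08d", seq_len(n)),
      retailer_id = sample(retailers, n, replace = TRUE),
      brand = paste0("BRAND", sample.int(max(20L, n %/% 10L), n, replace = TRUE)),
      brand_type = sample(names(config$brand_type_weights), n, replace = TRUE,
                          prob = config$brand_type_weights),
      tra_category = sample(cat_lets, n, replace = TRUE,
                            prob = config$category_weights),
      stringsAsFactors = FALSE)
    prod$container_unit <- ifelse(prod$tra_category == "B", "ml", "g")
    prod$serving_unit <- prod$container_unit
    prod$container_size <- sample(c(100, 200, 250, 300, 330, 400, 500, 600,
                                    750, 900, 1000), n, replace = TRUE)
    prod$serving_size <- pmin(prod$container_size,
                              sample(c(15, 30, 50, 100, 125, 250), n,
                                     replace = TRUE))

    # per-100 nutrient baselines (year 1)
    bl <- config$nutrient_baselines
    per100 <- matrix(NA_real_, n, length(NUTRIENT_COLS),
                     dimnames = list(NULL, NUTRIENT_COLS))
    for (nu in NUTRIENT_COLS) {
      row <- bl[bl$nutrient == nu, , drop = FALSE]
      if (nrow(row) == 0L) next
      p <- lnorm_pars(row$mean[1], row$sd[1])
      per100[, nu] <- rlnorm(n, p$meanlog, p$sdlog)
    }
    # keep label arithmetic sane
    per100[, "satfat_g"] <- pmin(per100[, "satfat_g"], per100[, "fat_g"])
    per100[, "sugars_g"] <- pmin(per100[, "sugars_g"], per100[, "carb_g"])
    fv_hi <- prod$tra_category %in% c("J", "K", "O", "P", "Q", "V")
    fvnl <- ifelse(fv_hi,
                   ifelse(runif(n) < 0.8, runif(n, 30, 100), 0),
                   ifelse(runif(n) < 0.35, runif(n, 0, 40), 0))

    pp <- lnorm_pars(config$price_baseline[["mean"]],
                     config$price_baseline[["sd"]])
    price100_y1 <- rlnorm(n, pp$meanlog, pp$sdlog)

    # which products exist in which year
    n_matched <- round(n * (1 - config$unmatched_frac))
    status <- rep("matched", n)
    if (n_matched < n) {
      extra <- seq.int(n_matched + 1L, n)
      status[extra] <- rep_len(c("only_y1", "only_y2"), length(extra))
    }
    shrunk <- status == "matched" & runif(n) < config$shrinkflation_prob

    # reformulation events: |delta| drawn as % of DV then mapped to absolute
    # per-100 deltas; a decrease the baseline cannot support is flipped to an
    # increase so the realized changed-fraction matches the event rate.
    nutrients <- names(config$reformulation_prevalence)
    delta100 <- matrix(0, n, length(nutrients),
                       dimnames = list(NULL, nutrients))
    mag <- config$reformulation_magnitude
    for (nu in nutrients) {
      ev <- status == "matched" &
        runif(n) < config$reformulation_prevalence[[nu]]
      k <- sum(ev)
      if (k == 0L) next
      pct <- pmax(5.01, rnorm(k, mag[["mean"]], mag[["sd"]]))
      up <- runif(k) < config$reformulation_direction_up[[nu]]
      dv_amt <- dv_lookup(dv, nu)
      d <- pct / 100 * dv_amt
      base <- per100[ev, nu]
      # a decrease is capped at the baseline (reformulation to zero) when the
      # baseline supports at least a 5% DV drop; otherwise the event flips to
      # an increase so the realized changed-fraction stays at the event rate
      min_d <- 5.01 / 100 * dv_amt
      down_ok <- !up & base >= min_d
      signed <- ifelse(down_ok, -pmin(d, base), d)
      delta100[ev, nu] <- signed
    }

    per100_y2 <- per100
    per100_y2[, nutrients] <- per100[, nutrients] + delta100

    # year-2 price: multiplicative inflation, additive retailer offset,
    # injected (category, nutrient, group) effects, gaussian noise
    ret_idx <- match(prod$retailer_id, retailers)
    injected <- rep(0, n)
    truth_groups <- do.call(rbind, lapply(nutrients, function(nu) {
      pct <- 100 * delta100[, nu] / dv_lookup(dv, nu)
      data.frame(product_code = prod$product_code, nutrient = nu,
                 delta_per100 = delta100[, nu], pct_dv = pct,
                 group = as.character(classify_reformulation(pct)),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(config$price_effect_beta)) {
      eff <- config$price_effect_beta
      stopifnot(all(c("tra_category", "nutrient", "group", "beta") %in%
                      names(eff)))
      for (i in seq_len(nrow(eff))) {
        tg <- truth_groups[truth_groups$nutrient == eff$nutrient[i] &
                             truth_groups$group == eff$group[i], "product_code"]
        hit <- prod$product_code %in% tg
        if (eff$tra_category[i] != "*")
          hit <- hit & prod$tra_category == eff$tra_category[i]
        injected[hit] <- injected[hit] + eff$beta[i]
      }
    }
    price100_y2 <- price100_y1 * (1 + config$inflation_rate) +
      offsets[ret_idx] + injected + rnorm(n, 0, config$price_noise_sd)
    price100_y2 <- pmax(price100_y2, 0.01)

    build_records <- function(year) {
      keep <- if (year == 1L) status != "only_y2" else status != "only_y1"
      r <- prod[keep, , drop = FALSE]
      p100 <- if (year == 1L) per100[keep, , drop = FALSE] else
        per100_y2[keep, , drop = FALSE]
      sv <- r$serving_size
      for (nu in NUTRIENT_COLS) r[[nu]] <- p100[, nu] * sv / 100
      r$fvnl_percent <- fvnl[keep]
      if (year == 1L) {
        r$price <- price100_y1[keep] * r$container_size / 100
      } else {
        r$container_size <- ifelse(shrunk[keep],
                                   round(r$container_size * 0.9),
                                   r$container_size)
        r$price <- price100_y2[keep] * r$container_size / 100
      }
      # missingness, applied per record-year
      m <- nrow(r)
      miss_p <- runif(m) < config$missing_price_frac
      r$price[miss_p] <- NA_real_
      u <- runif(m)
      panel <- u < config$missing_nutrition_frac * 0.6
      single <- !panel & u < config$missing_nutrition_frac
      for (nu in c(NUTRIENT_COLS, "fvnl_percent")) r[[nu]][panel] <- NA_real_
      if (any(single)) {
        which_f <- sample(c("fibre_g", "fvnl_percent", "calcium_mg"),
                          sum(single), replace = TRUE)
        idx <- which(single)
        for (j in seq_along(idx)) r[[which_f[j]]][idx[j]] <- NA_real_
      }
      r
    }

    db1 <- food_db(build_records(1L), "Y1", "synthetic supply, year 1")
    db2 <- food_db(build_records(2L), "Y2", "synthetic supply, year 2")

    truth <- structure(list(
      products = data.frame(product_code = prod$product_code,
                            retailer_id = prod$retailer_id,
                            tra_category = prod$tra_category,
                            brand_type = prod$brand_type,
                            status = status, shrunk = shrunk,
                            injected_price_effect = injected,
                            stringsAsFactors = FALSE),
      groups = truth_groups[truth_groups$product_code %in%
                              prod$product_code[status == "matched"], ],
      inflation_rate = config$inflation_rate,
      seed = config$seed), class = "supply_truth")
    rownames(truth$groups) <- NULL
    list(db1 = db1, db2 = db2, truth = truth)
  })
}

#' Tabulate ground-truth reformulation groups
#'
#' @param truth a `supply_truth` from [generate_supply()].
#' @return data.frame nutrient x group counts; for every nutrient the counts
#'   sum to the number of matched products.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "supply_truth"))
  g <- truth$groups
  if (nrow(g) == 0L)
    return(data.frame(nutrient = character(0), group = character(0),
                      n = integer(0)))
  tab <- as.data.frame(table(nutrient = g$nutrient,
                             group = factor(g$group,
                                            levels = REFORMULATION_GROUPS)),
                       responseName = "n", stringsAsFactors = FALSE)
  tab[order(tab$nutrient, match(tab$group, REFORMULATION_GROUPS)), ,
      drop = FALSE] -> tab
  rownames(tab) <- NULL
  tab
}
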
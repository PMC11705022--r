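# Table-driven FSANZ Nutrient Profiling Scoring Criterion (NPSC) scorer.
#
# score = baseline points (energy kJ, saturated fat, total sugars, sodium)
#         - V points (fruit/vegetable/nut/legume %) - P points (protein,
#         withheld when baseline reaches the gate unless V points reach the
#         exemption) - F points (fibre).
# A lower score indicates a healthier product. Pass thresholds: Category 1
# (beverages) < 1, Category 2 (other foods) < 4, Category 3 (cheese with
# calcium > 320 mg/100 g, edible oils, spreads, margarine, butter) < 28.
# Every threshold, cap and the protein gate live in a versioned JSON table
# file, never in code.

FSANZ_CATEGORIES <- c("cat1_beverages", "cat2_other", "cat3_cheese_fats_oils")

#' Load and validate NPSC point tables
#'
#' @param path path to the point-table JSON; defaults to the transcription
#'   shipped with the package.
#' @return list of class `npsc_tables` (baseline and modifying step lists,
#'   pass thresholds, protein gate, energy conversion, TRA category mapping)
#'   with a `version` field recorded into every report.
#' @export
load_npsc_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "npsc_tables.json", package = "reformprice")
  tb <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_steps <- function(steps, what) {
    if (is.null(steps)) return(invisible(NULL))
    steps <- as.matrix(steps)
    if (ncol(steps) != 2L)
      stop("malformed step list for ", what, call. = FALSE)
    if (any(diff(steps[, 1]) <= 0))
      stop("thresholds not strictly increasing for ", what, call. = FALSE)
    pts <- steps[, 2]
    if (any(diff(pts) <= 0) || any(pts != round(pts)))
      stop("points must be strictly increasing integers for ", what,
           call. = FALSE)
    invisible(NULL)
  }
  for (comp in names(tb$baseline)) {
    check_steps(tb$baseline[[comp]]$steps, comp)
    check_steps(tb$baseline[[comp]]$cat3_steps, paste0(comp, " (cat3)"))
  }
  for (comp in names(tb$modifying)) check_steps(tb$modifying[[comp]]$steps, comp)
  stopifnot(is.numeric(tb$kj_per_kcal), tb$kj_per_kcal > 0,
            all(FSANZ_CATEGORIES %in% names(tb$pass_below)),
            is.numeric(tb$protein_gate$baseline_trigger),
            is.numeric(tb$protein_gate$v_points_exempt))
  class(tb) <- "npsc_tables"
  tb
}

#' Assign products to FSANZ scoring categories
#'
#' Category 1 is beverages (TRA B by default, overridable in the table file's
#' mapping block); Category 3 is edible oils/spreads/margarine/butter (TRA H)
#' plus cheese (TRA D) with calcium strictly greater than 320 mg/100 g;
#' everything else is Category 2.
#'
#' @param tra_category TRA letter(s).
#' @param calcium_per100 calcium mg per 100 g (needed for cheese candidates;
#'   a cheese candidate with missing calcium gets NA and must be excluded
#'   upstream at the `fsanz_ineligible` stage).
#' @param tables [load_npsc_tables()] output.
#' @return factor over the three FSANZ categories.
#' @export
assign_fsanz_category <- function(tra_category, calcium_per100 = NA_real_,
                                  tables = load_npsc_tables()) {
  m <- tables$category_mapping
  n <- max(length(tra_category), length(calcium_per100))
  tra_category <- rep_len(tra_category, n)
  calcium_per100 <- rep_len(calcium_per100, n)
  out <- rep("cat2_other", n)
  out[tra_category %in% m$cat1_tra] <- "cat1_beverages"
  out[tra_category %in% m$cat3_tra] <- "cat3_cheese_fats_oils"
  cheese <- tra_category %in% m$cheese_tra
  out[cheese & !is.na(calcium_per100) &
        calcium_per100 > m$cheese_calcium_above_mg_per100] <-
    "cat3_cheese_fats_oils"
  out[cheese & is.na(calcium_per100)] <- NA_character_
  factor(out, levels = FSANZ_CATEGORIES)
}

#' Look up step-function points for one component value
#'
#' Returns the points of the highest step whose threshold is met
#' (value >= threshold), 0 below the first threshold, capped at the
#' component's maximum (the last step's points).
#'
#' @param value non-negative value(s) per 100 g (or ml).
#' @param steps two-column matrix/data.frame of (threshold, points).
#' @return integer points.
#' @export
lookup_points <- function(value, steps) {
  steps <- as.matrix(steps)
  if (any(!is.na(value) & value < 0))
    stop("component value must be non-negative", call. = FALSE)
  idx <- findInterval(value, steps[, 1])
  pts <- c(0L, as.integer(steps[, 2]))[idx + 1L]
  pts[is.na(value)] <- NA_integer_
  pts
}

baseline_steps <- function(tables, comp, category) {
  b <- tables$baseline[[comp]]
  if (category == "cat3_cheese_fats_oils" && !is.null(b$cat3_steps))
    b$cat3_steps else b$steps
}

#' Score products with the NPSC
#'
#' Vectorized over products. Inputs are per 100 g (or ml); energy is taken in
#' kcal and converted with the table's kJ/kcal factor before lookup.
#'
#' @param energy_kcal,satfat_g,sugars_g,sodium_mg per-100 nutrients to limit.
#' @param fvnl_pct,protein_g,fibre_g per-100 components scoring modifying
#'   points.
#' @param category FSANZ category per product (see
#'   [assign_fsanz_category()]).
#' @param tables [load_npsc_tables()] output.
#' @return data.frame of class `fsanz_result`: category, baseline_points,
#'   v_points, p_points (post-gate), f_points, score and `npsc_pass`.
#' @export
score_products <- function(energy_kcal, satfat_g, sugars_g, sodium_mg,
                           fvnl_pct, protein_g, fibre_g, category,
                           tables = load_npsc_tables()) {
  n <- length(energy_kcal)
  category <- as.character(rep_len(category, n))
  args <- list(energy_kcal = energy_kcal, satfat_g = satfat_g,
               sugars_g = sugars_g, sodium_mg = sodium_mg,
               fvnl_pct = fvnl_pct, protein_g = protein_g, fibre_g = fibre_g)
  for (a in names(args))
    if (any(is.na(args[[a]])))
      stop("score_products: missing required field '", a,
           "'; pre-filter with the fsanz_ineligible stage", call. = FALSE)
  if (any(is.na(category)))
    stop("score_products: missing required field 'category'", call. = FALSE)
  energy_kj <- energy_kcal * tables$kj_per_kcal
  base_val <- list(energy_kj = energy_kj, satfat_g = satfat_g,
                   sugars_g = sugars_g, sodium_mg = sodium_mg)
  baseline <- integer(n)
  for (comp in names(base_val)) {
    pts <- integer(n)
    for (cat in unique(category)) {
      sel <- category == cat
      pts[sel] <- lookup_points(base_val[[comp]][sel],
                                baseline_steps(tables, comp, cat))
    }
    baseline <- baseline + pts
  }
  v <- lookup_points(fvnl_pct, tables$modifying$fvnl_pct$steps)
  p <- lookup_points(protein_g, tables$modifying$protein_g$steps)
  f <- lookup_points(fibre_g, tables$modifying$fibre_g$steps)
  gate <- tables$protein_gate
  gated <- baseline >= gate$baseline_trigger & v < gate$v_points_exempt
  p[gated] <- 0L
  score <- baseline - v - p - f
  res <- data.frame(category = factor(category, levels = FSANZ_CATEGORIES),
                    baseline_points = baseline, v_points = v, p_points = p,
                    f_points = f, score = score,
                    npsc_pass = npsc_eligible(score, category, tables),
                    stringsAsFactors = FALSE)
  class(res) <- c("fsanz_result", "data.frame")
  attr(res, "table_version") <- tables$version
  res
}

#' Health-claim eligibility under the NPSC
#'
#' @param score integer NPSC score(s).
#' @param category FSANZ category per product.
#' @param tables [load_npsc_tables()] output.
#' @return logical: TRUE when the score is below the category's pass
#'   threshold (beverages < 1, other foods < 4, cheese/fats/oils < 28).
#' @export
npsc_eligible <- function(score, category, tables = load_npsc_tables()) {
  thr <- unlist(tables$pass_below)[as.character(category)]
  as.vector(score < thr)
}

#' Score both years of matched pairs and their change
#'
#' @param pairs matched pairs surviving the `fsanz_ineligible` stage.
#' @param tables [load_npsc_tables()] output.
#' @return pairs with `fsanz_category`, `score_y1`, `score_y2`,
#'   `npsc_pass_y1/2` and `score_change` (= year 2 - year 1; negative means
#'   the product became healthier). Pairs unscoreable in either year get NA
#'   and are counted in attribute `n_unscoreable`.
#' @export
fsanz_score_pairs <- function(pairs, tables = load_npsc_tables()) {
  cat1 <- assign_fsanz_category(pairs$tra_category,
                                pairs$calcium_mg_per100_y1, tables)
  cat2 <- assign_fsanz_category(pairs$tra_category,
                                pairs$calcium_mg_per100_y2, tables)
  score_year <- function(suffix, category) {
    g <- function(nu) pairs[[paste0(nu, "_per100_", suffix)]]
    fv <- pairs[[paste0("fvnl_percent_", suffix)]]
    ok <- !is.na(g("energy_kcal")) & !is.na(g("satfat_g")) &
      !is.na(g("sugars_g")) & !is.na(g("sodium_mg")) & !is.na(fv) &
      !is.na(g("protein_g")) & !is.na(g("fibre_g")) & !is.na(category)
    score <- rep(NA_integer_, nrow(pairs))
    pass <- rep(NA, nrow(pairs))
    if (any(ok)) {
      r <- score_products(g("energy_kcal")[ok], g("satfat_g")[ok],
                          g("sugars_g")[ok], g("sodium_mg")[ok],
                          fv[ok], g("protein_g")[ok], g("fibre_g")[ok],
                          category[ok], tables)
      score[ok] <- r$score
      pass[ok] <- r$npsc_pass
    }
    list(score = score, pass = pass, ok = ok)
  }
  y1 <- score_year("y1", cat1)
  y2 <- score_year("y2", cat2)
  pairs$fsanz_category <- cat1
  pairs$score_y1 <- y1$score
  pairs$score_y2 <- y2$score
  pairs$npsc_pass_y1 <- y1$pass
  pairs$npsc_pass_y2 <- y2$pass
  pairs$score_change <- y2$score - y1$score
  attr(pairs, "n_unscoreable") <- sum(!(y1$ok & y2$ok))
  attr(pairs, "npsc_version") <- tables$version
  pairs
}
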
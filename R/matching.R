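# Cross-year product matching, the exclusion cascade, and per-100 g (or ml)
# normalization. Pairing is one-to-one on exact equality of
# (product_code, retailer_id, container_size, unit); a key that appears more
# than once within a year is ambiguous and is excluded, never resolved
# arbitrarily. Price is normalized by container size, nutrients by serving
# size. Deltas are year-2 minus year-1 (positive = increase over time).

EXCLUSION_STAGES <- c("category_WX", "invalid_price",
                      "incomplete_nutrition", "fsanz_ineligible")

new_exclusion_log <- function() {
  data.frame(stage = character(0), criterion = character(0),
             n_in = integer(0), n_removed = integer(0), n_out = integer(0),
             stringsAsFactors = FALSE)
}

log_stage <- function(log, stage, criterion, n_in, n_removed) {
  rbind(log, data.frame(stage = stage, criterion = criterion,
                        n_in = n_in, n_removed = n_removed,
                        n_out = n_in - n_removed, stringsAsFactors = FALSE))
}

#' Exclusion log of a matched-pair set
#'
#' @param pairs a `matched_pairs` data.frame.
#' @return data.frame with one row per pipeline stage: stage, criterion,
#'   n_in, n_removed, n_out. Stage counts reconcile (n_in - n_removed = n_out)
#'   and surviving n is non-increasing.
#' @export
exclusion_log <- function(pairs) attr(pairs, "exclusion_log")

#' Normalize an amount to a 100 g (or ml) basis
#'
#' Price uses the container size as basis; per-serving nutrients use the
#' serving size.
#'
#' @param amount non-negative amount(s); NA propagates.
#' @param basis_size positive basis in g or ml.
#' @return amount * 100 / basis_size.
#' @export
per_hundred <- function(amount, basis_size) {
  if (any(!is.na(basis_size) & basis_size <= 0))
    stop("basis_size must be > 0", call. = FALSE)
  amount * 100 / basis_size
}

#' Match products across two database years
#'
#' @param db1,db2 [food_db()] objects for the two time points; must carry
#'   different year labels (guards against self-matching).
#' @return A `matched_pairs` data.frame, one row per matched product, sorted
#'   by key, with `_y1`/`_y2` fields, per-100 normalizations and deltas
#'   already computed, and an [exclusion_log()] attribute counting ambiguous
#'   keys and unmatched records.
#' @export
match_products <- function(db1, db2) {
  stopifnot(inherits(db1, "food_db"), inherits(db2, "food_db"))
  if (identical(db1$year_label, db2$year_label))
    stop("both databases carry year_label '", db1$year_label,
         "'; refusing to self-match", call. = FALSE)
  r1 <- db1$records; r2 <- db2$records
  k1 <- match_key(r1); k2 <- match_key(r2)
  amb1 <- k1 %in% k1[duplicated(k1)]
  amb2 <- k2 %in% k2[duplicated(k2)]
  log <- new_exclusion_log()
  log <- log_stage(log, "match", "ambiguous duplicate key in year 1",
                   nrow(r1), sum(amb1))
  log <- log_stage(log, "match", "ambiguous duplicate key in year 2",
                   nrow(r2), sum(amb2))
  u1 <- r1[!amb1, , drop = FALSE]; u2 <- r2[!amb2, , drop = FALSE]
  u1$.key <- k1[!amb1]; u2$.key <- k2[!amb2]
  shared <- intersect(u1$.key, u2$.key)
  log <- log_stage(log, "match", "year-1 records without a year-2 match",
                   nrow(u1), nrow(u1) - length(shared))
  log <- log_stage(log, "match", "year-2 records without a year-1 match",
                   nrow(u2), nrow(u2) - length(shared))
  shared <- sort(shared)
  i1 <- match(shared, u1$.key); i2 <- match(shared, u2$.key)
  a <- u1[i1, , drop = FALSE]; b <- u2[i2, , drop = FALSE]

  pairs <- data.frame(product_code = a$product_code,
                      retailer_id = a$retailer_id,
                      brand = a$brand, brand_type = a$brand_type,
                      tra_category = a$tra_category,
                      container_size = a$container_size,
                      container_unit = a$container_unit,
                      stringsAsFactors = FALSE)
  pairs$serving_size_y1 <- a$serving_size
  pairs$serving_size_y2 <- b$serving_size
  pairs$price_y1 <- a$price; pairs$price_y2 <- b$price
  for (nu in c(NUTRIENT_COLS, "fvnl_percent")) {
    pairs[[paste0(nu, "_y1")]] <- a[[nu]]
    pairs[[paste0(nu, "_y2")]] <- b[[nu]]
  }
  rownames(pairs) <- NULL
  pairs <- compute_deltas(pairs)
  attr(pairs, "exclusion_log") <- log
  attr(pairs, "year_labels") <- c(db1$year_label, db2$year_label)
  class(pairs) <- c("matched_pairs", "data.frame")
  pairs
}

#' Compute per-100 normalizations and year-2 minus year-1 deltas
#'
#' Populates `price_per100_y1/_y2`, `<nutrient>_per100_y1/_y2` (fvnl is
#' already a percentage and passes through), `delta_price` and
#' `delta_<nutrient>`. Missing inputs propagate to missing deltas.
#'
#' @param pairs matched pairs (see [match_products()]).
#' @return pairs with delta fields populated.
#' @export
compute_deltas <- function(pairs) {
  cs <- pairs$container_size
  pairs$price_per100_y1 <- per_hundred(pairs$price_y1, cs)
  pairs$price_per100_y2 <- per_hundred(pairs$price_y2, cs)
  pairs$delta_price <- pairs$price_per100_y2 - pairs$price_per100_y1
  for (nu in NUTRIENT_COLS) {
    y1 <- per_hundred(pairs[[paste0(nu, "_y1")]], pairs$serving_size_y1)
    y2 <- per_hundred(pairs[[paste0(nu, "_y2")]], pairs$serving_size_y2)
    pairs[[paste0(nu, "_per100_y1")]] <- y1
    pairs[[paste0(nu, "_per100_y2")]] <- y2
    pairs[[paste0("delta_", nu)]] <- y2 - y1
  }
  pairs$delta_fvnl <- pairs$fvnl_percent_y2 - pairs$fvnl_percent_y1
  pairs
}

#' Apply one stage of the exclusion cascade
#'
#' Stages, in the study's narrative order:
#' \describe{
#'   \item{category_WX}{drop TRA categories W (food for children <4 y) and X
#'     (meal replacements/substitutes), which face bespoke composition rules.}
#'   \item{invalid_price}{drop pairs where either year's price or the
#'     container size is missing or nonpositive.}
#'   \item{incomplete_nutrition}{drop pairs missing any of the seven core
#'     nutrients (energy, fat, saturated fat, carbohydrate, sugars, protein,
#'     sodium) or a serving size in either year.}
#'   \item{fsanz_ineligible}{drop pairs missing fields the FSANZ scorer needs:
#'     fibre, FVNL percentage, and calcium for cheese candidates (TRA D).}
#' }
#' Each stage is idempotent; every application appends a reconciled row to the
#' exclusion log.
#'
#' @param pairs matched pairs.
#' @param stage one of `"category_WX"`, `"invalid_price"`,
#'   `"incomplete_nutrition"`, `"fsanz_ineligible"`.
#' @return filtered `matched_pairs` with the log entry appended.
#' @export
apply_exclusions <- function(pairs, stage) {
  if (!(length(stage) == 1L && stage %in% EXCLUSION_STAGES))
    stop("unknown exclusion stage: ", paste(stage, collapse = ","),
         call. = FALSE)
  drop <- switch(stage,
    category_WX = pairs$tra_category %in% c("W", "X"),
    invalid_price = {
      bad <- function(x) is.na(x) | x <= 0
      bad(pairs$price_y1) | bad(pairs$price_y2) | bad(pairs$container_size)
    },
    incomplete_nutrition = {
      miss <- is.na(pairs$serving_size_y1) | pairs$serving_size_y1 <= 0 |
        is.na(pairs$serving_size_y2) | pairs$serving_size_y2 <= 0
      for (nu in CORE_NUTRIENTS)
        miss <- miss | is.na(pairs[[paste0(nu, "_y1")]]) |
          is.na(pairs[[paste0(nu, "_y2")]])
      miss
    },
    fsanz_ineligible = {
      miss <- is.na(pairs$fibre_g_y1) | is.na(pairs$fibre_g_y2) |
        is.na(pairs$fvnl_percent_y1) | is.na(pairs$fvnl_percent_y2)
      cheese <- pairs$tra_category %in% "D"
      miss | (cheese & (is.na(pairs$calcium_mg_y1) |
                          is.na(pairs$calcium_mg_y2)))
    })
  drop[is.na(drop)] <- FALSE
  criterion <- switch(stage,
    category_WX = "TRA category W or X",
    invalid_price = "missing or nonpositive price/container size",
    incomplete_nutrition = "incomplete core nutrition in either year",
    fsanz_ineligible = "missing fibre/FVNL/calcium needed for FSANZ")
  log <- log_stage(exclusion_log(pairs), stage, criterion,
                   nrow(pairs), sum(drop))
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  attr(out, "year_labels") <- attr(pairs, "year_labels")
  class(out) <- class(pairs)
  out
}
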
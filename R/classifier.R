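# Five-group reformulation classifier based on Health Canada's front-of-pack
# labelling thresholds: 5 % of the Daily Value ("a little") and 15 % ("a
# lot"). The printed bands are rounded to one decimal; here they tile the
# real line with no gaps: +/-5 and +/-15 exactly belong to the
# larger-magnitude group.

#' @name reformulation-groups
#' @title The five ordered reformulation groups
#' @description `REFORMULATION_GROUPS` holds the five ordered levels:
#'   large_decrease, medium_decrease, little_change, medium_increase,
#'   large_increase.
#' @export
REFORMULATION_GROUPS <- c("large_decrease", "medium_decrease", "little_change",
                          "medium_increase", "large_increase")

#' Load the default Daily Value table
#'
#' Reads the versioned DV reference file shipped with the package (energy
#' kcal, fat/satfat/carb/sugars/protein g, sodium mg). Values are inputs, not
#' logic: pass an edited copy via `path` to change the denominators.
#'
#' @param path optional path to an alternative DV CSV (columns nutrient, dv,
#'   unit; leading `#` lines are comments, one of which may carry
#'   `version: <string>`).
#' @return named list of DV amounts with attributes `unit` and `version`.
#' @export
default_dv_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dv_table.csv", package = "reformprice")
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  version <- sub(".*version:\\s*", "", grep("version:", comments,
                                            value = TRUE)[1])
  tab <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  stringsAsFactors = FALSE)
  stopifnot(all(c("nutrient", "dv") %in% names(tab)), all(tab$dv > 0))
  dv <- setNames(as.list(tab$dv), tab$nutrient)
  attr(dv, "unit") <- setNames(tab$unit, tab$nutrient)
  attr(dv, "version") <- if (is.na(version)) "unversioned" else version
  class(dv) <- "dv_table"
  dv
}

dv_lookup <- function(dv, nutrient) {
  if (is.null(dv[[nutrient]]))
    stop("DV table has no entry for nutrient '", nutrient, "'", call. = FALSE)
  dv[[nutrient]]
}

#' Express a per-100 nutrient delta as a signed percentage
#'
#' The default mode divides by the nutrient's Daily Value (the labelling
#' threshold denominators); `relative_to_baseline` divides by the year-1
#' per-100 amount instead. Both are provided because monitoring studies use
#' both conventions.
#'
#' @param delta_per100 signed change(s) per 100 g (or ml).
#' @param nutrient nutrient id (needed in DV mode).
#' @param dv a DV table from [default_dv_table()].
#' @param mode `"percent_of_dv"` (default) or `"relative_to_baseline"`.
#' @param baseline_per100 year-1 per-100 amount(s) (relative mode); a zero
#'   baseline yields NA.
#' @return signed percentage(s).
#' @export
percent_change <- function(delta_per100, nutrient = NULL,
                           dv = default_dv_table(),
                           mode = c("percent_of_dv", "relative_to_baseline"),
                           baseline_per100 = NULL) {
  mode <- match.arg(mode)
  if (mode == "percent_of_dv") {
    100 * delta_per100 / dv_lookup(dv, nutrient)
  } else {
    if (is.null(baseline_per100))
      stop("relative_to_baseline mode needs baseline_per100", call. = FALSE)
    out <- 100 * delta_per100 / baseline_per100
    out[!is.na(baseline_per100) & baseline_per100 == 0] <- NA_real_
    out
  }
}

#' Classify a signed percentage change into the five reformulation groups
#'
#' Bands: large decrease (<= -15), medium decrease (-15, -5], little change
#' (-5, +5), medium increase [+5, +15), large increase (>= +15).
#'
#' @param pct signed percentage(s); NA passes through, non-finite values are
#'   an error.
#' @return ordered factor over the five groups.
#' @export
classify_reformulation <- function(pct) {
  if (any(!is.na(pct) & !is.finite(pct)))
    stop("percentage change must be finite", call. = FALSE)
  g <- rep(NA_integer_, length(pct))
  ok <- !is.na(pct)
  x <- pct[ok]
  g[ok] <- ifelse(x <= -15, 1L,
           ifelse(x <= -5, 2L,
           ifelse(x < 5, 3L,
           ifelse(x < 15, 4L, 5L))))
  factor(REFORMULATION_GROUPS[g], levels = REFORMULATION_GROUPS,
         ordered = TRUE)
}

#' Classify matched pairs for a set of nutrients
#'
#' @param pairs matched pairs with deltas computed (see [match_products()]).
#' @param dv DV table.
#' @param mode see [percent_change()].
#' @param nutrients nutrient ids to classify (default: the seven core
#'   nutrients).
#' @return long data.frame of class `classified_pairs`: one row per
#'   (pair, nutrient) with the pair's identity/covariates, `delta`, `pct` and
#'   ordered `group`.
#' @export
classify_pairs <- function(pairs, dv = default_dv_table(),
                           mode = c("percent_of_dv", "relative_to_baseline"),
                           nutrients = CORE_NUTRIENTS) {
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(nutrients, function(nu) {
    delta <- pairs[[paste0("delta_", nu)]]
    pct <- percent_change(delta, nu, dv, mode,
                          baseline_per100 = pairs[[paste0(nu, "_per100_y1")]])
    data.frame(product_code = pairs$product_code,
               retailer_id = pairs$retailer_id,
               tra_category = pairs$tra_category,
               brand_type = pairs$brand_type,
               container_size = pairs$container_size,
               delta_price = pairs$delta_price,
               nutrient = nu, delta = delta, pct = pct,
               group = classify_reformulation(pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "dv_version") <- attr(dv, "version")
  attr(out, "mode") <- mode
  class(out) <- c("classified_pairs", "data.frame")
  out
}

#' Tabulate reformulation-group proportions
#'
#' @param classified [classify_pairs()] output.
#' @param by `"overall"`, `"tra_category"` or `"brand_type"`.
#' @return data.frame (cell, nutrient, group, n, prop); proportions over the
#'   five groups sum to 1 within each (cell, nutrient).
#' @export
tabulate_groups <- function(classified,
                            by = c("overall", "tra_category", "brand_type")) {
  by <- match.arg(by)
  if (nrow(classified) == 0L)
    return(data.frame(cell = character(0), nutrient = character(0),
                      group = character(0), n = integer(0),
                      prop = numeric(0)))
  cell <- if (by == "overall") rep("overall", nrow(classified)) else
    classified[[by]]
  keep <- !is.na(classified$group)
  tab <- as.data.frame(table(
    cell = cell[keep], nutrient = classified$nutrient[keep],
    group = factor(classified$group[keep], levels = REFORMULATION_GROUPS)),
    responseName = "n", stringsAsFactors = FALSE)
  tot <- stats::aggregate(n ~ cell + nutrient, tab, sum)
  names(tot)[3] <- "n_cell"
  tab <- merge(tab, tot, by = c("cell", "nutrient"))
  tab$prop <- ifelse(tab$n_cell > 0, tab$n / tab$n_cell, NA_real_)
  tab <- tab[tab$n_cell > 0,
             c("cell", "nutrient", "group", "n", "prop")]
  tab <- tab[order(tab$cell, tab$nutrient,
                   match(tab$group, REFORMULATION_GROUPS)), ]
  rownames(tab) <- NULL
  tab
}

#' Brand-type by reformulation contingency table
#'
#' Collapses the five groups into "reformulated" (any change group) versus
#' "little_change" and cross-tabulates against the four brand types, the
#' input to the chi-square association test.
#'
#' @param classified [classify_pairs()] output.
#' @param nutrient nutrient id.
#' @return 4 x 2 integer matrix (brand types x reformulated/little_change).
#' @export
brand_group_contingency <- function(classified, nutrient) {
  d <- classified[classified$nutrient == nutrient & !is.na(classified$group), ]
  reform <- factor(ifelse(d$group == "little_change", "little_change",
                          "reformulated"),
                   levels = c("reformulated", "little_change"))
  bt <- factor(d$brand_type, levels = BRAND_TYPES)
  as.matrix(table(brand_type = bt, reformulation = reform))
}
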
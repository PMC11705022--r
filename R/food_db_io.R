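#' @importFrom stats median pchisq pnorm psignrank rbinom rlnorm rnorm runif sd
#'   setNames aggregate as.formula coef complete.cases confint lm quantile vcov
#' @importFrom utils read.csv write.csv head
NULL

# Column dictionary for the tabular food-database format. Nutrients are stored
# per serving, as printed in a Nutrition Facts table; fvnl_percent is the
# fruit/vegetable/nut/legume content used for FSANZ V points.
NUTRIENT_COLS <- c("energy_kcal", "fat_g", "satfat_g", "carb_g", "sugars_g",
                   "fibre_g", "protein_g", "sodium_mg", "calcium_mg")

#' @name core-nutrients
#' @title The seven core Nutrition Facts nutrients
#' @description `CORE_NUTRIENTS` names the nutrients defining "complete
#'   nutrition" (and the reformulation analysis set): energy, fat, saturated
#'   fat, carbohydrate, sugars, protein and sodium.
#' @export
CORE_NUTRIENTS <- c("energy_kcal", "fat_g", "satfat_g", "carb_g", "sugars_g",
                    "protein_g", "sodium_mg")

BRAND_TYPES <- c("multinational", "private_label_premium",
                 "private_label_discount", "domestic_or_other")

# TRA major food categories: A..V analysed; W (food for children <4 y) and
# X (meal replacements/substitutes) are excluded from analysis.
TRA_LETTERS <- LETTERS[1:24]
TRA_ANALYSED <- LETTERS[1:22]

DB_NUMERIC_COLS <- c("container_size", "serving_size", "price",
                     NUTRIENT_COLS, "fvnl_percent")

DB_COLS <- c("product_code", "retailer_id", "brand", "brand_type",
             "tra_category", "container_size", "container_unit",
             "serving_size", "serving_unit", "price",
             NUTRIENT_COLS, "fvnl_percent", "year_label")

MANDATORY_COLS <- c("product_code", "retailer_id", "tra_category",
                    "container_size")

#' Construct a food database object
#'
#' A `food_db` wraps one time-point snapshot of a branded-food label database:
#' a data frame with one row per product (identity, classification, sizes,
#' price, per-serving nutrients, FVNL percentage) plus a year label and
#' free-text provenance.
#'
#' @param records data.frame with the columns of the database dictionary
#'   (see [db_column_dictionary()]); missing optional columns are added as NA.
#' @param year_label character scalar identifying the time point.
#' @param provenance free-text metadata carried through reports.
#' @return An object of class `food_db` with elements `records`, `year_label`,
#'   `provenance` and `parse_report`.
#' @export
food_db <- function(records, year_label, provenance = "") {
  stopifnot(is.data.frame(records), is.character(year_label),
            length(year_label) == 1L, nzchar(year_label))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_mand <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_mand) > 0L)
    stop("food database is missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  for (col in setdiff(DB_COLS, names(records))) {
    records[[col]] <- rep(if (col %in% DB_NUMERIC_COLS) NA_real_ else
      NA_character_, nrow(records))
  }
  for (col in DB_NUMERIC_COLS) records[[col]] <- as.numeric(records[[col]])
  for (col in setdiff(DB_COLS, DB_NUMERIC_COLS))
    records[[col]] <- as.character(records[[col]])
  records$year_label <- rep(year_label, nrow(records))
  records <- records[, DB_COLS]
  rownames(records) <- NULL
  structure(list(records = records, year_label = year_label,
                 provenance = provenance,
                 parse_report = data.frame(column = character(0),
                                           n_unparseable = integer(0))),
            class = "food_db")
}

#' @export
print.food_db <- function(x, ...) {
  cat("<food_db> year:", x$year_label, "-", nrow(x$records), "records\n")
  if (nrow(x$parse_report) > 0L)
    cat("  unparseable numeric cells:", sum(x$parse_report$n_unparseable), "\n")
  invisible(x)
}

#' Column dictionary of the food-database CSV format
#'
#' @return data.frame describing every column: name, type, unit and meaning.
#' @export
db_column_dictionary <- function() {
  data.frame(
    column = DB_COLS,
    type = ifelse(DB_COLS %in% DB_NUMERIC_COLS, "numeric", "character"),
    required = DB_COLS %in% MANDATORY_COLS,
    description = c(
      "UPC or retailer-specific product identifier (primary match key)",
      "retailer identifier (match key)",
      "brand name",
      paste("one of:", paste(BRAND_TYPES, collapse = ", ")),
      "TRA major food category letter A-X",
      "container (package) size; basis for price per 100",
      "g or ml",
      "serving size; basis for nutrients per 100",
      "g or ml (must agree with container_unit)",
      "shelf price in currency units (undiscounted)",
      "energy per serving (kcal)", "total fat per serving (g)",
      "saturated fat per serving (g)", "carbohydrate per serving (g)",
      "total sugars per serving (g)", "fibre per serving (g)",
      "protein per serving (g)", "sodium per serving (mg)",
      "calcium per serving (mg)",
      "fruit/vegetable/nut/legume content (% of product)",
      "time-point label shared by all rows"),
    stringsAsFactors = FALSE)
}

#' Read a food database from CSV
#'
#' The dialect is comma-separated UTF-8 with a header row; the empty string is
#' the missing value. Unparseable numeric cells become NA and are counted in
#' the returned object's `parse_report`. Row order is preserved.
#'
#' @param path path to a CSV file with the dictionary columns.
#' @param year_label time-point label; defaults to the file's `year_label`
#'   column when present.
#' @return A [food_db()].
#' @export
read_food_db <- function(path, year_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- suppressWarnings(
    data.table::fread(path, colClasses = "character", sep = ",",
                      header = TRUE, na.strings = NULL,
                      encoding = "UTF-8", data.table = FALSE))
  if (nrow(raw) == 0L && ncol(raw) == 0L)
    stop("empty food database file: ", path, call. = FALSE)
  missing_mand <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_mand) > 0L)
    stop("food database file is missing mandatory column(s): ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  if (is.null(year_label)) {
    yl <- unique(raw$year_label)
    yl <- yl[!is.na(yl) & nzchar(yl)]
    if (length(yl) != 1L)
      stop("year_label not supplied and not unique in file", call. = FALSE)
    year_label <- yl
  }
  parse <- data.frame(column = character(0), n_unparseable = integer(0))
  for (col in intersect(DB_NUMERIC_COLS, names(raw))) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & nzchar(trimws(txt)) & is.na(num)
    if (any(bad))
      parse <- rbind(parse, data.frame(column = col,
                                       n_unparseable = sum(bad)))
    raw[[col]] <- num
  }
  for (col in setdiff(names(raw), DB_NUMERIC_COLS)) {
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA_character_
  }
  db <- food_db(raw, year_label, provenance = paste("read from", path))
  db$parse_report <- parse
  db
}

#' Write a food database to CSV
#'
#' Numeric fields are written with 15 significant digits so that
#' `read_food_db(write_food_db(db))` round-trips all values; missing values
#' are written as the empty string.
#'
#' @param db a [food_db()].
#' @param path output path.
#' @export
write_food_db <- function(db, path) {
  stopifnot(inherits(db, "food_db"))
  out <- db$records
  for (col in DB_NUMERIC_COLS) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.15g", v))
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = ",", na = "", quote = "auto")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write food database to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

match_key <- function(records) {
  paste(records$product_code, records$retailer_id,
        sprintf("%.15g", records$container_size),
        records$container_unit, sep = "\r")
}

#' Validate a food database
#'
#' Pure reporting: flags duplicate (product_code, retailer_id, container_size)
#' keys, nonpositive sizes, unit disagreements, saturated fat exceeding total
#' fat, sugars exceeding carbohydrate, FVNL outside [0, 100], and unknown
#' brand types or TRA categories. Label data can genuinely violate the
#' nutrient-consistency rules, so these are warnings surfaced for logging, not
#' rejections.
#'
#' @param db a [food_db()].
#' @return data.frame of class `validation_report` with columns `rule`, `row`,
#'   `product_code`, `detail`. Empty when the database is clean.
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "food_db"))
  r <- db$records
  out <- list()
  flag <- function(rule, idx, detail) {
    if (length(idx) > 0L)
      out[[length(out) + 1L]] <<- data.frame(
        rule = rule, row = idx, product_code = r$product_code[idx],
        detail = detail, stringsAsFactors = FALSE)
  }
  key <- match_key(r)
  dup <- key %in% key[duplicated(key)]
  flag("duplicate_key", which(dup), "duplicate (code, retailer, size) key")
  flag("nonpositive_container", which(!is.na(r$container_size) & r$container_size <= 0),
       "container_size <= 0")
  flag("nonpositive_serving", which(!is.na(r$serving_size) & r$serving_size <= 0),
       "serving_size <= 0")
  flag("unit_mismatch",
       which(!is.na(r$container_unit) & !is.na(r$serving_unit) &
               r$container_unit != r$serving_unit),
       "serving and container units disagree")
  flag("satfat_gt_fat",
       which(!is.na(r$satfat_g) & !is.na(r$fat_g) & r$satfat_g > r$fat_g),
       "saturated fat exceeds total fat")
  flag("sugars_gt_carb",
       which(!is.na(r$sugars_g) & !is.na(r$carb_g) & r$sugars_g > r$carb_g),
       "sugars exceed carbohydrate")
  flag("fvnl_range",
       which(!is.na(r$fvnl_percent) &
               (r$fvnl_percent < 0 | r$fvnl_percent > 100)),
       "fvnl_percent outside [0, 100]")
  flag("unknown_brand_type",
       which(!is.na(r$brand_type) & !(r$brand_type %in% BRAND_TYPES)),
       "brand_type not one of the four recognised values")
  flag("unknown_tra_category",
       which(!is.na(r$tra_category) & !(r$tra_category %in% TRA_LETTERS)),
       "tra_category not a letter A-X")
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(0), row = integer(0),
               product_code = character(0), detail = character(0))
  rownames(rep) <- NULL
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation: clean\n")
  } else {
    cat("validation:", nrow(x), "flag(s)\n")
    print(as.data.frame(table(rule = x$rule)), row.names = FALSE)
  }
  invisible(x)
}
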
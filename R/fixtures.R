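# A small, fully hand-verified two-year fixture exercising every exclusion
# branch, every reformulation group and all three FSANZ categories. The
# companion expected-output list is written from hand-derived literals (the
# template scores are worked out once, by hand, in the comments below), never
# by running the pipeline, so it can serve as an independent oracle.

fixture_template <- function(name) {
  # per-100 g (or ml) values:
  # energy fat satfat carb sugars fibre protein sodium calcium fvnl
  switch(name,
    # cat2: 418.4 kJ -> 1, satfat 1 -> 1, sugars 4 -> 0, sodium 80 -> 0;
    # baseline 2; V 0, P 2 (protein 4), F 2 (fibre 2) => score -2, pass
    plain  = c(100, 3, 1, 15, 4, 2, 4, 80, 50, 0),
    # plain with sodium 800: baseline 1+1+0+8 = 10 => score 6, fail
    salty  = c(100, 3, 1, 15, 4, 2, 4, 800, 50, 0),
    # plain with sugars 30: baseline 1+1+6+0 = 8 => score 4, fail
    sugary = c(100, 3, 1, 35, 30, 2, 4, 80, 50, 0),
    # cat1: 167.4 kJ -> 0, sugars 9 -> 2, sodium 10 -> 0 => score 2, fail
    soda   = c(40, 0, 0, 10, 9, 0, 0, 10, 0, 0),
    # cat1: all zero => score 0, pass
    water  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    # cat3 (TRA H): 3012.48 kJ -> 8, satfat 50 -> 24 (cat3 ladder),
    # sugars 0.6 -> 0, sodium 600 -> 6; baseline 38; P gated => 38, fail
    butter = c(720, 81, 50, 0.6, 0.6, 0, 0.5, 600, 20, 0),
    # cheese, calcium 800 > 320 -> cat3: 1673.6 kJ -> 4, satfat 21 -> 16,
    # sugars 1 -> 0, sodium 700 -> 7; baseline 27; P gated => 27, pass (<28)
    cheese = c(400, 33, 21, 2, 1, 0, 25, 700, 800, 0),
    # same nutrients, calcium 300 -> cat2: 4 + 10 (satfat capped) + 0 + 7
    # = 21; P gated => 21, fail
    cheese_lowca = c(400, 33, 21, 2, 1, 0, 25, 700, 300, 0),
    # cat2 veg, fvnl 100: 125.5 kJ -> 0, sodium 200 -> 2; baseline 2;
    # V 5, P 1 (protein 2), F 3 (fibre 3) => score 2-5-1-3 = -7, pass
    veg    = c(30, 0.3, 0.1, 5, 3, 3, 2, 200, 40, 100),
    stop("unknown template ", name))
}

fixture_row <- function(code, template, tra = "C", brand_type = "multinational",
                        serving = 100, container = 500, price = 5,
                        year_label = "2017", overrides = NULL) {
  v <- fixture_template(template)
  names(v) <- c(NUTRIENT_COLS, "fvnl_percent")
  if (!is.null(overrides)) v[names(overrides)] <- overrides
  unit <- if (tra == "B") "ml" else "g"
  row <- data.frame(product_code = code, retailer_id = "RA",
                    brand = "FIXTURE", brand_type = brand_type,
                    tra_category = tra, container_size = container,
                    container_unit = unit, serving_size = serving,
                    serving_unit = unit, price = price,
                    stringsAsFactors = FALSE)
  for (nu in c(NUTRIENT_COLS, "fvnl_percent"))
    row[[nu]] <- unname(v[nu]) * serving / 100   # stored per serving
  row$year_label <- year_label
  row
}

#' Write the checked-in example fixture databases
#'
#' Builds a 60-product two-year fixture pair exercising every exclusion
#' branch (W/X categories, invalid prices, incomplete nutrition, FSANZ
#' ineligibility, ambiguous duplicate keys, shrinkflation, one-year-only
#' products), every sodium reformulation group, and all three FSANZ
#' categories, together with a companion JSON of hand-verified expected
#' outputs (exclusion flow, sodium group counts, brand contingency, and
#' per-product NPSC scores).
#'
#' @param out_dir directory to write `fixture_y1.csv`, `fixture_y2.csv` and
#'   `fixture_expected.json`.
#' @return invisibly, the list of written paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  P <- function(i) sprintf("P%02d", i)
  y1 <- list(); y2 <- list()
  add <- function(i, template, y2_overrides = NULL, y1_overrides = NULL,
                  tra = "C", brand_type = "multinational", serving = 100,
                  price_y1 = 5 + 0.01 * i, price_y2 = 5.5 + 0.03 * ((i * 7) %% 11),
                  container = 500, container_y2 = NULL, years = c(1, 2)) {
    if (1 %in% years)
      y1[[length(y1) + 1L]] <<- fixture_row(P(i), template, tra, brand_type,
                                            serving, container, price_y1,
                                            "2017", y1_overrides)
    if (2 %in% years)
      y2[[length(y2) + 1L]] <<- fixture_row(P(i), template, tra, brand_type,
                                            serving,
                                            container_y2 %||% container,
                                            price_y2, "2020", y2_overrides)
  }
  # sodium reformulation groups (DV 2300 mg: 5% = 115, 15% = 345 per 100 g);
  # P01 uses a 50 g serving so per-serving storage exercises normalization
  add(1, "salty", y2_overrides = c(sodium_mg = 400), serving = 50,
      brand_type = "private_label_premium")          # -400 -> large_decrease
  add(2, "salty", y2_overrides = c(sodium_mg = 600),
      brand_type = "private_label_discount")         # -200 -> medium_decrease
  add(3, "salty", y2_overrides = c(sodium_mg = 950)) # +150 -> medium_increase
  add(4, "salty", y2_overrides = c(sodium_mg = 1200),
      brand_type = "domestic_or_other")              # +400 -> large_increase
  add(5, "salty", y2_overrides = c(sodium_mg = 900)) # +100 -> little_change
  # sugars: -20 g/100 g = -20% DV -> large_decrease
  add(6, "sugary", y2_overrides = c(sugars_g = 10))
  # FSANZ category 1 (beverages)
  add(7, "soda", tra = "B")
  add(8, "water", tra = "B")
  add(9, "soda", tra = "B", y2_overrides = c(sugars_g = 4.4))  # -4.6% little
  add(10, "soda", tra = "B", y1_overrides = c(sugars_g = 4.4),
      y2_overrides = c(sugars_g = 4.4))
  # FSANZ category 3 and the calcium split
  add(11, "butter", tra = "H")
  add(12, "cheese", tra = "D")
  add(13, "cheese_lowca", tra = "D")
  add(14, "veg", tra = "V")
  for (i in 15:43) add(i, "plain")
  add(52, "plain")
  # fsanz_ineligible branch
  add(44, "plain", y1_overrides = c(fibre_g = NA), y2_overrides = c(fibre_g = NA))
  add(45, "plain", y2_overrides = c(fvnl_percent = NA))
  add(46, "cheese", tra = "D", y2_overrides = c(calcium_mg = NA))
  # incomplete_nutrition branch
  add(47, "plain", y2_overrides = c(sodium_mg = NA))
  add(48, "plain", y1_overrides = setNames(rep(NA_real_, 7), CORE_NUTRIENTS))
  add(49, "plain", y1_overrides = c(carb_g = NA))
  # invalid_price branch
  add(50, "plain", price_y2 = NA)
  add(51, "plain", price_y1 = 0)
  # category W/X branch
  add(53, "plain", tra = "W")
  add(54, "plain", tra = "X")
  # unmatched and ambiguous branches
  add(55, "plain", years = 1)
  add(56, "plain", years = 1)
  add(57, "plain", years = 2)
  add(58, "plain", years = 2)
  add(59, "plain", container = 500, container_y2 = 450)  # shrinkflation
  add(60, "plain", years = 1)
  add(60, "plain", years = 1)  # duplicate key -> ambiguous
  add(60, "plain", years = 2)

  db1 <- food_db(do.call(rbind, y1), "2017", "hand-built fixture")
  db2 <- food_db(do.call(rbind, y2), "2020", "hand-built fixture")
  f1 <- file.path(out_dir, "fixture_y1.csv")
  f2 <- file.path(out_dir, "fixture_y2.csv")
  write_food_db(db1, f1)
  write_food_db(db2, f2)

  # ---- hand-verified expectations -----------------------------------------
  plain_scores <- setNames(rep(list(c(-2, -2)), 30),
                           c(sapply(15:43, P), P(52)))
  scores <- c(list(
    P01 = c(6, 2), P02 = c(6, 4), P03 = c(6, 8), P04 = c(6, 8),
    P05 = c(6, 8), P06 = c(4, 0), P07 = c(2, 2), P08 = c(0, 0),
    P09 = c(2, 0), P10 = c(0, 0), P11 = c(38, 38), P12 = c(27, 27),
    P13 = c(21, 21), P14 = c(-7, -7)), plain_scores)
  expected <- list(
    n_y1_rows = 59, n_y2_rows = 58,
    n_ambiguous_y1 = 2, n_ambiguous_y2 = 0,
    n_unmatched_y1 = 3, n_unmatched_y2 = 4,
    n_matched = 54,
    n_after_category_WX = 52,
    n_after_invalid_price = 50,
    n_after_incomplete_nutrition = 47,
    n_after_fsanz_ineligible = 44,
    sodium_groups = list(large_decrease = 1, medium_decrease = 1,
                         little_change = 43, medium_increase = 1,
                         large_increase = 1),
    sugars_groups = list(large_decrease = 1, medium_decrease = 0,
                         little_change = 46, medium_increase = 0,
                         large_increase = 0),
    # brand_type x (reformulated, little_change) for sodium, n = 47
    sodium_contingency = list(multinational = c(1, 43),
                              private_label_premium = c(1, 0),
                              private_label_discount = c(1, 0),
                              domestic_or_other = c(1, 0)),
    fsanz_category_counts = list(cat1_beverages = 4, cat2_other = 38,
                                 cat3_cheese_fats_oils = 2),
    scores = scores)
  fj <- file.path(out_dir, "fixture_expected.json")
  jsonlite::write_json(expected, fj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(y1 = f1, y2 = f2, expected = fj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
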
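tables <- load_npsc_tables()

test_that("category assignment follows the TRA mapping and calcium split", {
  expect_equal(as.character(assign_fsanz_category("B", tables = tables)),
               "cat1_beverages")
  expect_equal(as.character(assign_fsanz_category("D", 321, tables)),
               "cat3_cheese_fats_oils")
  expect_equal(as.character(assign_fsanz_category("D", 320, tables)),
               "cat2_other")
  expect_equal(as.character(assign_fsanz_category("H", tables = tables)),
               "cat3_cheese_fats_oils")
  expect_equal(as.character(assign_fsanz_category("A", tables = tables)),
               "cat2_other")
  expect_true(is.na(assign_fsanz_category("D", NA, tables)))
})

test_that("lookup_points is a capped inclusive step function", {
  steps <- stub_steps()
  expect_equal(lookup_points(0, steps), 0L)
  expect_equal(lookup_points(700, steps), 2L)
  expect_equal(lookup_points(334.9, steps), 0L)
  expect_equal(lookup_points(335, steps), 1L)
  expect_equal(lookup_points(1e6, steps), 2L)
  expect_error(lookup_points(-1, steps), "non-negative")
  # the real energy table at its first threshold (expressed in kcal input)
  expect_equal(lookup_points(335, as.matrix(tables$baseline$energy_kj$steps)),
               1L)
})

test_that("score arithmetic: baseline minus V, P, F", {
  r <- score_products(0, 0, 0, 0, 0, 0, 0, "cat2_other", tables)
  expect_equal(r$baseline_points, 0L)
  expect_equal(r$score, 0L)
  # baseline 5 (energy 1675.1 kJ = 400.36 kcal), V 2 (fvnl 65), P 1
  # (protein 2), F 1 (fibre 1) -> score 1
  r2 <- score_products(1675.1 / 4.184, 0, 0, 0, 65, 2, 1, "cat2_other",
                       tables)
  expect_equal(r2$baseline_points, 5L)
  expect_equal(c(r2$v_points, r2$p_points, r2$f_points), c(2L, 1L, 1L))
  expect_equal(r2$score, 1L)
  expect_error(score_products(NA, 0, 0, 0, 0, 0, 0, "cat2_other", tables),
               "missing required field")
})

test_that("protein points are withheld at the gate unless V points exempt", {
  # baseline 14 from sodium alone is impossible in cat2 (cap 10); use
  # energy 6 + sodium 8 = 14 >= gate 13
  args <- list(energy_kcal = 2011 / 4.184, satfat_g = 0, sugars_g = 0,
               sodium_mg = 720, protein_g = 10, fibre_g = 0)
  gated <- score_products(args$energy_kcal, 0, 0, args$sodium_mg, 0,
                          args$protein_g, 0, "cat2_other", tables)
  expect_equal(gated$baseline_points, 14L)
  expect_equal(gated$p_points, 0L)
  exempt <- score_products(args$energy_kcal, 0, 0, args$sodium_mg, 100,
                           args$protein_g, 0, "cat2_other", tables)
  expect_equal(exempt$v_points, 5L)
  expect_equal(exempt$p_points, 5L)
  below <- score_products(0, 0, 0, 720, 0, args$protein_g, 0, "cat2_other",
                          tables)
  expect_equal(below$p_points, 5L)
})

test_that("eligibility thresholds are strict 'below'", {
  expect_true(npsc_eligible(0, "cat1_beverages", tables))
  expect_false(npsc_eligible(1, "cat1_beverages", tables))
  expect_true(npsc_eligible(3, "cat2_other", tables))
  expect_false(npsc_eligible(4, "cat2_other", tables))
  expect_true(npsc_eligible(27, "cat3_cheese_fats_oils", tables))
  expect_false(npsc_eligible(28, "cat3_cheese_fats_oils", tables))
})

test_that("score is monotone in nutrients to limit and encouraged components", {
  base <- list(e = 150, sf = 3, su = 12, na = 400, fv = 20, pr = 4, fb = 2)
  s0 <- score_products(base$e, base$sf, base$su, base$na, base$fv, base$pr,
                       base$fb, "cat2_other", tables)$score
  grid <- seq(0, 60, by = 1.7)
  for (x in grid) {
    expect_gte(score_products(base$e, base$sf + x, base$su, base$na, base$fv,
                              base$pr, base$fb, "cat2_other", tables)$score,
               s0)
    expect_lte(score_products(base$e, base$sf, base$su, base$na,
                              min(100, base$fv + x), base$pr, base$fb,
                              "cat2_other", tables)$score, s0)
    expect_lte(score_products(base$e, base$sf, base$su, base$na, base$fv,
                              base$pr, base$fb + x, "cat2_other",
                              tables)$score, s0)
  }
})

test_that("two scorer instances from the same file agree on a boundary grid", {
  t2 <- load_npsc_tables(system.file("extdata", "npsc_tables.json",
                                     package = "reformprice"))
  thr <- as.matrix(tables$baseline$sodium_mg$cat3_steps)[, 1]
  vals <- sort(c(thr, thr - 1e-9, thr + 1e-9, 0))
  for (cat in c("cat2_other", "cat3_cheese_fats_oils")) {
    a <- score_products(rep(100, length(vals)), 2, 6, vals, 0, 3, 1, cat,
                        tables)
    b <- score_products(rep(100, length(vals)), 2, 6, vals, 0, 3, 1, cat, t2)
    expect_identical(a$score, b$score)
  }
})

test_that("score change is year 2 minus year 1 with missing propagation", {
  d <- tempfile()
  paths <- make_fixtures(d)
  db1 <- read_food_db(paths$y1); db2 <- read_food_db(paths$y2)
  pairs <- match_products(db1, db2)
  pairs <- apply_exclusions(pairs, "category_WX")
  pairs <- apply_exclusions(pairs, "invalid_price")
  pairs <- apply_exclusions(pairs, "incomplete_nutrition")
  scored_all <- fsanz_score_pairs(pairs)   # without the eligibility filter
  expect_gt(attr(scored_all, "n_unscoreable"), 0)
  scored <- fsanz_score_pairs(apply_exclusions(pairs, "fsanz_ineligible"))
  expect_equal(attr(scored, "n_unscoreable"), 0L)
  sc <- setNames(scored$score_change, scored$product_code)
  expect_equal(unname(sc["P01"]), -4)   # sodium 800 -> 400 per 100 g
  expect_equal(unname(sc["P15"]), 0)
  unlink(d, recursive = TRUE)
})
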
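test_that("generation is deterministic given config and seed", {
  cfg <- supply_config(n_products = 200, seed = 42)
  a <- generate_supply(cfg)
  b <- generate_supply(cfg)
  expect_identical(a$db1$records, b$db1$records)
  expect_identical(a$db2$records, b$db2$records)
  expect_identical(a$truth$groups, b$truth$groups)
  c2 <- generate_supply(supply_config(n_products = 200, seed = 43))
  expect_false(identical(a$db1$records, c2$db1$records))
})

test_that("degenerate configs behave as stated", {
  cfg <- supply_config(n_products = 50, unmatched_frac = 0,
                       shrinkflation_prob = 0, missing_price_frac = 0,
                       missing_nutrition_frac = 0, seed = 5)
  sim <- generate_supply(cfg)
  pairs <- match_products(sim$db1, sim$db2)
  expect_equal(nrow(pairs), 50L)

  cfg0 <- supply_config(n_products = 80, seed = 5,
                        reformulation_prevalence = c(sodium_mg = 0))
  t0 <- generate_supply(cfg0)$truth
  expect_true(all(t0$groups$group[t0$groups$nutrient == "sodium_mg"] ==
                    "little_change"))
})

test_that("invalid configs fail before any generation", {
  expect_error(supply_config(n_products = 0), "n_products")
  expect_error(supply_config(unmatched_frac = 1.2), "probabilities")
  expect_error(supply_config(brand_type_weights = c(multinational = 0.7,
                                                    private_label_premium = 0.7,
                                                    private_label_discount = 0,
                                                    domestic_or_other = 0)),
               "sum to 1")
  expect_error(supply_config(reformulation_prevalence = c(unknown = 0.1)),
               "core nutrients")
})

test_that("realized changed fraction tracks the configured prevalence", {
  cfg <- supply_config(n_products = 5000, unmatched_frac = 0,
                       shrinkflation_prob = 0,
                       reformulation_prevalence = c(sodium_mg = 0.18),
                       seed = 11)
  truth <- generate_supply(cfg)$truth
  g <- truth$groups[truth$groups$nutrient == "sodium_mg", ]
  frac <- mean(g$group != "little_change")
  se <- sqrt(0.18 * 0.82 / 5000)
  expect_lt(abs(frac - 0.18), 3 * se)
})

test_that("every product is accounted for across years", {
  cfg <- supply_config(n_products = 400, seed = 9)
  sim <- generate_supply(cfg)
  st <- sim$truth$products$status
  expect_equal(sum(st == "matched") + sum(st == "only_y1") +
                 sum(st == "only_y2"), 400L)
  expect_equal(nrow(sim$db1$records), sum(st != "only_y2"))
  expect_equal(nrow(sim$db2$records), sum(st != "only_y1"))
})

test_that("classifying generated deltas reproduces the truth groups exactly", {
  cfg <- supply_config(n_products = 600, unmatched_frac = 0.1,
                       shrinkflation_prob = 0, missing_price_frac = 0,
                       missing_nutrition_frac = 0, seed = 3)
  sim <- generate_supply(cfg)
  pairs <- match_products(sim$db1, sim$db2)
  cl <- classify_pairs(pairs)
  truth <- sim$truth$groups
  m <- merge(cl[, c("product_code", "nutrient", "group")],
             truth[, c("product_code", "nutrient", "group")],
             by = c("product_code", "nutrient"),
             suffixes = c("_est", "_truth"))
  expect_equal(nrow(m), nrow(cl))
  expect_identical(as.character(m$group_est), m$group_truth)
})

test_that("truth_summary conserves counts per nutrient", {
  cfg <- supply_config(n_products = 300, seed = 21)
  truth <- generate_supply(cfg)$truth
  ts <- truth_summary(truth)
  n_matched <- sum(truth$products$status == "matched")
  sums <- tapply(ts$n, ts$nutrient, sum)
  expect_true(all(sums == n_matched))
  empty <- truth
  empty$groups <- truth$groups[0, ]
  expect_equal(nrow(truth_summary(empty)), 0L)
})
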
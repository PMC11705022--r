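test_that("wilcoxon exact p matches exhaustive sign-pattern enumeration", {
  # oracle: enumerate all 2^n sign assignments of ranks 1..n
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- signs %*% r
    mean(Vs >= V) * 2  # all-positive case: upper tail, doubled
  }
  d <- c(1, 2, 3, 4, 5)
  w <- wilcoxon_paired(rep(0, 5), d)
  expect_equal(w$method, "exact")
  expect_equal(w$statistic, 15)
  expect_equal(enum_p(d), 2 / 32)
  expect_equal(w$p.value, 2 / 32)
  # mixed-sign case against the same enumeration
  d2 <- c(3, -1, 4, 2, -6, 5, 7)
  w2 <- wilcoxon_paired(rep(0, 7), d2)
  n <- 7; r <- rank(abs(d2)); V <- sum(r[d2 > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_enum <- 2 * min(mean(Vs >= V), mean(Vs <= V))
  expect_equal(w2$p.value, p_enum)
})

test_that("wilcoxon handles zeros, degeneracy and large n", {
  expect_equal(wilcoxon_paired(1:10, 1:10)$p.value, 1)
  expect_true(wilcoxon_paired(1:10, 1:10)$degenerate)
  w <- wilcoxon_paired(rep(0, 6), c(0, 0, 1, -2, 3, 4))
  expect_equal(w$n_zero, 2L)
  expect_equal(w$n, 4L)
  # agreement with the stats implementation in the approximate regime
  set.seed(4)
  x <- rnorm(60); y <- x + rnorm(60, 0.2)
  ours <- wilcoxon_paired(x, y)
  ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("null p-values are approximately uniform across replicates", {
  set.seed(99)
  p <- replicate(400, wilcoxon_paired(rnorm(40), rnorm(40))$p.value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("chi-square matches hand computation", {
  r <- chi_square(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r$statistic, 20 / 3)
  expect_equal(r$df, 1L)
  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  # a table proportional to its margins has statistic 0
  tab <- outer(c(2, 3), c(10, 30, 60))
  expect_equal(chi_square(tab)$statistic, 0)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margins")
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_true(chi_square(matrix(c(1, 2, 3, 4), 2))$caution)
})

test_that("BH step-up matches the hand computation and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    expect_true(all(bh_adjust(p) >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("single-retailer mixed model reduces to the OLS fit", {
  sim <- generate_supply(supply_config(n_products = 800, n_retailers = 1,
                                       unmatched_frac = 0,
                                       shrinkflation_prob = 0,
                                       missing_price_frac = 0,
                                       missing_nutrition_frac = 0,
                                       retailer_price_offsets = 0, seed = 12))
  pairs <- match_products(sim$db1, sim$db2)
  cl <- classify_pairs(pairs)
  m <- fit_reformulation_model(cl, "sodium_mg")
  expect_true(all(m$model == "lm"))
  d <- cl[cl$nutrient == "sodium_mg", ]
  d$group <- factor(as.character(d$group),
                    levels = c("little_change",
                               setdiff(REFORMULATION_GROUPS, "little_change")))
  d$group <- droplevels(d$group)
  d <- d[d$group %in% names(which(table(d$group) >= 5)), ]
  d$cont_std <- (d$container_size - mean(d$container_size)) /
    sd(d$container_size)
  ols <- lm(delta_price ~ group + cont_std + brand_type,
            data = transform(d, brand_type = factor(brand_type,
                                                    levels = c("multinational",
                                                               "private_label_premium",
                                                               "private_label_discount",
                                                               "domestic_or_other"))))
  cf <- coef(ols)
  for (i in seq_len(nrow(m))) {
    expect_equal(m$beta[i], unname(cf[paste0("group", m$term[i])]),
                 tolerance = 1e-6)
  }
})

test_that("groups below the minimum size are dropped before fitting", {
  cl <- data.frame(
    product_code = paste0("P", 1:40), retailer_id = rep(c("RA", "RB"), 20),
    tra_category = "C", brand_type = "multinational",
    container_size = rep(c(250, 500), 20),
    delta_price = rnorm(40), nutrient = "sodium_mg", delta = 0,
    pct = c(rep(0, 30), rep(20, 7), rep(-20, 3)),
    stringsAsFactors = FALSE)
  cl$group <- classify_reformulation(cl$pct)
  m <- fit_reformulation_model(cl, "sodium_mg", min_n = 5)
  expect_equal(m$term, "large_increase")
  expect_equal(attr(m, "dropped"), "large_decrease")
  m_none <- fit_reformulation_model(cl[cl$group == "little_change", ],
                                    "sodium_mg")
  expect_equal(nrow(m_none), 0L)
})

test_that("fsanz model skips constant-predictor and small cells", {
  sim <- generate_supply(supply_config(n_products = 300, unmatched_frac = 0,
                                       shrinkflation_prob = 0,
                                       missing_price_frac = 0,
                                       missing_nutrition_frac = 0, seed = 31))
  pairs <- match_products(sim$db1, sim$db2)
  pairs <- apply_exclusions(pairs, "category_WX")
  scored <- fsanz_score_pairs(pairs)
  scored$score_change <- 0L   # constant predictor everywhere
  m <- fit_fsanz_model(scored, "overall")
  expect_equal(nrow(m), 0L)
  expect_equal(attr(m, "skipped"), "overall")
})

test_that("price summaries are internally consistent", {
  sim <- generate_supply(supply_config(n_products = 300, seed = 17))
  pairs <- apply_exclusions(apply_exclusions(
    match_products(sim$db1, sim$db2), "category_WX"), "invalid_price")
  s <- summarize_prices(pairs, "retailer_id")
  expect_equal(sum(s$n), nrow(pairs))
  one <- pairs[pairs$retailer_id == s$cell[1], ]
  expect_equal(s$mean_y1[1], mean(one$price_per100_y1))
  expect_equal(s$median_y2[1], median(one$price_per100_y2))
  expect_true(all(s$p_adj >= s$p_raw - 1e-15))
  ident <- summarize_prices(tiny_pairs(5, function(r2) r2), "overall")
  expect_true(ident$degenerate)
  expect_equal(ident$p_raw, 1)
})
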
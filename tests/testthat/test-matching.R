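test_that("self-match of a relabelled copy pairs everything with zero deltas", {
  pairs <- tiny_pairs(10)
  expect_equal(nrow(pairs), 10L)
  expect_true(all(pairs$delta_price == 0))
  expect_true(all(pairs$delta_sodium_mg == 0))
  expect_error(match_products(tiny_db(3, "2017"), tiny_db(3, "2017")),
               "self-match")
})

test_that("shrinkflation breaks the size-based match key", {
  pairs <- tiny_pairs(3, function(r2) {
    r2$container_size[1] <- 450  # was 500
    r2
  })
  expect_equal(nrow(pairs), 2L)
  log <- exclusion_log(pairs)
  expect_equal(log$n_removed[log$criterion ==
                               "year-1 records without a year-2 match"], 1L)
})

test_that("hand-enumerated fixture: shared, one-year-only and ambiguous keys", {
  r1 <- tiny_records(8)                       # C1..C8
  r2 <- tiny_records(9, year_label = "2020")  # C1..C9
  r1 <- r1[r1$product_code %in% paste0("C", 1:7), ]   # 5 shared + dup + 1 only-y1
  r2 <- r2[r2$product_code %in% paste0("C", c(1:5, 7:9)), ]
  r1 <- rbind(r1, r1[r1$product_code == "C5", ])      # C5 duplicated in y1
  r2 <- r2[r2$product_code != "C6", ]
  # shared keys: C1..C5, C7; C5 ambiguous -> 5 pairs... minus the duplicate
  pairs <- match_products(food_db(r1, "2017"), food_db(r2, "2020"))
  expect_equal(nrow(pairs), 5L)
  expect_false("C5" %in% pairs$product_code)
  log <- exclusion_log(pairs)
  expect_equal(log$n_removed[log$criterion ==
                               "ambiguous duplicate key in year 1"], 2L)
})

test_that("matching output is invariant to input row order", {
  r1 <- tiny_records(20); r2 <- tiny_records(20, "2020")
  r2$sodium_mg <- r2$sodium_mg + seq_len(20)
  a <- match_products(food_db(r1, "2017"), food_db(r2, "2020"))
  b <- match_products(food_db(r1[rev(seq_len(20)), ], "2017"),
                      food_db(r2[sample(20), ], "2020"))
  attr_strip <- function(x) { attributes(x) <- attributes(x)[c("names", "class", "row.names")]; x }
  expect_equal(attr_strip(a), attr_strip(b))
})

test_that("exclusion cascade counts reconcile on a hand-counted fixture", {
  pairs <- tiny_pairs(10, function(r2) {
    r2$price[3] <- NA
    r2$sodium_mg[4:6] <- NA
    r2
  })
  # put two pairs in W/X via shared mutation of both years
  pairs$tra_category[1:2] <- c("W", "X")
  n0 <- nrow(pairs)
  p1 <- apply_exclusions(pairs, "category_WX")
  p2 <- apply_exclusions(p1, "invalid_price")
  p3 <- apply_exclusions(p2, "incomplete_nutrition")
  expect_equal(c(n0, nrow(p1), nrow(p2), nrow(p3)), c(10, 8, 7, 4))
  log <- exclusion_log(p3)
  expect_true(all(log$n_in - log$n_removed == log$n_out))
  expect_true(all(diff(log$n_out[log$stage != "match"]) <= 0))
  expect_error(apply_exclusions(pairs, "bogus"), "unknown exclusion stage")
})

test_that("each exclusion stage is idempotent", {
  pairs <- tiny_pairs(8, function(r2) { r2$price[1] <- NA; r2 })
  pairs$tra_category[2] <- "W"
  for (stage in c("category_WX", "invalid_price", "incomplete_nutrition",
                  "fsanz_ineligible")) {
    once <- apply_exclusions(pairs, stage)
    twice <- apply_exclusions(once, stage)
    expect_equal(nrow(twice), nrow(once))
    log <- exclusion_log(twice)
    expect_equal(log$n_removed[nrow(log)], 0L)
  }
})

test_that("per_hundred arithmetic, scale invariance and error handling", {
  expect_equal(per_hundred(3.00, 300), 1.00)
  expect_equal(per_hundred(240, 30), 800)
  expect_error(per_hundred(1, 0), "basis_size")
  expect_error(per_hundred(1, -5), "basis_size")
  expect_true(is.na(per_hundred(NA, 50)))
  for (k in c(0.1, 1, 7, 250)) {
    expect_equal(per_hundred(k * 240, k * 30), per_hundred(240, 30))
  }
})

test_that("deltas follow the year-2 minus year-1 sign convention", {
  r1 <- tiny_records(2)
  r1$sodium_mg <- c(240, 80); r1$serving_size <- c(30, 100)  # 800, 80 /100 g
  r2 <- tiny_records(2, "2020")
  r2$sodium_mg <- c(204, 80); r2$serving_size <- c(30, 100)  # 680, 80 /100 g
  r2$price <- c(7.6, 5)                                      # 1.52, 1.00 /100 g
  pairs <- match_products(food_db(r1, "2017"), food_db(r2, "2020"))
  expect_equal(pairs$delta_sodium_mg, c(-120, 0))
  expect_equal(pairs$delta_price, c(0.52, 0), tolerance = 1e-12)
})
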
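test_that("two-way mean squares match the brute-force oracle", {
  # hand fixture: columns 1,3,5,7 and 2,4,6,8 -> zero residual
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  ms <- two_way_mean_squares(m)
  expect_equal(ms$msr, 40 / 3)
  expect_equal(ms$msc, 2)
  expect_equal(ms$mse, 0)
  # frozen values on the 10x3 fixture
  ms3 <- two_way_mean_squares(icc_fixture_matrix())
  expect_equal(ms3$msr, icc_fixture_expected$ms$msr, tolerance = 1e-12)
  expect_equal(ms3$msc, icc_fixture_expected$ms$msc, tolerance = 1e-12)
  expect_equal(ms3$mse, icc_fixture_expected$ms$mse, tolerance = 1e-12)
})

test_that("sum-of-squares conservation holds on random matrices", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:15, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 100, 10), n, k)
    ms <- two_way_mean_squares(m)
    total <- sum((m - mean(m))^2)
    recon <- (n - 1) * ms$msr + (k - 1) * ms$msc +
      (n - 1) * (k - 1) * ms$mse
    expect_equal(recon, total, tolerance = 1e-10)
  }
})

test_that("degenerate matrices are rejected", {
  expect_error(two_way_mean_squares(matrix(1:4, 2, 2)),
               class = "volagree_insufficient_data_error")
  expect_error(icc_absolute(matrix(1:4, 4, 1)),
               class = "volagree_insufficient_data_error")
  expect_error(icc_consistency(matrix(5, 4, 2)),
               class = "volagree_undefined_icc_error")
})

test_that("identical and offset columns behave as the two models demand", {
  base <- c(10, 12, 9, 14, 11)
  same <- cbind(base, base)
  expect_equal(icc_absolute(same)$value, 1)
  expect_equal(icc_consistency(same)$value, 1)
  offset <- cbind(base, base + 3)
  expect_equal(icc_consistency(offset)$value, 1)
  expect_lt(icc_absolute(offset)$value, 1)
})

test_that("a planted rater offset separates consistency from agreement", {
  set.seed(8)
  m <- cbind(rnorm(6, 50, 5), rnorm(6, 50, 5) + 4)
  m[, 2] <- m[, 1] + 4 + rnorm(6, 0, 0.5)
  expect_gt(icc_consistency(m)$value, icc_absolute(m)$value)
})

test_that("point estimates and CIs match the frozen reference values", {
  m <- icc_fixture_matrix()
  a <- icc_absolute(m)
  expect_equal(a$value, icc_fixture_expected$absolute$icc,
               tolerance = 1e-9)
  expect_equal(a$ci_low, icc_fixture_expected$absolute$ci_low,
               tolerance = 1e-9)
  expect_equal(a$ci_high, icc_fixture_expected$absolute$ci_high,
               tolerance = 1e-9)
  cc <- icc_consistency(m)
  expect_equal(cc$value, icc_fixture_expected$consistency$icc,
               tolerance = 1e-9)
  expect_equal(cc$ci_low, icc_fixture_expected$consistency$ci_low,
               tolerance = 1e-9)
  expect_equal(cc$ci_high, icc_fixture_expected$consistency$ci_high,
               tolerance = 1e-9)
  expect_true(a$ci_low <= a$value && a$value <= a$ci_high)
})

test_that("ICCs are invariant to affine rescaling of all cells", {
  m <- icc_fixture_matrix()
  m2 <- 3.2 * m + 17
  expect_equal(icc_absolute(m)$value, icc_absolute(m2)$value,
               tolerance = 1e-12)
  expect_equal(icc_consistency(m)$value, icc_consistency(m2)$value,
               tolerance = 1e-12)
})

test_that("agreement never exceeds consistency when MSC >= MSE", {
  # the ordering holds whenever the common numerator MSR - MSE is
  # non-negative and rater variance is at least residual variance
  set.seed(77)
  checked <- 0
  for (i in 1:40) {
    n <- sample(5:20, 1); k <- sample(2:4, 1)
    subj <- rnorm(n, 100, 8)
    m <- matrix(subj, n, k) + rep(rnorm(k, 0, 2), each = n) +
      rnorm(n * k, 0, 3)
    ms <- two_way_mean_squares(m)
    if (ms$msc >= ms$mse && ms$msr >= ms$mse) {
      expect_lte(icc_absolute(m)$value,
                 icc_consistency(m)$value + 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("classification bands are lower-inclusive", {
  expect_equal(classify_icc(c(0.95, 0.9, 0.89, 0.75, 0.74, 0.5, 0.49,
                              0.4, -0.2)),
               c("excellent", "excellent", "good", "good", "moderate",
                 "moderate", "poor", "poor", "poor"))
  expect_error(classify_icc(1.2))
})

test_that("icc_table covers scanners, pairs and the joint comparison", {
  cfg <- synthetic_config(
    structures = tibble::tibble(structure = c("brain", "gm"),
                                mean_volume = c(1.05e6, 6e5),
                                subject_cv = 0.046),
    scanner_bias = data.frame(scanner_id = "GE", structure = "gm",
                              bias = 1.02),
    interaction_cv = 0.005, seed = 2,
    missing = data.frame(subject = 1L, scanner_id = "GE", run = 2L))
  co <- generate_cohort(cfg, software = "t")
  tbl <- icc_table(co)
  expect_setequal(unique(tbl$unit[tbl$comparison == "within"]),
                  c("GE", "Philips", "Toshiba"))
  expect_setequal(unique(tbl$unit[tbl$comparison == "between"]),
                  c("GE-Philips", "GE-Toshiba", "Philips-Toshiba", "all"))
  expect_true(all(tbl$model[tbl$comparison == "within"] ==
                    "absolute_agreement"))
  expect_true(all(tbl$model[tbl$comparison == "between"] ==
                    "consistency"))
  expect_true(all(tbl$icc >= tbl$ci_low - 1e-12 &
                    tbl$icc <= tbl$ci_high + 1e-12))
})
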
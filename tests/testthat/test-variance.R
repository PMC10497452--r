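test_that("SEM and SDC arithmetic follow their definitions", {
  vc <- structure(list(sigma2_subject = 1, sigma2_scanner = 0,
                       sigma2_interaction = 0, sigma2_residual = 4,
                       sigma2_scanner_main = 0, mean_volume = 200,
                       n_observations = 10, n_subjects = 5,
                       n_scanners = 2, n_runs = 2, method = "moments",
                       interaction = "fold_into_scanner",
                       truncated = FALSE),
                  class = "variance_components")
  expect_equal(sem_within(vc), 1.0)
  vc$sigma2_scanner <- 3; vc$sigma2_residual <- 1; vc$mean_volume <- 100
  expect_equal(sem_between(vc), 2.0)
  vc$sigma2_scanner <- 0
  expect_equal(sem_between(vc), sem_within(vc))
  vc$sigma2_residual <- 0
  expect_equal(sem_within(vc), 0)

  expect_equal(round(sdc_from_sem(5.25), 2), 14.55)
  expect_equal(round(sdc_from_sem(1.63), 2), 4.52)
  expect_equal(sdc_from_sem(0), 0)
  expect_error(sdc_from_sem(-1), class = "volagree_validation_error")
  expect_equal(sdc_from_sem(1), 1.96 * sqrt(2), tolerance = 1e-12)
})

test_that("all-equal data give zero components without error", {
  co <- tiny_cohort(volumes = rep(1000, 12))
  vc <- suppressWarnings(
    fit_variance_components(co, "tool", "thalamus"))
  expect_equal(vc$sigma2_subject, 0)
  expect_equal(vc$sigma2_scanner, 0)
  expect_equal(vc$sigma2_residual, 0)
  expect_equal(vc$mean_volume, 1000)
})

test_that("moments and REML agree on balanced data", {
  cfg <- synthetic_config(
    scanner_bias = data.frame(scanner_id = c("GE", "Philips", "Toshiba"),
                              structure = "brain",
                              bias = c(1.00, 0.98, 0.99)),
    interaction_cv = 0.01, tiv_cv = 0, seed = 31)
  d <- tibble::as_tibble(generate_cohort(cfg))
  d$lv <- log(d$volume)
  mom <- variance_components(d, value = lv, method = "moments")
  reml <- variance_components(d, value = lv, method = "reml")
  for (f in c("sigma2_subject", "sigma2_scanner", "sigma2_interaction",
              "sigma2_residual")) {
    expect_lt(abs(mom[[f]] - reml[[f]]), 1e-6,
              label = paste("|moments - REML|", f))
  }
})

test_that("a deleted run switches to REML with close estimates", {
  cfg <- synthetic_config(
    scanner_bias = data.frame(scanner_id = "GE", structure = "brain",
                              bias = 0.98),
    interaction_cv = 0.01, tiv_cv = 0, seed = 57)
  full <- tibble::as_tibble(generate_cohort(cfg))
  drop1 <- full[!(full$subject_id == "S01" & full$scanner_id == "GE" &
                    full$run == 2L), ]
  bal <- variance_components(full, method = "auto")
  unb <- variance_components(drop1, method = "auto")
  expect_equal(bal$method, "moments")
  expect_equal(unb$method, "reml")
  expect_equal(unb$sigma2_subject, bal$sigma2_subject, tolerance = 0.05)
  expect_equal(unb$sigma2_residual, bal$sigma2_residual, tolerance = 0.1)
})

test_that("moments on unbalanced data is refused", {
  co <- generate_cohort(preset_cohort_config(seed = 9), software = "t")
  expect_error(
    suppressWarnings(fit_variance_components(co, "t", "brain",
                                             method = "moments")),
    class = "volagree_config_error")
})

test_that("interaction policies repartition without losing variance", {
  cfg <- synthetic_config(interaction_cv = 0.02, tiv_cv = 0, seed = 13)
  d <- tibble::as_tibble(generate_cohort(cfg))
  fold <- variance_components(d, interaction = "fold_into_scanner")
  pool <- variance_components(d, interaction = "pool_into_residual")
  expect_equal(fold$sigma2_scanner,
               pool$sigma2_scanner + fold$sigma2_interaction,
               tolerance = 1e-12)
  expect_equal(pool$sigma2_residual,
               fold$sigma2_residual + fold$sigma2_interaction,
               tolerance = 1e-12)
  # between-scanner error budget is identical under both policies
  expect_equal(fold$sigma2_scanner + fold$sigma2_residual,
               pool$sigma2_scanner + pool$sigma2_residual,
               tolerance = 1e-12)
})

test_that("reliability summaries satisfy the structural identities", {
  co <- generate_cohort(preset_cohort_config(seed = 17), software = "t")
  rel <- summarize_reliability(co)
  expect_equal(nrow(rel), 11)
  expect_equal(rel$sdc_within_pct / rel$sem_within_pct,
               rep(1.96 * sqrt(2), nrow(rel)), tolerance = 1e-9)
  expect_equal(rel$sdc_between_pct / rel$sem_between_pct,
               rep(1.96 * sqrt(2), nrow(rel)), tolerance = 1e-9)
  expect_true(all(rel$sem_between_pct >= rel$sem_within_pct - 1e-12))
})

test_that("zero-bias cohorts give near-equal within and between SEM", {
  cfg <- synthetic_config(interaction_cv = 0, tiv_cv = 0, seed = 23)
  diffs <- vapply(1:20, function(i) {
    cfg$seed <- 400 + i
    co <- normalize_by_tiv(generate_cohort(cfg, software = "t"))
    vc <- fit_variance_components(co, "t", "brain")
    sem_between(vc) - sem_within(vc)
  }, numeric(1))
  # scanner variance is zero in truth; estimates are >= 0 by truncation
  expect_true(all(diffs >= -1e-12))
  expect_lt(mean(diffs), 0.25)
})

test_that("extreme cells are located correctly on a hand-built summary", {
  summ <- tibble::tibble(
    software = c("a", "b", "c"), structure = c("gm", "wm", "csf"),
    lesion_filled = FALSE, mean_volume = 1,
    sem_within_pct = c(0.5, 2.0, 1.0),
    sem_between_pct = c(1.5, 4.0, 2.0),
    sdc_within_pct = sdc_from_sem(c(0.5, 2.0, 1.0)),
    sdc_between_pct = sdc_from_sem(c(1.5, 4.0, 2.0)))
  ext <- reliability_extremes(summ)
  mn <- dplyr::filter(ext, metric == "sem_within_pct", which == "min")
  mx <- dplyr::filter(ext, metric == "sdc_between_pct", which == "max")
  expect_equal(mn$software, "a")
  expect_equal(mx$software, "b")
  expect_equal(mx$value, sdc_from_sem(4.0))
})
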
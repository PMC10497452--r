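test_that("volume tables round-trip through write and read", {
  co <- tiny_cohort(volumes = c(1200, 1210, 1190, 1205, 1198, 1202,
                                1201, 1211, 1189, 1204, 1199, 1203))
  path <- withr::local_tempfile(fileext = ".csv")
  write_volume_table(co, path)
  back <- read_volume_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co))
})

test_that("column mapping and delimiter options are honoured", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::as_tibble(co)
  names(df)[names(df) == "volume"] <- "vol"
  names(df)[names(df) == "tiv"] <- "icv"
  readr::write_tsv(df, path, progress = FALSE)
  back <- read_volume_table(path, delim = "\t",
                            col_map = c(volume = "vol", tiv = "icv"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co))
  expect_error(read_volume_table(path, delim = "\t"),
               class = "volagree_config_error")
})

test_that("validation rejects duplicates, bad volumes, unknown structures", {
  df <- tibble::as_tibble(tiny_cohort())
  expect_error(as_cohort(dplyr::bind_rows(df, df[1, ])),
               "Duplicate", class = "volagree_validation_error")
  bad <- df; bad$volume[4] <- -5
  expect_error(as_cohort(bad), "row", class = "volagree_validation_error")
  bad <- df; bad$structure[1] <- "cerebellum"
  expect_error(as_cohort(bad), "Allowed",
               class = "volagree_validation_error")
  bad <- df; bad$volume[2] <- bad$tiv[2] * 1.1
  expect_error(as_cohort(bad), "TIV", class = "volagree_validation_error")
})

test_that("TIV normalization divides, flags, and refuses to run twice", {
  df <- tiny_cohort()
  df$volume[1] <- 1200; df$tiv <- 1500
  nrm <- normalize_by_tiv(df)
  expect_equal(nrm$volume[1], 0.8)
  expect_true(is_normalized(nrm))
  expect_error(normalize_by_tiv(nrm), class = "volagree_state_error")
})

test_that("exclusions drop matching acquisitions and log misses", {
  co <- tiny_cohort()
  out <- exclude_records(co, tibble::tibble(
    subject_id = "s1", scanner_id = "A", run = 2L))
  expect_equal(nrow(out), nrow(co) - 1L)
  expect_equal(attr(out, "exclusion_log")$n_removed, 1L)
  # s1 contributes only run 1 on scanner A
  left <- dplyr::filter(tibble::as_tibble(out), subject_id == "s1",
                        scanner_id == "A")
  expect_equal(left$run, 1L)
  expect_warning(
    exclude_records(co, tibble::tibble(subject_id = "nobody",
                                       scanner_id = "A", run = 1L)),
    "matched no records")
  expect_identical(exclude_records(co, NULL), co)
})

test_that("ratings matrices have the design shapes and drop accounting", {
  co <- generate_cohort(preset_cohort_config(seed = 3), software = "t")
  m_ge <- pivot_ratings(co, "t", "brain", "within", scanner = "GE")
  expect_equal(dim(m_ge), c(20L, 2L))
  expect_equal(attr(m_ge, "dropped_subjects"), 1L)
  m_ph <- pivot_ratings(co, "t", "brain", "within", scanner = "Philips")
  expect_equal(dim(m_ph), c(21L, 2L))
  m_pair <- pivot_ratings(co, "t", "brain", "between",
                          scanners = c("GE", "Philips"))
  expect_equal(dim(m_pair), c(21L, 2L))
  m_all <- pivot_ratings(co, "t", "brain", "between")
  expect_equal(dim(m_all), c(21L, 3L))
  design_n <- length(cohort_design_of(co)$subjects)
  for (m in list(m_ge, m_ph, m_pair, m_all)) {
    expect_equal(nrow(m) + attr(m, "dropped_subjects"), design_n)
  }
})

test_that("excluding all runs of a scanner shrinks pairwise matrices", {
  co <- generate_cohort(preset_cohort_config(seed = 3), software = "t")
  excl <- tidyr::expand_grid(subject_id = "S05", scanner_id = "Toshiba",
                             run = 1:2)
  out <- exclude_records(co, excl)
  m <- pivot_ratings(out, "t", "brain", "between",
                     scanners = c("GE", "Toshiba"))
  expect_equal(nrow(m), 20L)
  expect_false("S05" %in% rownames(m))
  # a pair not involving the excluded scanner is untouched
  m2 <- pivot_ratings(out, "t", "brain", "between",
                      scanners = c("GE", "Philips"))
  expect_equal(nrow(m2), 21L)
})

test_that("insufficient complete subjects is an error", {
  co <- tiny_cohort()
  out <- suppressWarnings(exclude_records(co, tibble::tibble(
    subject_id = c("s1", "s2"), scanner_id = "A", run = 2L)))
  expect_error(pivot_ratings(out, "tool", "thalamus", "within",
                             scanner = "A"),
               class = "volagree_insufficient_data_error")
})

test_that("percent-of-mean reliability is invariant to global rescaling", {
  co <- generate_cohort(synthetic_config(
    n_subjects = 8, scanners = c("A", "B"), seed = 11,
    scanner_bias = data.frame(scanner_id = "B", structure = "brain",
                              bias = 0.99),
    interaction_cv = 0.004), software = "t")
  scaled <- tibble::as_tibble(co)
  scaled$volume <- scaled$volume * 3.7
  scaled$tiv <- scaled$tiv * 3.7
  scaled <- as_cohort(scaled)
  r1 <- summarize_reliability(co)
  r2 <- summarize_reliability(scaled)
  cols <- c("sem_within_pct", "sem_between_pct",
            "sdc_within_pct", "sdc_between_pct")
  expect_equal(r1[cols], r2[cols], tolerance = 1e-10)
})
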
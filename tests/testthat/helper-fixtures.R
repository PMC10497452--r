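# Deterministic fixtures and frozen oracle values. The ICC expectations
# were computed with an independent reference (pingouin 0.6.1 point
# estimates; scipy F-distribution arithmetic for the CIs); the
# Bland-Altman expectations with independent numpy spreadsheet-style
# arithmetic. All frozen before the implementation was run against them.

icc_fixture_matrix <- function() {
  matrix(c(10.2, 10.8, 10.5,
           12.1, 12.6, 12.9,
           9.4, 9.9, 9.1,
           14.0, 14.5, 14.8,
           11.3, 11.1, 11.9,
           8.7, 9.2, 8.9,
           13.2, 13.9, 13.4,
           10.9, 11.4, 11.7,
           12.8, 12.5, 13.1,
           9.8, 10.3, 10.1),
         ncol = 3, byrow = TRUE)
}

icc_fixture_expected <- list(
  ms = list(msr = 9.723703703703702, msc = 0.5079999999999989,
            mse = 0.08392592592592604),
  absolute = list(icc = 0.9621710343909768,
                  ci_low = 0.8681662962686904,
                  ci_high = 0.9902354001064654),
  consistency = list(icc = 0.9745461897915167,
                     ci_low = 0.927806226434024,
                     ci_high = 0.9930371103957117))

ba_fixture <- function() {
  cbind(A = c(101.5, 98.2, 110.4, 95.7, 103.3, 99.8, 107.1, 94.6),
        B = c(99.0, 97.5, 108.8, 96.9, 101.1, 98.2, 104.9, 95.5))
}

ba_fixture_expected <- list(
  bias = 1.0874999999999986,
  sd_diff = 1.4307215961584867,
  loa_low = -1.7167143284706352,
  loa_high = 3.8917143284706324,
  ci_bias = c(-0.10861318741595083, 2.283613187415948),
  ci_loa_low = c(-3.854781288675335, 0.4213526317340648),
  ci_loa_high = c(1.7536473682659324, 6.029781288675332),
  slope = 0.1919717723839585,
  slope_p = 0.0718943161560041)

# small hand-buildable cohort: 3 subjects x 2 scanners x 2 runs, 1 structure
tiny_cohort <- function(volumes = NULL, tiv = 1500) {
  grid <- expand.grid(subject_id = c("s1", "s2", "s3"),
                      scanner_id = c("A", "B"), run = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$software <- "tool"
  grid$structure <- "thalamus"
  grid$lesion_filled <- FALSE
  grid$volume <- volumes %||% (10 + seq_len(nrow(grid)))
  grid$tiv <- tiv
  as_cohort(grid)
}

# run the shipped Python reference implementation on a list of matrices
run_icc_oracle <- function(mats, alpha = 0.05) {
  script <- system.file("oracle", "icc_reference.py", package = "volagree")
  stopifnot(nzchar(script))
  long <- purrr::imap_dfr(mats, function(m, i) {
    tibble::tibble(matrix_id = i,
                   subject = rep(seq_len(nrow(m)), times = ncol(m)),
                   rater = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  })
  inp <- tempfile(fileext = ".csv"); outp <- tempfile(fileext = ".csv")
  readr::write_csv(long, inp, progress = FALSE)
  status <- system2("python", c(script, inp, outp, alpha),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  readr::read_csv(outp, show_col_types = FALSE, progress = FALSE)
}
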
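# Synthetic scan-rescan cohorts with the statistical structure the
# reliability analysis assumes: multiplicative subject variation, fixed
# per-scanner biases, subject-by-scanner interaction, replicate noise.

#' Configure a synthetic scan-rescan cohort
#'
#' The generative model is multiplicative (lognormal): for subject i,
#' scanner j, run r and structure s,
#' `volume = mean_s * subj_i * bias_js * inter_ij * noise_ijr`,
#' where `subj`, `inter` and `noise` are lognormal with unit mean and
#' coefficients of variation `subject_cv`, `interaction_cv` and
#' `residual_cv`, and `bias_js` is a fixed multiplicative scanner bias
#' (e.g. 0.97 = 3% low). TIV is drawn once per subject (true anatomy) and
#' is constant across scanners and runs. Structure volumes scale with the
#' subject's head size as `(tiv_i / tiv_mean)^tiv_scaling` (default
#' exponent 1), so TIV-normalization removes head-size variation and
#' `subject_cv` is the between-subject variation that remains after
#' normalization.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param scanners Character vector of scanner ids.
#' @param n_runs Number of runs (scan, rescan, ...) per scanner.
#' @param structures Data frame with columns `structure`, `mean_volume`
#'   (mm^3) and `subject_cv` (between-subject coefficient of variation).
#' @param scanner_bias Data frame with columns `scanner_id`, `structure`,
#'   `bias` (multiplicative); unspecified combinations default to 1.
#' @param residual_cv Replicate (scan-rescan) coefficient of variation:
#'   a single number or a vector named by structure.
#' @param interaction_cv Subject-by-scanner coefficient of variation.
#' @param tiv_mean,tiv_cv Mean and coefficient of variation of
#'   intracranial volume (mm^3).
#' @param tiv_scaling Allometric exponent coupling structure volumes to
#'   head size (default 1 = proportional scaling; 0 decouples them).
#' @param missing Data frame with columns `subject`, `scanner_id`, `run`
#'   listing acquisitions to omit (`subject` is the 1-based subject index).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @return A list with class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects = 21,
                             scanners = c("GE", "Philips", "Toshiba"),
                             n_runs = 2,
                             structures = tibble::tibble(
                               structure = "brain",
                               mean_volume = 1.05e6,
                               subject_cv = 0.046),
                             scanner_bias = NULL,
                             residual_cv = 0.005,
                             interaction_cv = 0,
                             tiv_mean = 1.5e6,
                             tiv_cv = 0.04,
                             tiv_scaling = 1,
                             missing = NULL,
                             seed = 1L) {
  if (n_subjects < 3) {
    abort("n_subjects must be at least 3.", class = "volagree_config_error")
  }
  structures <- tibble::as_tibble(structures)
  stopifnot(all(c("structure", "mean_volume", "subject_cv") %in%
                  names(structures)))
  cvs <- c(structures$subject_cv, unname(residual_cv), interaction_cv, tiv_cv)
  if (any(cvs < 0)) {
    abort("Coefficients of variation must be non-negative.",
          class = "volagree_config_error")
  }
  if (any(structures$mean_volume <= 0) || tiv_mean <= 0) {
    abort("Mean volumes must be positive.", class = "volagree_config_error")
  }
  if (!is.null(scanner_bias)) {
    scanner_bias <- tibble::as_tibble(scanner_bias)
    stopifnot(all(c("scanner_id", "structure", "bias") %in%
                    names(scanner_bias)))
    if (any(scanner_bias$bias <= 0)) {
      abort("Scanner biases must be positive.",
            class = "volagree_config_error")
    }
  }
  if (!is.null(missing)) {
    missing <- tibble::as_tibble(missing)
    stopifnot(all(c("subject", "scanner_id", "run") %in% names(missing)))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         scanners = as.character(scanners),
         n_runs = as.integer(n_runs),
         structures = structures,
         scanner_bias = scanner_bias,
         residual_cv = residual_cv,
         interaction_cv = interaction_cv,
         tiv_mean = tiv_mean, tiv_cv = tiv_cv,
         tiv_scaling = tiv_scaling,
         missing = missing,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Preset configuration mirroring a 21-subject three-scanner MS study
#'
#' 21 subjects scanned twice on each of three 3T scanners (GE, Philips,
#' Toshiba), 11 structures (whole brain, GM, WM, CSF and seven bilateral
#' deep grey matter structures), one rescan lost to motion (subject 1, GE,
#' run 2), and systematic GE biases in the tissue classes: GM segmented
#' high (+2%) and WM segmented low (-3%) on GE relative to the other
#' vendors. Structure means are plausible adult values; the between-subject
#' CV of 4.6% is back-calculated from published between-scanner sample-size
#' requirements (see the methods vignette); bias magnitudes are free
#' parameters of the generator, with only their direction anchored to
#' published findings.
#'
#' @param seed Integer seed passed through to [synthetic_config()].
#' @return A `"synthetic_config"`.
#' @export
preset_cohort_config <- function(seed = 1L) {
  structures <- tibble::tribble(
    ~structure,    ~mean_volume, ~subject_cv,
    "brain",        1.05e6,       0.046,
    "gm",           6.0e5,        0.046,
    "wm",           4.2e5,        0.046,
    "csf",          3.3e5,        0.046,
    "thalamus",     1.55e4,       0.046,
    "putamen",      1.00e4,       0.046,
    "hippocampus",  8.8e3,        0.046,
    "caudate",      7.6e3,        0.046,
    "pallidum",     3.7e3,        0.046,
    "amygdala",     3.0e3,        0.046,
    "accumbens",    1.0e3,        0.046)
  residual_cv <- c(brain = 0.005, gm = 0.006, wm = 0.007, csf = 0.020,
                   thalamus = 0.012, putamen = 0.015, hippocampus = 0.015,
                   caudate = 0.015, pallidum = 0.020, amygdala = 0.025,
                   accumbens = 0.030)
  scanner_bias <- tibble::tribble(
    ~scanner_id, ~structure, ~bias,
    "GE",        "gm",       1.02,
    "GE",        "wm",       0.97)
  synthetic_config(
    n_subjects = 21,
    scanners = c("GE", "Philips", "Toshiba"),
    n_runs = 2,
    structures = structures,
    scanner_bias = scanner_bias,
    residual_cv = residual_cv,
    interaction_cv = 0.005,
    tiv_mean = 1.5e6, tiv_cv = 0.04,
    missing = tibble::tibble(subject = 1L, scanner_id = "GE", run = 2L),
    seed = seed)
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}

#' Generate a synthetic cohort table
#'
#' Draws one cohort from the model described in [synthetic_config()].
#' A fixed seed yields bit-identical output; the global RNG state is
#' restored on exit.
#'
#' @param config A `"synthetic_config"`.
#' @param software Software label stamped on the records (the generator
#'   models one segmentation tool at a time).
#' @param lesion_filled Lesion-filled flag stamped on the records.
#' @return A cohort table ([as_cohort()]).
#' @export
generate_cohort <- function(config, software = "synthetic",
                            lesion_filled = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  scanners <- config$scanners
  runs <- seq_len(config$n_runs)
  structs <- config$structures

  tiv <- config$tiv_mean * lognormal_factor(n, config$tiv_cv)
  names(tiv) <- subjects

  res_cv_for <- function(s) {
    rc <- config$residual_cv
    if (is.null(names(rc))) rc[[1]] else unname(rc[[s]] %||% 0)
  }
  bias_for <- function(scanner, s) {
    sb <- config$scanner_bias
    if (is.null(sb)) return(1)
    hit <- sb$bias[sb$scanner_id == scanner & sb$structure == s]
    if (length(hit) == 0) 1 else hit[[1]]
  }

  head_size <- (tiv / config$tiv_mean)^(config$tiv_scaling %||% 1)

  pieces <- lapply(seq_len(nrow(structs)), function(si) {
    s <- structs$structure[si]
    subj_eff <- head_size * lognormal_factor(n, structs$subject_cv[si])
    inter <- matrix(lognormal_factor(n * length(scanners),
                                     config$interaction_cv),
                    nrow = n)
    grid <- expand.grid(subject_id = subjects, scanner_id = scanners,
                        run = runs, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    i <- match(grid$subject_id, subjects)
    j <- match(grid$scanner_id, scanners)
    noise <- lognormal_factor(nrow(grid), res_cv_for(s))
    bias <- vapply(scanners, bias_for, numeric(1), s = s)
    grid$volume <- structs$mean_volume[si] * subj_eff[i] * bias[j] *
      inter[cbind(i, j)] * noise
    grid$structure <- s
    grid$tiv <- tiv[grid$subject_id]
    grid
  })
  df <- dplyr::bind_rows(pieces)
  df$software <- software
  df$lesion_filled <- lesion_filled
  df$run <- as.integer(df$run)

  if (!is.null(config$missing) && nrow(config$missing) > 0) {
    miss_key <- paste(subjects[config$missing$subject],
                      config$missing$scanner_id, config$missing$run,
                      sep = "|")
    df <- df[!(paste(df$subject_id, df$scanner_id, df$run, sep = "|") %in%
                 miss_key), , drop = FALSE]
  }

  design <- cohort_design(subjects = subjects, scanners = scanners,
                          runs = runs, software = software,
                          structures = structs$structure)
  as_cohort(df, design = design)
}
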
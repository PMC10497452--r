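# Crossed variance-component decomposition per (software, structure) cell:
# value_ijr = mu + subject_i + scanner_j + (subject x scanner)_ij + e_ijr.
# Balanced designs use method-of-moments via expected mean squares; designs
# with missing runs use REML (lme4). SEM/SDC are derived as % of the mean.

SDC_FACTOR <- 1.96 * sqrt(2)

#' Estimate crossed variance components from a long data frame
#'
#' Lower-level fitter used by [fit_variance_components()]; takes any long
#' data frame (so it can equally be applied to, e.g., log-volumes in
#' simulation studies). The model is a two-way crossed random-effects
#' layout with replicates: subject, scanner, subject-by-scanner
#' interaction, residual.
#'
#' The reported scanner component depends on the `interaction` policy:
#' `"fold_into_scanner"` (default) reports `var(scanner) +
#' var(interaction)` as the scanner term, since both contribute to
#' between-scanner but not within-scanner error; `"pool_into_residual"`
#' adds the interaction to the residual; `"drop"` refits without an
#' interaction term.
#'
#' @param data Data frame with one measurement per row.
#' @param value,subject,scanner,run Column names (unquoted) of the
#'   measurement, subject id, scanner id and run index.
#' @param method `"auto"` (moments when balanced, REML otherwise),
#'   `"moments"`, or `"reml"`.
#' @param interaction Interaction-handling policy (see Details).
#' @return A `"variance_components"` object: `sigma2_subject`,
#'   `sigma2_scanner`, `sigma2_interaction`, `sigma2_residual`,
#'   `mean_volume`, `n_observations`, `method`, `truncated`.
#' @export
variance_components <- function(data, value = volume, subject = subject_id,
                                scanner = scanner_id, run = run,
                                method = c("auto", "moments", "reml"),
                                interaction = c("fold_into_scanner",
                                                "pool_into_residual",
                                                "drop")) {
  method <- match.arg(method)
  interaction <- match.arg(interaction)
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    subj = as.character(dplyr::pull(data, {{ subject }})),
    scan = as.character(dplyr::pull(data, {{ scanner }})),
    run = dplyr::pull(data, {{ run }}))
  n <- length(unique(d$subj)); k <- length(unique(d$scan))
  if (n < 3 || k < 2) {
    abort(sprintf("Need >= 3 subjects and >= 2 scanners (got %d, %d).",
                  n, k),
          class = "volagree_insufficient_data_error")
  }
  cell_sizes <- table(d$subj, d$scan)
  m <- max(cell_sizes)
  if (m < 2) {
    abort("Need >= 2 runs in at least one subject-scanner cell.",
          class = "volagree_insufficient_data_error")
  }
  balanced <- length(unique(as.vector(cell_sizes))) == 1 &&
    all(cell_sizes > 0)
  if (method == "moments" && !balanced) {
    abort("Method-of-moments requires a balanced design; use REML.",
          class = "volagree_config_error")
  }
  if (method == "auto") method <- if (balanced) "moments" else "reml"

  if (method == "moments") {
    est <- vc_moments(d, n, k, m, interaction)
  } else {
    est <- vc_reml(d, interaction)
  }
  truncated <- any(unlist(est[c("s", "r", "i", "e")]) < 0, na.rm = TRUE)
  clamp <- function(x) if (is.na(x)) x else max(x, 0)
  s2_s <- clamp(est$s); s2_r <- clamp(est$r)
  s2_i <- clamp(est$i); s2_e <- clamp(est$e)
  if (interaction == "fold_into_scanner" && !is.na(s2_i)) {
    scanner_rep <- s2_r + s2_i
    resid_rep <- s2_e
  } else if (interaction == "pool_into_residual" && !is.na(s2_i)) {
    scanner_rep <- s2_r
    resid_rep <- s2_e + s2_i
  } else {
    scanner_rep <- s2_r
    resid_rep <- s2_e
  }
  structure(
    list(sigma2_subject = s2_s, sigma2_scanner = scanner_rep,
         sigma2_interaction = s2_i, sigma2_residual = resid_rep,
         sigma2_scanner_main = s2_r,
         mean_volume = mean(d$y), n_observations = nrow(d),
         n_subjects = n, n_scanners = k, n_runs = m,
         method = method, interaction = interaction,
         truncated = truncated),
    class = "variance_components")
}

vc_moments <- function(d, n, k, m, interaction) {
  gm <- mean(d$y)
  sm <- tapply(d$y, d$subj, mean)
  cm <- tapply(d$y, d$scan, mean)
  icm <- tapply(d$y, list(d$subj, d$scan), mean)
  mss <- k * m * sum((sm - gm)^2) / (n - 1)
  msr <- n * m * sum((cm - gm)^2) / (k - 1)
  ss_int <- m * sum((icm - outer(sm, rep(1, k)) -
                       outer(rep(1, n), cm) + gm)^2)
  msi <- ss_int / ((n - 1) * (k - 1))
  sse <- sum((d$y - icm[cbind(d$subj, d$scan)])^2)
  mse <- sse / (n * k * (m - 1))
  if (interaction == "drop") {
    mse_pooled <- (ss_int + sse) / ((n - 1) * (k - 1) + n * k * (m - 1))
    list(s = (mss - mse_pooled) / (k * m),
         r = (msr - mse_pooled) / (n * m),
         i = NA_real_, e = mse_pooled)
  } else {
    list(s = (mss - msi) / (k * m),
         r = (msr - msi) / (n * m),
         i = (msi - mse) / m, e = mse)
  }
}

vc_reml <- function(d, interaction) {
  form <- if (interaction == "drop") {
    y ~ 1 + (1 | subj) + (1 | scan)
  } else {
    y ~ 1 + (1 | subj) + (1 | scan) + (1 | subj:scan)
  }
  fit <- lme4::lmer(form, data = d, control = lme4::lmerControl(
    optimizer = "bobyqa", calc.derivs = FALSE,
    optCtrl = list(rhobeg = 0.2, rhoend = 1e-12),
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  list(s = unname(v[["subj"]]), r = unname(v[["scan"]]),
       i = if (interaction == "drop") NA_real_
       else unname(v[["subj:scan"]]),
       e = unname(v[["Residual"]]))
}

#' Fit variance components for one (software, structure) cell of a cohort
#'
#' Convention: the decomposition runs on TIV-normalized volumes; a warning
#' is issued when the table is raw (override by normalizing first or pass
#' raw values deliberately).
#'
#' @param table A cohort table.
#' @param software,structure Cell selectors.
#' @param lesion_filled Lesion-filled flag to select (default `FALSE`).
#' @inheritParams variance_components
#' @return A `"variance_components"` object.
#' @export
fit_variance_components <- function(table, software, structure,
                                    lesion_filled = FALSE,
                                    method = c("auto", "moments", "reml"),
                                    interaction = c("fold_into_scanner",
                                                    "pool_into_residual",
                                                    "drop")) {
  if (!is_normalized(table)) {
    warn(paste("Fitting variance components on raw volumes;",
               "SEM/SDC are conventionally derived from TIV-normalized",
               "volumes."))
  }
  df <- dplyr::filter(tibble::as_tibble(table),
                      .data$software == !!software,
                      .data$structure == !!structure,
                      .data$lesion_filled == !!lesion_filled)
  if (nrow(df) == 0) {
    abort(sprintf("No records for software '%s', structure '%s'.",
                  software, structure),
          class = "volagree_validation_error")
  }
  variance_components(df, method = method, interaction = interaction)
}

#' Within-scanner standard error of measurement (% of mean)
#'
#' `100 * sqrt(sigma2_residual) / mean`: the scan-rescan (replicate) error
#' alone.
#'
#' @param vc A `"variance_components"` object.
#' @return SEM_within as a percentage of the mean.
#' @export
sem_within <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$mean_volume <= 0) {
    abort("Mean volume must be positive.",
          class = "volagree_validation_error")
  }
  100 * sqrt(vc$sigma2_residual) / vc$mean_volume
}

#' Between-scanner standard error of measurement (% of mean)
#'
#' `100 * sqrt(sigma2_scanner + sigma2_residual) / mean`: replicate error
#' plus the scanner-associated variance (scanner main effect and, under
#' the default policy, the subject-by-scanner interaction).
#'
#' @inheritParams sem_within
#' @return SEM_between as a percentage of the mean.
#' @export
sem_between <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$mean_volume <= 0) {
    abort("Mean volume must be positive.",
          class = "volagree_validation_error")
  }
  100 * sqrt(vc$sigma2_scanner + vc$sigma2_residual) / vc$mean_volume
}

#' Smallest detectable change from an SEM
#'
#' `SDC = 1.96 * sqrt(2) * SEM`: the smallest change in one subject
#' distinguishable from measurement error with 95% confidence (the factor
#' sqrt(2) accounts for the error entering both measurements).
#'
#' @param sem_pct SEM as a percentage of the mean (>= 0).
#' @return SDC on the same percentage scale.
#' @export
sdc_from_sem <- function(sem_pct) {
  if (any(sem_pct < 0)) {
    abort("SEM must be non-negative.", class = "volagree_validation_error")
  }
  SDC_FACTOR * sem_pct
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s, interaction: %s)%s\n",
    x$method, x$interaction, if (x$truncated) " [truncated at 0]" else ""))
  cat(sprintf("  subject   %.6g\n  scanner   %.6g\n", x$sigma2_subject,
              x$sigma2_scanner))
  if (!is.na(x$sigma2_interaction))
    cat(sprintf("  (interaction %.6g, reported per policy)\n",
                x$sigma2_interaction))
  cat(sprintf("  residual  %.6g\n  mean      %.6g  (N = %d)\n",
              x$sigma2_residual, x$mean_volume, x$n_observations))
  invisible(x)
}

#' @rdname tidy_volagree
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(
    component = c("subject", "scanner", "interaction", "residual"),
    variance = c(x$sigma2_subject, x$sigma2_scanner_main,
                 x$sigma2_interaction, x$sigma2_residual))
}

#' @rdname tidy_volagree
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(mean_volume = x$mean_volume,
                 n_observations = x$n_observations,
                 n_subjects = x$n_subjects, n_scanners = x$n_scanners,
                 method = x$method, truncated = x$truncated)
}

#' Reliability summary: SEM and SDC per (software, structure)
#'
#' Fits the crossed variance decomposition for every (software, structure,
#' lesion-filled) cell and derives `sem_within_pct`, `sem_between_pct`,
#' `sdc_within_pct`, `sdc_between_pct`, all as percentages of the cell
#' mean. A raw table is TIV-normalized internally first (the convention
#' for these statistics); percent-of-mean output is invariant to global
#' rescaling either way.
#'
#' @param table A cohort table.
#' @inheritParams variance_components
#' @return A tibble, one row per cell, with the four reliability columns
#'   plus `mean_volume` and `method`.
#' @export
summarize_reliability <- function(table,
                                  method = c("auto", "moments", "reml"),
                                  interaction = c("fold_into_scanner",
                                                  "pool_into_residual",
                                                  "drop")) {
  method <- match.arg(method); interaction <- match.arg(interaction)
  if (!is_normalized(table)) table <- normalize_by_tiv(table)
  cells <- dplyr::distinct(tibble::as_tibble(table),
                           .data$software, .data$structure,
                           .data$lesion_filled)
  purrr::pmap_dfr(cells, function(software, structure, lesion_filled) {
    vc <- fit_variance_components(table, software, structure,
                                  lesion_filled, method = method,
                                  interaction = interaction)
    sw <- sem_within(vc); sb <- sem_between(vc)
    tibble::tibble(software = software, structure = structure,
                   lesion_filled = lesion_filled,
                   mean_volume = vc$mean_volume,
                   sem_within_pct = sw, sem_between_pct = sb,
                   sdc_within_pct = sdc_from_sem(sw),
                   sdc_between_pct = sdc_from_sem(sb),
                   method = vc$method)
  })
}

#' Extreme cells of a reliability summary
#'
#' Reports, for each reliability metric, the (software, structure) cells
#' attaining the minimum and maximum — the usual way the overall range of
#' measurement error is quoted.
#'
#' @param summary Output of [summarize_reliability()].
#' @return A tibble with columns `metric`, `which` (min/max), `software`,
#'   `structure`, `value`.
#' @export
reliability_extremes <- function(summary) {
  metrics <- c("sem_within_pct", "sem_between_pct",
               "sdc_within_pct", "sdc_between_pct")
  purrr::map_dfr(metrics, function(mt) {
    v <- summary[[mt]]
    idx <- c(min = which.min(v), max = which.max(v))
    tibble::tibble(metric = mt, which = names(idx),
                   software = summary$software[idx],
                   structure = summary$structure[idx],
                   value = v[idx])
  })
}
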
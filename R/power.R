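# Two-sample power planning: minimum per-group n to detect a stated
# percent volume difference, contrasting within-scanner with
# between-scanner measurement variance.

#' Exact power of the two-sided two-sample t-test
#'
#' Noncentral-t power at per-group size `n`, effect `delta`, common SD
#' `total_sd` (any consistent units; percentages of the mean here).
#'
#' @param n Per-group sample size (>= 2).
#' @param total_sd Common standard deviation.
#' @param delta Group difference to detect.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_group <- function(n, total_sd, delta, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (total_sd * sqrt(2 / n))
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp)
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group such that a two-sided, equal-variance
#' two-sample t-test reaches the requested power, found by iterating the
#' noncentral-t power expression (the z-approximation is available as a
#' cheaper alternative; it understates n slightly at small sizes).
#' The search floor is n = 2.
#'
#' @param total_sd_pct Total SD of the measurement, as % of the mean
#'   (> 0).
#' @param delta_pct Group difference to detect, as % of the mean
#'   (default 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param method `"noncentral_t"` (default) or `"normal_approx"`.
#' @return Integer sample size per group.
#' @export
sample_size_two_group <- function(total_sd_pct, delta_pct = 1,
                                  alpha = 0.05, power = 0.80,
                                  method = c("noncentral_t",
                                             "normal_approx")) {
  method <- match.arg(method)
  if (total_sd_pct <= 0) {
    abort("Total SD must be positive.", class = "volagree_config_error")
  }
  stopifnot(delta_pct > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n_z <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 *
    (total_sd_pct / delta_pct)^2
  if (method == "normal_approx") return(max(2L, as.integer(ceiling(n_z))))
  n <- max(2L, as.integer(floor(n_z)) - 2L)
  while (power_two_group(n, total_sd_pct, delta_pct, alpha) < power) {
    n <- n + 1L
  }
  while (n > 2L &&
         power_two_group(n - 1L, total_sd_pct, delta_pct, alpha) >= power) {
    n <- n - 1L
  }
  n
}

#' Within- vs between-scanner sample sizes from variance components
#'
#' For a stated percent group difference, the per-group n under
#' within-scanner measurement (total variance = subject + residual) and
#' under between-scanner measurement (subject + scanner + residual), with
#' their ratio. The subject variance comes from the fitted decomposition
#' unless `subject_cv_pct` overrides it.
#'
#' @param vc A `"variance_components"` object (fitted on normalized
#'   volumes by convention).
#' @param delta_pct,alpha,power Power specification (defaults: detect a
#'   1% difference at alpha 0.05 with 80% power).
#' @param subject_cv_pct Optional override of the between-subject SD as %
#'   of the mean.
#' @return A `"power_result"`: `n_within`, `n_between`, `ratio`
#'   (n_between / n_within from the integer sizes), and
#'   `variance_ratio` (the continuous between/within total-variance
#'   ratio).
#' @export
power_pair <- function(vc, delta_pct = 1, alpha = 0.05, power = 0.80,
                       subject_cv_pct = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  vbar <- vc$mean_volume
  s2_subj_pct <- if (!is.null(subject_cv_pct)) subject_cv_pct^2
  else 1e4 * vc$sigma2_subject / vbar^2
  s2_scan_pct <- 1e4 * vc$sigma2_scanner / vbar^2
  s2_res_pct <- 1e4 * vc$sigma2_residual / vbar^2
  within_var <- s2_subj_pct + s2_res_pct
  between_var <- s2_subj_pct + s2_scan_pct + s2_res_pct
  if (within_var <= 0) {
    abort("Zero total variance: sample size undefined.",
          class = "volagree_validation_error")
  }
  n_within <- sample_size_two_group(sqrt(within_var), delta_pct, alpha,
                                    power)
  n_between <- sample_size_two_group(sqrt(between_var), delta_pct, alpha,
                                     power)
  structure(
    list(n_within = n_within, n_between = n_between,
         ratio = n_between / n_within,
         variance_ratio = between_var / within_var,
         delta_pct = delta_pct, alpha = alpha, power = power,
         subject_sd_pct = sqrt(s2_subj_pct)),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "n per group to detect %.3g%% difference (alpha %.3g, power %.3g):\n",
    x$delta_pct, x$alpha, x$power))
  cat(sprintf("  within-scanner  %d\n  between-scanner %d  (ratio %.2f)\n",
              x$n_within, x$n_between, x$ratio))
  invisible(x)
}

#' @rdname tidy_volagree
#' @method tidy power_result
#' @export
tidy.power_result <- function(x, ...) {
  tibble::tibble(n_within = x$n_within, n_between = x$n_between,
                 ratio = x$ratio, variance_ratio = x$variance_ratio,
                 delta_pct = x$delta_pct, alpha = x$alpha,
                 power = x$power)
}

#' Sample-size table across a cohort
#'
#' One [power_pair()] per (software, structure, lesion-filled) cell, the
#' per-cell participant-ratio matrix used to compare study designs.
#'
#' @param table A cohort table.
#' @inheritParams power_pair
#' @inheritParams variance_components
#' @return A tibble, one row per cell.
#' @export
power_table <- function(table, delta_pct = 1, alpha = 0.05, power = 0.80,
                        method = c("auto", "moments", "reml"),
                        interaction = c("fold_into_scanner",
                                        "pool_into_residual", "drop")) {
  method <- match.arg(method); interaction <- match.arg(interaction)
  if (!is_normalized(table)) table <- normalize_by_tiv(table)
  cells <- dplyr::distinct(tibble::as_tibble(table),
                           .data$software, .data$structure,
                           .data$lesion_filled)
  purrr::pmap_dfr(cells, function(software, structure, lesion_filled) {
    vc <- fit_variance_components(table, software, structure,
                                  lesion_filled, method = method,
                                  interaction = interaction)
    dplyr::bind_cols(
      tibble::tibble(software = software, structure = structure,
                     lesion_filled = lesion_filled),
      tidy(power_pair(vc, delta_pct, alpha, power)))
  })
}
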
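# Single-measurement intraclass correlation under the two-way random
# effects layout: ICC(A,1) for absolute agreement (scan-rescan within one
# scanner) and ICC(C,1) for consistency (first runs across scanners).
# Point estimates and F-based 95% CIs follow McGraw & Wong.

#' Two-way mean squares of a ratings matrix
#'
#' Decomposes an n x k matrix (rows = subjects, columns = raters) without
#' replication into row, column and residual mean squares. The sums of
#' squares are conserved: `(n-1) MSR + (k-1) MSC + (n-1)(k-1) MSE` equals
#' the total sum of squared deviations from the grand mean.
#'
#' @param m Numeric matrix, n >= 3 rows and k >= 2 columns, no missing
#'   cells.
#' @return A list with `msr`, `msc`, `mse`, `n`, `k`, `grand_mean`.
#' @export
two_way_mean_squares <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || anyNA(m)) {
    abort("Ratings must be a complete numeric matrix.",
          class = "volagree_validation_error")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) {
    abort(sprintf("Degenerate ratings matrix (%d x %d): need n >= 3, k >= 2.",
                  n, k),
          class = "volagree_insufficient_data_error")
  }
  gm <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k, grand_mean = gm)
}

new_icc_estimate <- function(model, value, ci_low, ci_high, alpha, ms,
                             dropped) {
  structure(
    list(model = model, value = value, ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, n = ms$n, k = ms$k,
         classification = classify_icc(value),
         dropped_subjects = dropped,
         msr = ms$msr, msc = ms$msc, mse = ms$mse),
    class = "icc_estimate")
}

dropped_of <- function(m) attr(m, "dropped_subjects") %||% 0L

#' Consistency ICC, single measurement
#'
#' `ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE)`: rater offsets do not
#' count as disagreement, so a fixed between-scanner shift leaves the
#' consistency ICC untouched. The 95% CI comes from the exact F ratio
#' `MSR/MSE` with `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param m Ratings matrix (see [pivot_ratings()]).
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return An `"icc_estimate"` object.
#' @export
icc_consistency <- function(m, alpha = 0.05) {
  ms <- two_way_mean_squares(m)
  denom <- ms$msr + (ms$k - 1) * ms$mse
  if (denom == 0) {
    abort("ICC undefined: all ratings identical (zero total variance).",
          class = "volagree_undefined_icc_error")
  }
  value <- (ms$msr - ms$mse) / denom
  n <- ms$n; k <- ms$k
  f_obs <- ms$msr / ms$mse
  fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci_low <- (fl - 1) / (fl + k - 1)
  ci_high <- (fu - 1) / (fu + k - 1)
  new_icc_estimate("consistency", value, ci_low, ci_high, alpha, ms,
                   dropped_of(m))
}

#' Absolute-agreement ICC, single measurement
#'
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`:
#' systematic rater (run or scanner) offsets enter the denominator, so
#' absolute agreement is penalized by fixed bias that consistency ignores.
#' The 95% CI uses the Satterthwaite-approximated F procedure.
#'
#' @inheritParams icc_consistency
#' @return An `"icc_estimate"` object.
#' @export
icc_absolute <- function(m, alpha = 0.05) {
  ms <- two_way_mean_squares(m)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)
  if (denom == 0) {
    abort("ICC undefined: zero denominator.",
          class = "volagree_undefined_icc_error")
  }
  value <- (ms$msr - ms$mse) / denom
  if (ms$msc == 0 && ms$mse == 0) {
    # identical columns: perfect agreement, no sampling uncertainty left
    return(new_icc_estimate("absolute_agreement", value, value, value,
                            alpha, ms, dropped_of(m)))
  }
  a <- k * value / (n * (1 - value))
  b <- 1 + k * value * (n - 1) / (n * (1 - value))
  nu <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f1 <- qf(1 - alpha / 2, n - 1, nu)
  f2 <- qf(1 - alpha / 2, nu, n - 1)
  ci_low <- n * (ms$msr - f1 * ms$mse) /
    (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  ci_high <- n * (f2 * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
  new_icc_estimate("absolute_agreement", value, ci_low, ci_high, alpha, ms,
                   dropped_of(m))
}

#' Classify ICC values
#'
#' Conventional reliability bands: below 0.5 poor, 0.5 to below 0.75
#' moderate, 0.75 to below 0.9 good, 0.9 and above excellent
#' (lower-inclusive boundaries). Negative estimates classify as poor.
#'
#' @param value Numeric vector of ICC values (each <= 1).
#' @return Character vector of classifications.
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  out <- rep("poor", length(value))
  out[value >= 0.5] <- "moderate"
  out[value >= 0.75] <- "good"
  out[value >= 0.9] <- "excellent"
  out
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.4f  %d%% CI [%.4f, %.4f]  (%s)\n",
              if (x$model == "consistency") "C" else "A",
              x$value, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$classification))
  cat(sprintf("  n = %d subjects, k = %d raters, %d dropped\n",
              x$n, x$k, x$dropped_subjects))
  invisible(x)
}

#' @rdname tidy_volagree
#' @method tidy icc_estimate
#' @export
tidy.icc_estimate <- function(x, ...) {
  tibble::tibble(model = x$model, icc = x$value, ci_low = x$ci_low,
                 ci_high = x$ci_high, classification = x$classification,
                 n = x$n, k = x$k, dropped_subjects = x$dropped_subjects)
}

#' @rdname tidy_volagree
#' @method glance icc_estimate
#' @export
glance.icc_estimate <- function(x, ...) {
  tibble::tibble(msr = x$msr, msc = x$msc, mse = x$mse, alpha = x$alpha)
}

scanner_pairs <- function(scanners) {
  utils::combn(scanners, 2, simplify = FALSE)
}

#' Tidy table of ICCs across a cohort
#'
#' Computes, for every (software, structure, lesion-filled) cell present in
#' the cohort: the within-scanner absolute-agreement ICC per scanner
#' (scan vs rescan), and/or the between-scanner consistency ICC on
#' first-run values for every scanner pair plus all scanners jointly.
#'
#' @param table A cohort table (raw volumes).
#' @param comparison `"within"`, `"between"`, or both (default).
#' @param alpha CI level is `1 - alpha`.
#' @param run_policy Passed to [pivot_ratings()] for between-scanner
#'   matrices.
#' @return A tibble with one row per ICC: `software`, `structure`,
#'   `lesion_filled`, `comparison`, `unit` (scanner, pair, or `"all"`),
#'   `model`, `icc`, `ci_low`, `ci_high`, `classification`, `n`, `k`,
#'   `dropped_subjects`.
#' @export
icc_table <- function(table, comparison = c("within", "between"),
                      alpha = 0.05, run_policy = "first") {
  comparison <- match.arg(comparison, several.ok = TRUE)
  design <- cohort_design_of(table)
  cells <- dplyr::distinct(tibble::as_tibble(table),
                           .data$software, .data$structure,
                           .data$lesion_filled)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sw <- cells$software[ci]; st <- cells$structure[ci]
    lf <- cells$lesion_filled[ci]
    if ("within" %in% comparison) {
      for (sc in design$scanners) {
        m <- pivot_ratings(table, sw, st, "within", scanner = sc,
                           lesion_filled = lf)
        est <- icc_absolute(m, alpha)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(software = sw, structure = st, lesion_filled = lf,
                         comparison = "within", unit = sc),
          tidy(est))
      }
    }
    if ("between" %in% comparison) {
      units <- c(scanner_pairs(design$scanners),
                 if (length(design$scanners) > 2) list(design$scanners))
      for (u in units) {
        m <- pivot_ratings(table, sw, st, "between", scanners = u,
                           run_policy = run_policy, lesion_filled = lf)
        est <- icc_consistency(m, alpha)
        label <- if (length(u) == length(design$scanners) &&
                     length(u) > 2) "all" else paste(u, collapse = "-")
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(software = sw, structure = st, lesion_filled = lf,
                         comparison = "between", unit = label),
          tidy(est))
      }
    }
  }
  dplyr::bind_rows(rows)
}
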
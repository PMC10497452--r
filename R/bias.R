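# Systematic between-scanner differences: omnibus repeated-measures test
# per (software, structure) cell with Bonferroni-corrected pairwise
# post-hocs, and Bland-Altman agreement statistics per scanner pair.

#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric (repeated-measures ANOVA, paired t) and
#' non-parametric (Friedman, Wilcoxon) branches. Returns `TRUE`
#' ("treat as normal") when Shapiro-Wilk does not reject at `alpha`.
#' A constant vector carries no evidence against normality and returns
#' `TRUE` with a warning.
#'
#' @param values Numeric vector (>= 3 values), typically within-subject
#'   residuals.
#' @param alpha Significance level of the normality test (default 0.05).
#' @return Logical scalar.
#' @export
check_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    abort("Need at least 3 values for a normality check.",
          class = "volagree_insufficient_data_error")
  }
  if (diff(range(values)) == 0) {
    warn("Constant values: normality test is undefined; assuming normal.")
    return(TRUE)
  }
  stats::shapiro.test(values)$p.value >= alpha
}

# Greenhouse-Geisser epsilon from the k x k covariance of the wide data.
gg_epsilon <- function(wide) {
  k <- ncol(wide)
  s <- stats::cov(wide)
  cmat <- diag(k) - 1 / k
  sd_ <- cmat %*% s %*% cmat
  lambda <- eigen(sd_, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  eps <- sum(lambda)^2 / ((k - 1) * sum(lambda^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Omnibus test of systematic scanner differences
#'
#' One-within-factor (scanner) repeated-measures analysis on complete-case
#' first-run values of one (software, structure) cell, on raw volumes by
#' convention. Normally distributed residuals (Shapiro-Wilk gate) give a
#' repeated-measures ANOVA with Greenhouse-Geisser-corrected p; otherwise
#' a Friedman test. Pairwise post-hocs (paired t or Wilcoxon signed-rank,
#' matching the omnibus branch) are Bonferroni-corrected over the scanner
#' pairs of the cell; by default they are reported when the omnibus
#' rejects at `alpha`.
#'
#' @param table A cohort table (raw volumes).
#' @param software,structure Cell selectors.
#' @param lesion_filled Lesion-filled flag to select.
#' @param alpha Significance level for the normality gate and the
#'   post-hoc gate.
#' @param test `"auto"` (normality-gated), `"rm_anova"`, or `"friedman"`.
#' @param posthoc `"if_significant"` (default), `"always"`, or `"never"`.
#' @param sphericity `"greenhouse_geisser"` (default) or `"none"`.
#' @param run_policy Run selection for the per-scanner values
#'   (see [pivot_ratings()]).
#' @return A `"bias_test"` object; `tidy()` gives the post-hoc table.
#' @export
omnibus_scanner_test <- function(table, software, structure,
                                 lesion_filled = FALSE, alpha = 0.05,
                                 test = c("auto", "rm_anova", "friedman"),
                                 posthoc = c("if_significant", "always",
                                             "never"),
                                 sphericity = c("greenhouse_geisser",
                                                "none"),
                                 run_policy = "first") {
  test <- match.arg(test); posthoc <- match.arg(posthoc)
  sphericity <- match.arg(sphericity)
  m <- pivot_ratings(table, software, structure, "between",
                     run_policy = run_policy,
                     lesion_filled = lesion_filled)
  wide <- unclass(m); attr(wide, "rater_kind") <- NULL
  attr(wide, "dropped_subjects") <- NULL
  n <- nrow(wide); k <- ncol(wide)
  gm <- mean(wide)
  resid <- wide - rowMeans(wide) - outer(rep(1, n), colMeans(wide)) + gm

  constant <- diff(range(wide)) == 0
  if (test == "auto") {
    normal <- if (constant) TRUE else check_normality(as.vector(resid),
                                                      alpha)
    test <- if (normal) "rm_anova" else "friedman"
  }

  if (constant) {
    # no variance anywhere: no evidence of scanner differences
    omnibus <- list(test = "friedman", statistic = 0, df = k - 1,
                    p_value = 1, epsilon = NA_real_)
    test <- "friedman"
  } else if (test == "rm_anova") {
    ms <- two_way_mean_squares(wide)
    f <- ms$msc / ms$mse
    eps <- if (sphericity == "greenhouse_geisser") gg_epsilon(wide) else 1
    p <- pf(f, eps * (k - 1), eps * (n - 1) * (k - 1), lower.tail = FALSE)
    omnibus <- list(test = "rm_anova", statistic = f, df = k - 1,
                    p_value = p, epsilon = eps)
  } else {
    fr <- stats::friedman.test(wide)
    omnibus <- list(test = "friedman",
                    statistic = unname(fr$statistic),
                    df = unname(fr$parameter),
                    p_value = fr$p.value, epsilon = NA_real_)
  }

  gate_passed <- switch(posthoc,
                        always = TRUE,
                        never = FALSE,
                        if_significant = omnibus$p_value < alpha)
  ph <- NULL
  if (gate_passed) {
    pairs <- scanner_pairs(colnames(wide))
    n_comp <- length(pairs)
    ph <- purrr::map_dfr(pairs, function(pr) {
      a <- wide[, pr[1]]; b <- wide[, pr[2]]
      if (test == "rm_anova") {
        tt <- stats::t.test(a, b, paired = TRUE)
        raw_p <- tt$p.value; ph_test <- "paired_t"
      } else {
        if (diff(range(a - b)) == 0 && all(a - b == 0)) {
          raw_p <- 1
        } else {
          raw_p <- suppressWarnings(
            stats::wilcox.test(a, b, paired = TRUE)$p.value)
        }
        ph_test <- "wilcoxon"
      }
      tibble::tibble(scanner_pair = paste(pr, collapse = "-"),
                     test = ph_test,
                     mean_difference = mean(a - b),
                     raw_p = raw_p,
                     bonferroni_p = min(1, raw_p * n_comp))
    })
  }

  structure(
    list(software = software, structure = structure,
         lesion_filled = lesion_filled,
         omnibus_test = omnibus$test, statistic = omnibus$statistic,
         df = omnibus$df, p_value = omnibus$p_value,
         gg_epsilon = omnibus$epsilon,
         n = n, posthoc = ph, posthoc_policy = posthoc,
         gate_passed = gate_passed, alpha = alpha),
    class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g  (%s / %s, n = %d)\n",
              x$omnibus_test, x$statistic, x$p_value,
              x$software, x$structure, x$n))
  if (!is.null(x$posthoc)) print(x$posthoc)
  else cat(sprintf("  post-hocs not run (policy: %s, gate %s)\n",
                   x$posthoc_policy,
                   if (x$gate_passed) "passed" else "not passed"))
  invisible(x)
}

#' @rdname tidy_volagree
#' @method tidy bias_test
#' @export
tidy.bias_test <- function(x, ...) {
  base <- tibble::tibble(software = x$software, structure = x$structure,
                         lesion_filled = x$lesion_filled,
                         omnibus_test = x$omnibus_test,
                         statistic = x$statistic, p_value = x$p_value,
                         n = x$n)
  if (is.null(x$posthoc)) return(base)
  dplyr::bind_cols(base[rep(1, nrow(x$posthoc)), ], x$posthoc)
}

#' Scanner-bias significance table across a cohort
#'
#' Runs [omnibus_scanner_test()] on every (software, structure,
#' lesion-filled) cell and binds the tidy results — the table from which
#' pairwise significance annotations are reconstructed.
#'
#' @inheritParams omnibus_scanner_test
#' @return A tibble with omnibus and (where produced) post-hoc columns.
#' @export
bias_table <- function(table, alpha = 0.05,
                       posthoc = c("if_significant", "always", "never"),
                       run_policy = "first") {
  posthoc <- match.arg(posthoc)
  cells <- dplyr::distinct(tibble::as_tibble(table),
                           .data$software, .data$structure,
                           .data$lesion_filled)
  purrr::pmap_dfr(cells, function(software, structure, lesion_filled) {
    tidy(omnibus_scanner_test(table, software, structure, lesion_filled,
                              alpha = alpha, posthoc = posthoc,
                              run_policy = run_policy))
  })
}

#' Bland-Altman agreement statistics for one scanner pair
#'
#' Fixed bias is the mean paired difference, limits of agreement are
#' `bias +/- 1.96 sd(diff)`, with t-based 95% CIs for the bias and for
#' each limit; proportional bias is the slope of regressing the
#' difference on the pair mean, with its p-value. Swapping the columns
#' negates bias, limits and slope exactly.
#'
#' @param pairs n x 2 numeric matrix or data frame (value on scanner A,
#'   value on scanner B), n >= 3.
#' @param alpha CI level is `1 - alpha`.
#' @return A `"bland_altman"` object.
#' @export
bland_altman <- function(pairs, alpha = 0.05) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 3 || anyNA(pairs)) {
    abort("Need a complete n x 2 matrix with n >= 3.",
          class = "volagree_validation_error")
  }
  pair_names <- colnames(pairs) %||% c("A", "B")
  d <- pairs[, 1] - pairs[, 2]
  avg <- rowMeans(pairs)
  n <- length(d)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  tcrit <- qt(1 - alpha / 2, n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  degenerate <- sd_diff == 0 || stats::sd(avg) == 0
  if (degenerate) {
    slope <- 0; slope_p <- NA_real_
  } else {
    fit <- stats::lm(d ~ avg)
    sm <- summary(fit)$coefficients
    slope <- unname(sm["avg", "Estimate"])
    slope_p <- unname(sm["avg", "Pr(>|t|)"])
  }
  structure(
    list(scanner_pair = paste(pair_names, collapse = "-"),
         bias = bias, sd_diff = sd_diff,
         loa_low = loa_low, loa_high = loa_high,
         ci_bias = c(bias - tcrit * se_bias, bias + tcrit * se_bias),
         ci_loa_low = c(loa_low - tcrit * se_loa, loa_low + tcrit * se_loa),
         ci_loa_high = c(loa_high - tcrit * se_loa,
                         loa_high + tcrit * se_loa),
         proportional_slope = slope, proportional_p = slope_p,
         degenerate_slope = degenerate,
         n = n, alpha = alpha,
         data = tibble::tibble(mean = avg, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman %s (n = %d)\n", x$scanner_pair, x$n))
  cat(sprintf("  bias %.4g [%.4g, %.4g], LoA [%.4g, %.4g]\n",
              x$bias, x$ci_bias[1], x$ci_bias[2], x$loa_low, x$loa_high))
  cat(sprintf("  proportional slope %.4g (p = %.3g)%s\n",
              x$proportional_slope, x$proportional_p,
              if (x$degenerate_slope) " [degenerate]" else ""))
  invisible(x)
}

#' @rdname tidy_volagree
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    scanner_pair = x$scanner_pair, bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_bias_low = x$ci_bias[1], ci_bias_high = x$ci_bias[2],
    ci_loa_low_low = x$ci_loa_low[1], ci_loa_low_high = x$ci_loa_low[2],
    ci_loa_high_low = x$ci_loa_high[1],
    ci_loa_high_high = x$ci_loa_high[2],
    proportional_slope = x$proportional_slope,
    proportional_p = x$proportional_p, n = x$n)
}

#' Bland-Altman table across a cohort
#'
#' One Bland-Altman analysis per (software, structure, lesion-filled,
#' scanner pair) on first-run values.
#'
#' @param table A cohort table (raw volumes).
#' @param alpha CI level is `1 - alpha`.
#' @param run_policy Run selection (see [pivot_ratings()]).
#' @return A tibble of tidy Bland-Altman rows.
#' @export
bland_altman_table <- function(table, alpha = 0.05, run_policy = "first") {
  design <- cohort_design_of(table)
  cells <- dplyr::distinct(tibble::as_tibble(table),
                           .data$software, .data$structure,
                           .data$lesion_filled)
  purrr::pmap_dfr(cells, function(software, structure, lesion_filled) {
    purrr::map_dfr(scanner_pairs(design$scanners), function(pr) {
      m <- pivot_ratings(table, software, structure, "between",
                         scanners = pr, run_policy = run_policy,
                         lesion_filled = lesion_filled)
      dplyr::bind_cols(
        tibble::tibble(software = software, structure = structure,
                       lesion_filled = lesion_filled),
        tidy(bland_altman(unclass(m)[, , drop = FALSE], alpha = alpha)))
    })
  })
}
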
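#' Published SEM/SDC reference values
#'
#' Reference table of standard errors of measurement and smallest
#' detectable changes (both as % of the mean) reported by a published
#' multi-vendor scan-rescan MS volumetry study: five structures, six
#' segmentation tools, within- and between-scanner comparisons. Shipped as
#' a plain-text input for consistency checks of the SDC transform; these
#' are printed (rounded to two decimals) values.
#'
#' @return A tibble with columns `software`, `structure`, `comparison`
#'   (`within`/`between`), `sem_pct`, `sdc_pct`.
#' @export
published_reliability_table <- function() {
  path <- system.file("extdata", "published_sem_sdc.csv",
                      package = "volagree", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
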
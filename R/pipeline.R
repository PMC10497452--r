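# End-to-end orchestration: cohort in (file or synthetic), all analysis
# tables out, with a JSON manifest recording seed, policies and content
# hashes so a rerun with the same config and seed is bit-identical.

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#'   Recognized fields: `input` (either `path`, with optional `delim` and
#'   `col_map`, or `synthetic`, holding [synthetic_config()] fields),
#'   `exclusions` (list of subject_id/scanner_id/run), `alpha`,
#'   `run_policy`, `icc_on` (`"raw"`/`"normalized"`), `delta_pct`,
#'   `power`, `seed`, `out_dir`.
#' @return A config list with class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "volagree_config_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_pipeline_config(cfg)
}

#' Build a pipeline configuration in code
#'
#' @param ... Configuration fields (see [read_pipeline_config()]).
#' @return A config list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) as_pipeline_config(list(...))

as_pipeline_config <- function(cfg) {
  defaults <- list(alpha = 0.05, run_policy = "first", icc_on = "raw",
                   delta_pct = 1, power = 0.80, seed = 1L,
                   out_dir = "volagree-output")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (!cfg$run_policy %in% c("first", "mean")) {
    abort("run_policy must be 'first' or 'mean'.",
          class = "volagree_config_error")
  }
  if (!cfg$icc_on %in% c("raw", "normalized")) {
    abort("icc_on must be 'raw' or 'normalized'.",
          class = "volagree_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

load_pipeline_cohort <- function(config) {
  input <- config$input %||% list()
  if (!is.null(input$path)) {
    read_volume_table(input$path, delim = input$delim %||% ",",
                      col_map = unlist(input$col_map))
  } else {
    syn <- input$synthetic %||% list()
    sc <- if (length(syn) == 0) {
      preset_cohort_config(seed = config$seed)
    } else {
      syn$seed <- syn$seed %||% config$seed
      if (!is.null(syn$structures))
        syn$structures <- tibble::as_tibble(syn$structures)
      if (!is.null(syn$scanner_bias))
        syn$scanner_bias <- tibble::as_tibble(syn$scanner_bias)
      if (!is.null(syn$missing))
        syn$missing <- tibble::as_tibble(syn$missing)
      do.call(synthetic_config, syn)
    }
    generate_cohort(sc, software = input$software %||% "synthetic")
  }
}

#' Run the full reliability pipeline
#'
#' Loads or generates a cohort, applies quality-control exclusions, and
#' writes per-cell analysis tables: within-scanner and between-scanner
#' ICCs (on raw volumes by convention), the scanner-bias significance
#' table, Bland-Altman statistics per scanner pair, the SEM/SDC
#' reliability summary, and the within- vs between-scanner sample-size
#' table (both on TIV-normalized volumes), plus `manifest.json` listing
#' every emitted file with its MD5 hash, the seed and the policies. Any
#' stage failure is recorded in the manifest; completed outputs are kept.
#'
#' @param config A `"pipeline_config"` (or path to one).
#' @param out_dir Output directory (overrides the config field).
#' @param seed Seed (overrides the config field).
#' @return Invisibly, a list with `status` (0 on full success) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  failures <- character()
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    files <<- c(files, path)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
    inform(sprintf("[volagree] stage %-14s %s (%.2fs)", name,
                   if (is.null(res)) "FAILED" else "ok",
                   as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cohort <- stage("load", {
    tab <- load_pipeline_cohort(config)
    if (!is.null(config$exclusions)) {
      tab <- exclude_records(
        tab, dplyr::bind_rows(lapply(config$exclusions, tibble::as_tibble)))
    }
    tab
  })
  if (is.null(cohort)) {
    manifest <- pipeline_manifest(config, files, failures)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(list(status = 1L, manifest = manifest)))
  }

  icc_input <- cohort
  if (config$icc_on == "normalized") {
    warn(paste("ICC and bias stages forced onto TIV-normalized volumes;",
               "the convention is to run them on raw volumes."))
    icc_input <- suppressWarnings(normalize_by_tiv(cohort))
  }
  run_quiet <- function(x) suppressWarnings(x)

  st <- stage("icc_within", run_quiet(
    icc_table(icc_input, "within", alpha = config$alpha)))
  if (!is.null(st)) emit(st, "icc_within.csv")
  st <- stage("icc_between", run_quiet(
    icc_table(icc_input, "between", alpha = config$alpha,
              run_policy = config$run_policy)))
  if (!is.null(st)) emit(st, "icc_between.csv")
  st <- stage("bias", run_quiet(
    bias_table(icc_input, alpha = config$alpha,
               run_policy = config$run_policy)))
  if (!is.null(st)) emit(st, "bias_tests.csv")
  st <- stage("bland_altman", run_quiet(
    bland_altman_table(icc_input, alpha = config$alpha,
                       run_policy = config$run_policy)))
  if (!is.null(st)) emit(st, "bland_altman.csv")

  normalized <- stage("normalize", {
    if (is_normalized(cohort)) cohort else normalize_by_tiv(cohort)
  })
  rel <- stage("reliability", summarize_reliability(normalized))
  if (!is.null(rel)) {
    emit(rel, "reliability_sem_sdc.csv")
    emit(reliability_extremes(rel), "reliability_extremes.csv")
  }
  st <- stage("power", power_table(normalized, delta_pct = config$delta_pct,
                                   alpha = config$alpha,
                                   power = config$power))
  if (!is.null(st)) emit(st, "power_sample_sizes.csv")

  manifest <- pipeline_manifest(config, files, failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(status = if (length(failures) > 0) 1L else 0L,
                 manifest = manifest))
}

pipeline_manifest <- function(config, files, failures) {
  list(
    package = "volagree",
    version = as.character(utils::packageVersion("volagree")),
    seed = config$seed,
    policies = list(alpha = config$alpha, run_policy = config$run_policy,
                    icc_on = config$icc_on, delta_pct = config$delta_pct,
                    power = config$power),
    files = if (length(files) > 0) {
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    } else list(),
    failures = if (length(failures) > 0) failures else list(),
    status = if (length(failures) > 0) "failed" else "complete")
}
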
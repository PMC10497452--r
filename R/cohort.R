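# Cohort data model: one row per measured volume, keyed by
# (subject, scanner, run, software, structure, lesion_filled).

#' Controlled vocabulary of brain structures
#'
#' The structures handled by the pipeline: whole brain, the three tissue
#' classes, and the seven bilateral deep grey matter structures.
#'
#' @return Character vector of allowed structure labels.
#' @export
structure_vocabulary <- function() {
  c("brain", "gm", "wm", "csf",
    "amygdala", "accumbens", "caudate", "hippocampus",
    "pallidum", "putamen", "thalamus")
}

#' Declare the design of a scan-rescan cohort
#'
#' A design records the declared sets every cohort row must belong to. It is
#' attached to a cohort table and used to validate membership and to count
#' subjects dropped when building ratings matrices.
#'
#' @param subjects Character vector of subject identifiers.
#' @param scanners Character vector of scanner identifiers.
#' @param runs Integer vector of run indices (default `1:2`).
#' @param software Character vector of segmentation software labels.
#' @param structures Character vector of structure labels; must be a subset
#'   of [structure_vocabulary()].
#' @return A list with class `"cohort_design"`.
#' @export
cohort_design <- function(subjects, scanners, runs = 1:2,
                          software = "unknown",
                          structures = structure_vocabulary()) {
  bad <- setdiff(structures, structure_vocabulary())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown structure label(s): %s. Allowed: %s",
      paste(bad, collapse = ", "),
      paste(structure_vocabulary(), collapse = ", ")),
      class = "volagree_validation_error")
  }
  structure(
    list(subjects = as.character(subjects),
         scanners = as.character(scanners),
         runs = as.integer(runs),
         software = as.character(software),
         structures = as.character(structures)),
    class = "cohort_design")
}

required_cohort_columns <- function() {
  c("subject_id", "scanner_id", "run", "software", "structure",
    "lesion_filled", "volume", "tiv")
}

new_cohort <- function(df, design, normalized = FALSE, exclusion_log = NULL) {
  out <- tibble::as_tibble(df)[, required_cohort_columns()]
  attr(out, "design") <- design
  attr(out, "normalized") <- normalized
  attr(out, "exclusion_log") <- exclusion_log %||%
    tibble::tibble(subject_id = character(), scanner_id = character(),
                   run = integer(), n_removed = integer())
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Is a cohort table TIV-normalized?
#'
#' @param table A cohort table.
#' @return `TRUE` if [normalize_by_tiv()] has been applied.
#' @export
is_normalized <- function(table) isTRUE(attr(table, "normalized"))

#' Retrieve the design attached to a cohort table
#'
#' @param table A cohort table.
#' @return The `"cohort_design"` object.
#' @export
cohort_design_of <- function(table) attr(table, "design")

#' Validate a data frame as a cohort table
#'
#' Checks column presence and types, positivity of volumes and TIVs,
#' `volume <= tiv` row-wise (each single structure is bounded by the
#' intracranial volume), run membership, structure vocabulary, design
#' membership, and uniqueness of the record key.
#'
#' @param df Data frame with columns `subject_id`, `scanner_id`, `run`,
#'   `software`, `structure`, `lesion_filled`, `volume`, `tiv`.
#' @param design Optional [cohort_design()]; defaults to the sets observed
#'   in `df`.
#' @param normalized Whether `volume` already holds TIV fractions.
#' @return A validated cohort table (a tibble with class `"cohort_tbl"`).
#' @export
as_cohort <- function(df, design = NULL, normalized = FALSE) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(required_cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "volagree_config_error")
  }
  df$subject_id <- as.character(df$subject_id)
  df$scanner_id <- as.character(df$scanner_id)
  df$run <- as.integer(df$run)
  df$software <- as.character(df$software)
  df$structure <- as.character(df$structure)
  df$lesion_filled <- as.logical(df$lesion_filled)
  df$volume <- as.numeric(df$volume)
  df$tiv <- as.numeric(df$tiv)

  bad_rows <- which(!is.finite(df$volume) | df$volume <= 0)
  if (length(bad_rows) > 0) {
    abort(sprintf("Non-positive or missing volume at row(s): %s",
                  paste(utils::head(bad_rows, 5), collapse = ", ")),
          class = "volagree_validation_error")
  }
  bad_rows <- which(!is.finite(df$tiv) | df$tiv <= 0)
  if (length(bad_rows) > 0) {
    abort(sprintf("Non-positive or missing TIV at row(s): %s",
                  paste(utils::head(bad_rows, 5), collapse = ", ")),
          class = "volagree_validation_error")
  }
  if (!normalized) {
    bad_rows <- which(df$volume > df$tiv)
    if (length(bad_rows) > 0) {
      abort(sprintf("Volume exceeds TIV at row(s): %s",
                    paste(utils::head(bad_rows, 5), collapse = ", ")),
            class = "volagree_validation_error")
    }
  }
  bad <- setdiff(unique(df$structure), structure_vocabulary())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown structure label(s): %s. Allowed: %s",
      paste(bad, collapse = ", "),
      paste(structure_vocabulary(), collapse = ", ")),
      class = "volagree_validation_error")
  }

  if (is.null(design)) {
    design <- cohort_design(
      subjects = sort(unique(df$subject_id)),
      scanners = sort(unique(df$scanner_id)),
      runs = sort(unique(df$run)),
      software = sort(unique(df$software)),
      structures = intersect(structure_vocabulary(),
                             unique(df$structure)))
  }
  check_membership <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0) {
      abort(sprintf("%s not declared in design: %s", what,
                    paste(bad, collapse = ", ")),
            class = "volagree_validation_error")
    }
  }
  check_membership(df$subject_id, design$subjects, "Subject(s)")
  check_membership(df$scanner_id, design$scanners, "Scanner(s)")
  check_membership(df$run, design$runs, "Run(s)")
  check_membership(df$software, design$software, "Software label(s)")
  check_membership(df$structure, design$structures, "Structure(s)")

  key <- paste(df$subject_id, df$scanner_id, df$run, df$software,
               df$structure, df$lesion_filled, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf("Duplicate record key: %s",
                  sub("\\|", " / ", key[which(dup)[1]], fixed = FALSE)),
          class = "volagree_validation_error")
  }
  new_cohort(df, design, normalized = normalized)
}

default_column_map <- function() {
  c(subject_id = "subject_id", scanner_id = "scanner_id", run = "run",
    software = "software", structure = "structure",
    lesion_filled = "lesion_filled", volume = "volume_mm3",
    tiv = "tiv_mm3")
}

#' Read a long-format volume table
#'
#' Reads a delimited text file with one measured volume per row and returns
#' a validated cohort table. The expected header is `subject_id,
#' scanner_id, run, software, structure, lesion_filled, volume_mm3,
#' tiv_mm3`; differently named columns are handled through `col_map`.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default `","`).
#' @param col_map Named character vector mapping the logical column names
#'   (`subject_id`, ..., `volume`, `tiv`) to the names used in the file;
#'   unspecified entries fall back to the standard schema.
#' @param design Optional [cohort_design()] to validate against.
#' @return A cohort table.
#' @export
read_volume_table <- function(path, delim = ",", col_map = NULL,
                              design = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "volagree_config_error")
  }
  map <- default_column_map()
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), names(map))
    if (length(bad) > 0) {
      abort(sprintf("Unknown logical column(s) in col_map: %s",
                    paste(bad, collapse = ", ")),
            class = "volagree_config_error")
    }
    map[names(col_map)] <- col_map
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("File %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "volagree_config_error")
  }
  df <- raw[, unname(map)]
  names(df) <- names(map)
  as_cohort(df, design = design)
}

#' Write a cohort table to delimited text
#'
#' Emits the standard schema (`volume_mm3`, `tiv_mm3` for the real-valued
#' columns, written with 6 significant digits); string and integer fields
#' round-trip exactly.
#'
#' @param table A cohort table.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(table, path, delim = ",") {
  out <- tibble::as_tibble(table)
  out$volume <- signif(out$volume, 6)
  out$tiv <- signif(out$tiv, 6)
  names(out)[names(out) == "volume"] <- "volume_mm3"
  names(out)[names(out) == "tiv"] <- "tiv_mm3"
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Normalize volumes by intracranial volume
#'
#' Replaces each volume by `volume / tiv` (a dimensionless fraction of head
#' size) and flags the table as normalized. SEM/SDC and power planning
#' consume normalized volumes by convention; ICC and the scanner-bias tests
#' consume raw volumes. Normalizing twice is an error.
#'
#' @param table A cohort table.
#' @return The normalized cohort table.
#' @export
normalize_by_tiv <- function(table) {
  if (is_normalized(table)) {
    abort("Cohort table is already TIV-normalized.",
          class = "volagree_state_error")
  }
  table$volume <- table$volume / table$tiv
  attr(table, "normalized") <- TRUE
  table
}

#' Remove excluded (subject, scanner, run) acquisitions
#'
#' Drops every record matching an exclusion key across all software,
#' structures and lesion-filled flags — the quality-control path for runs
#' rejected for, e.g., motion artifacts. Keys matching no record raise a
#' warning, not an error. The exclusion log is retained on the returned
#' table (attribute `"exclusion_log"`).
#'
#' @param table A cohort table.
#' @param exclusions Data frame with columns `subject_id`, `scanner_id`,
#'   `run`, one row per excluded acquisition.
#' @return The filtered cohort table.
#' @export
exclude_records <- function(table, exclusions) {
  if (is.null(exclusions) || nrow(as.data.frame(exclusions)) == 0) {
    return(table)
  }
  exclusions <- tibble::as_tibble(exclusions)
  stopifnot(all(c("subject_id", "scanner_id", "run") %in% names(exclusions)))
  exclusions$run <- as.integer(exclusions$run)
  design <- cohort_design_of(table)
  normalized <- is_normalized(table)
  log_old <- attr(table, "exclusion_log")

  tab_key <- paste(table$subject_id, table$scanner_id, table$run, sep = "|")
  log_new <- exclusions
  log_new$n_removed <- vapply(seq_len(nrow(exclusions)), function(i) {
    key <- paste(exclusions$subject_id[i], exclusions$scanner_id[i],
                 exclusions$run[i], sep = "|")
    sum(tab_key == key)
  }, integer(1))
  no_hit <- log_new$n_removed == 0
  if (any(no_hit)) {
    warn(sprintf("Exclusion key(s) matched no records: %s",
                 paste(sprintf("(%s, %s, %d)",
                               exclusions$subject_id[no_hit],
                               exclusions$scanner_id[no_hit],
                               exclusions$run[no_hit]), collapse = "; ")))
  }
  excl_key <- paste(exclusions$subject_id, exclusions$scanner_id,
                    exclusions$run, sep = "|")
  kept <- table[!(tab_key %in% excl_key), , drop = FALSE]
  new_cohort(kept, design, normalized = normalized,
             exclusion_log = dplyr::bind_rows(log_old, log_new))
}

#' Extract a subjects-by-raters ratings matrix
#'
#' Builds the n x k matrix every ICC computation consumes. For
#' `comparison = "within"` the columns are the runs of one scanner
#' (scan vs rescan); for `comparison = "between"` the columns are the
#' selected scanners, each represented by its first-run value (or the mean
#' over runs when `run_policy = "mean"`). Subjects with any missing cell
#' are dropped listwise; the count of dropped subjects is retained as an
#' attribute so that `nrow + dropped` always equals the number of design
#' subjects.
#'
#' @param table A cohort table (raw volumes by convention; a warning is
#'   issued if the table is normalized).
#' @param software Software label to select.
#' @param structure Structure label to select.
#' @param comparison `"within"` (runs of one scanner) or `"between"`
#'   (first-run values across scanners).
#' @param scanner Scanner id, required for `comparison = "within"`.
#' @param scanners Scanner ids for `comparison = "between"`; defaults to
#'   all scanners in the design (use a pair for pairwise comparisons).
#' @param run_policy For `"between"`: `"first"` (default) or `"mean"`.
#' @param lesion_filled Which lesion-filled flag to select (default
#'   `FALSE`).
#' @return A numeric matrix with class `"ratings_matrix"` and attributes
#'   `rater_kind`, `dropped_subjects`.
#' @export
pivot_ratings <- function(table, software, structure,
                          comparison = c("within", "between"),
                          scanner = NULL, scanners = NULL,
                          run_policy = c("first", "mean"),
                          lesion_filled = FALSE) {
  comparison <- match.arg(comparison)
  run_policy <- match.arg(run_policy)
  design <- cohort_design_of(table)
  if (is_normalized(table)) {
    warn(paste("Building a ratings matrix from TIV-normalized volumes;",
               "ICCs are conventionally computed on raw volumes."))
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

  if (comparison == "within") {
    if (is.null(scanner)) {
      abort("comparison = 'within' requires a scanner id.",
            class = "volagree_config_error")
    }
    df <- dplyr::filter(df, .data$scanner_id == !!scanner)
    wide <- tidyr::pivot_wider(df[, c("subject_id", "run", "volume")],
                               names_from = "run", values_from = "volume",
                               names_prefix = "run")
    rater_cols <- paste0("run", sort(design$runs))
    rater_kind <- "runs_within_scanner"
  } else {
    scanners <- scanners %||% design$scanners
    if (length(scanners) < 2) {
      abort("comparison = 'between' needs at least two scanners.",
            class = "volagree_config_error")
    }
    df <- dplyr::filter(df, .data$scanner_id %in% !!scanners)
    if (run_policy == "first") {
      df <- dplyr::filter(df, .data$run == min(design$runs))
    } else {
      df <- dplyr::summarise(
        dplyr::group_by(df, .data$subject_id, .data$scanner_id),
        volume = mean(.data$volume), .groups = "drop")
    }
    wide <- tidyr::pivot_wider(df[, c("subject_id", "scanner_id", "volume")],
                               names_from = "scanner_id",
                               values_from = "volume")
    rater_cols <- scanners
    rater_kind <- "scanners_first_run"
  }

  missing_cols <- setdiff(rater_cols, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  wide <- wide[, c("subject_id", rater_cols)]
  complete <- stats::complete.cases(wide[, rater_cols])
  dropped <- length(design$subjects) - sum(complete)
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3) {
    abort(sprintf(
      "Fewer than 3 complete subjects (%d) for software '%s', structure '%s'.",
      nrow(wide), software, structure),
      class = "volagree_insufficient_data_error")
  }
  m <- as.matrix(wide[, rater_cols])
  rownames(m) <- wide$subject_id
  attr(m, "rater_kind") <- rater_kind
  attr(m, "dropped_subjects") <- dropped
  class(m) <- c("ratings_matrix", class(m))
  m
}
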
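# Readers/writers for the tabular schemas. All tables are RFC-4180 CSV
# (UTF-8, comma, header row); summaries and configuration are JSON. MRD is
# carried as a percentage everywhere (1.0 means 1%), never as a fraction.

REPORT_COLS <- c("lab_id", "sample_id", "status", "value_percent")
SAMPLE_COLS <- c("sample_id", "lineage", "timepoint", "regeneration_level",
                 "true_mrd_percent")
GROUP_COLS <- c("lab_id", "group")
MATURATION_COLS <- c("lab_id", "lineage", "case_index", "gross_error",
                     "error_type")

read_schema_csv <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_input("%s: missing column(s) %s", path,
               paste(missing_cols, collapse = ", "))
  df
}

as_num <- function(x, path, col) {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop_input("%s: row %d, column %s: not a number ('%s')",
               path, bad[1], col, x[bad[1]])
  out
}

#' Read a trial bundle from CSV files
#'
#' Reads and cross-validates the reports table and, when given, the sample
#' and group tables: schema and types are checked (errors name file, row and
#' column), report statuses are normalised (`pos`/`neg`/`missing`,
#' case-insensitive), duplicate (lab, sample) pairs and dangling sample or
#' group references are rejected.
#'
#' @param reports_path path to `reports.csv`
#'   (`lab_id, sample_id, status, value_percent`).
#' @param samples_path optional path to `samples.csv`
#'   (`sample_id, lineage, timepoint, regeneration_level, true_mrd_percent`).
#' @param groups_path optional path to `groups.csv` (`lab_id, group`).
#' @return a list of class `"trial_bundle"` with `reports` and, when read,
#'   `samples` and `groups`.
#' @export
read_bundle <- function(reports_path, samples_path = NULL, groups_path = NULL) {
  rep_raw <- read_schema_csv(reports_path, REPORT_COLS)
  reports <- data.frame(
    lab_id = rep_raw$lab_id, sample_id = rep_raw$sample_id,
    status = rep_raw$status,
    value_percent = as_num(rep_raw$value_percent, reports_path, "value_percent"),
    stringsAsFactors = FALSE)
  reports <- validate_reports(reports, file = reports_path)
  bundle <- list(reports = reports)
  if (!is.null(samples_path)) {
    s_raw <- read_schema_csv(samples_path, SAMPLE_COLS)
    samples <- data.frame(
      sample_id = s_raw$sample_id, lineage = s_raw$lineage,
      timepoint = s_raw$timepoint,
      regeneration_level = as_num(s_raw$regeneration_level, samples_path,
                                  "regeneration_level"),
      true_mrd_percent = as_num(s_raw$true_mrd_percent, samples_path,
                                "true_mrd_percent"),
      stringsAsFactors = FALSE)
    unknown <- setdiff(reports$sample_id, samples$sample_id)
    if (length(unknown))
      stop_input("%s: report references unknown sample(s): %s",
                 reports_path, paste(unknown, collapse = ", "))
    bundle$samples <- samples
  }
  if (!is.null(groups_path)) {
    g_raw <- read_schema_csv(groups_path, GROUP_COLS)
    unknown <- setdiff(reports$lab_id, g_raw$lab_id)
    if (length(unknown))
      stop_input("%s: laboratory without group mapping: %s",
                 groups_path, paste(unknown, collapse = ", "))
    bundle$groups <- g_raw[GROUP_COLS]
  }
  structure(bundle, class = "trial_bundle")
}

#' Read a maturation case log
#'
#' @param path path to `maturation_log.csv`
#'   (`lab_id, lineage, case_index, gross_error[, error_type]`).
#' @return validated `data.frame` suitable for [maturation_series()].
#' @export
read_maturation_log <- function(path) {
  raw <- read_schema_csv(path, setdiff(MATURATION_COLS, "error_type"))
  log <- data.frame(
    lab_id = raw$lab_id, lineage = raw$lineage,
    case_index = as_num(raw$case_index, path, "case_index"),
    gross_error = as_num(raw$gross_error, path, "gross_error"),
    error_type = if ("error_type" %in% names(raw)) raw$error_type else "",
    stringsAsFactors = FALSE)
  if (any(!log$gross_error %in% c(0, 1)))
    stop_input("%s: gross_error must be 0 or 1", path)
  log
}

# fixed formatting (6 significant digits, plain notation) so identical
# bundles serialize byte-identically
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

write_csv_deterministic <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
    error = function(e) stop_input("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' Write a trial bundle to a directory
#'
#' Writes `reports.csv`, plus `samples.csv`, `groups.csv`, `targets.csv`
#' when present, and a `provenance.json` (tool version, seed, configuration
#' hash). Column order and number formatting are fixed, so writing the same
#' bundle twice yields byte-identical files, and
#' `read_bundle(write_bundle(b))` restores `b`.
#'
#' @param bundle a `"trial_bundle"` (from [read_bundle()] or
#'   [simulate_ring_trial()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reports = file.path(dir, "reports.csv"))
  write_csv_deterministic(bundle$reports[REPORT_COLS], paths[["reports"]])
  if (!is.null(bundle$samples)) {
    paths["samples"] <- file.path(dir, "samples.csv")
    write_csv_deterministic(bundle$samples[SAMPLE_COLS], paths[["samples"]])
  }
  if (!is.null(bundle$groups)) {
    paths["groups"] <- file.path(dir, "groups.csv")
    write_csv_deterministic(bundle$groups[GROUP_COLS], paths[["groups"]])
  }
  if (!is.null(bundle$targets)) {
    paths["targets"] <- file.path(dir, "targets.csv")
    write_csv_deterministic(bundle$targets, paths[["targets"]])
  }
  prov <- bundle$provenance
  if (is.null(prov)) prov <- list(tool = "mrdqc")
  prov$config_hash <- sum(utf8ToInt(paste(
    capture_provenance_string(bundle), collapse = "")))
  paths["provenance"] <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

capture_provenance_string <- function(bundle) {
  c(dim(bundle$reports), names(bundle),
    if (!is.null(bundle$provenance$seed)) bundle$provenance$seed)
}
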
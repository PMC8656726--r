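#' Positivity rule for flow-cytometric MRD
#'
#' MRD positivity in multi-centre list-mode-data exchanges is defined by an
#' event-count rule: a sample is positive when at least `min_events` leukemic
#' events are found among `denominator_events` nucleated events. The default
#' (>= 10 events among 3e5) corresponds to a threshold of 1/300 percent,
#' conventionally printed as 0.003% after truncation.
#'
#' @param min_events minimum number of MRD events for a positive call.
#' @param denominator_events number of nucleated events in the denominator.
#' @return an object of class `"positivity_rule"` with fields `min_events`,
#'   `denominator_events` and the derived `threshold_percent`.
#' @examples
#' rule <- positivity_rule()
#' rule$threshold_percent           # 1/300 = 0.003333...
#' positivity_threshold_percent(rule, truncate_digits = 3)  # printed 0.003
#' @export
positivity_rule <- function(min_events = 10, denominator_events = 3e5) {
  if (length(min_events) != 1L || min_events < 1 || min_events != trunc(min_events))
    stop_input("min_events must be a positive integer, got %s", format(min_events))
  if (length(denominator_events) != 1L || denominator_events <= 0)
    stop_input("denominator_events must be > 0, got %s", format(denominator_events))
  structure(
    list(min_events = as.integer(min_events),
         denominator_events = denominator_events,
         threshold_percent = 100 * min_events / denominator_events),
    class = "positivity_rule"
  )
}

#' @export
print.positivity_rule <- function(x, ...) {
  cat(sprintf("MRD positivity rule: >=%d events among %g nucleated (threshold %s%%)\n",
              x$min_events, x$denominator_events,
              format(x$threshold_percent, digits = 4)))
  invisible(x)
}

#' Classify a sample as MRD positive or negative from event counts
#'
#' @param events non-negative integer count of MRD events.
#' @param rule a [positivity_rule()].
#' @return `"positive"` if `events >= rule$min_events`, else `"negative"`.
#'   Vectorised over `events`.
#' @examples
#' classify_positivity(c(0, 9, 10, 250))
#' @export
classify_positivity <- function(events, rule = positivity_rule()) {
  if (any(is.na(events)) || any(events < 0) || any(events != trunc(events)))
    stop_input("events must be non-negative integers")
  ifelse(events >= rule$min_events, "positive", "negative")
}

#' Positivity threshold as a percentage of nucleated cells
#'
#' The exact threshold is `100 * min_events / denominator_events`. Reports and
#' figure captions print it truncated (not rounded) to three decimals, e.g.
#' 1/300% prints as 0.003%; `truncate_digits` reproduces that view.
#'
#' @param rule a [positivity_rule()].
#' @param truncate_digits if non-`NULL`, truncate the threshold to this many
#'   decimal places (the printed convention); `NULL` returns full precision.
#' @return threshold in percent.
#' @export
positivity_threshold_percent <- function(rule = positivity_rule(),
                                         truncate_digits = NULL) {
  p <- rule$threshold_percent
  if (is.null(truncate_digits)) return(p)
  trunc(p * 10^truncate_digits) / 10^truncate_digits
}

# normalize status strings: pos/neg/missing, case-insensitive
normalize_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  s[s %in% c("pos", "positive", "p")] <- "positive"
  s[s %in% c("neg", "negative", "n")] <- "negative"
  s[s %in% c("missing", "na", "")] <- "missing"
  bad <- setdiff(unique(s), c("positive", "negative", "missing"))
  if (length(bad))
    stop_input("unknown report status value(s): %s", paste(bad, collapse = ", "))
  s
}

#' Assemble and validate a table of laboratory MRD reports
#'
#' A report is one laboratory's result for one sample: an explicit status
#' (`positive`, `negative` or `missing`) and, for positive reports only, the
#' reported MRD as a percentage of nucleated cells (so 1.0 means 1%).
#'
#' @param lab_id,sample_id identifiers (coerced to character).
#' @param status report status; `pos`/`neg`/`missing` accepted case-insensitively.
#' @param value_percent reported MRD percent; must be `NA` unless positive,
#'   and `> 0` when positive.
#' @return a validated `data.frame` with columns
#'   `lab_id`, `sample_id`, `status`, `value_percent`.
#' @examples
#' mrd_reports(c("L1", "L1"), c("S1", "S2"), c("pos", "neg"), c(0.25, NA))
#' @export
mrd_reports <- function(lab_id, sample_id, status, value_percent = NA_real_) {
  df <- data.frame(lab_id = as.character(lab_id),
                   sample_id = as.character(sample_id),
                   status = normalize_status(status),
                   value_percent = as.numeric(value_percent),
                   stringsAsFactors = FALSE)
  validate_reports(df)
}

# shared validation for report tables (constructor and CSV reader)
validate_reports <- function(df, file = NULL) {
  where <- function(i, col) {
    if (is.null(file)) sprintf("report row %d, column %s", i, col)
    else sprintf("%s: row %d, column %s", file, i, col)
  }
  df$status <- normalize_status(df$status)
  pos <- df$status == "positive"
  bad <- which(pos & (is.na(df$value_percent) | df$value_percent <= 0))
  if (length(bad))
    stop_input("%s: positive report requires value_percent > 0", where(bad[1], "value_percent"))
  bad <- which(!pos & !is.na(df$value_percent))
  if (length(bad))
    stop_input("%s: value_percent must be empty unless status is positive", where(bad[1], "value_percent"))
  dup <- duplicated(df[c("lab_id", "sample_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    j <- which(df$lab_id == df$lab_id[i] & df$sample_id == df$sample_id[i])[1]
    stop_input("duplicate report for (lab %s, sample %s) at rows %d and %d",
               df$lab_id[i], df$sample_id[i], j, i)
  }
  df
}

#' Consensus target vote for one sample
#'
#' The target MRD value of a proficiency-test sample is the median of the
#' contributing laboratories' reported values, with negative reports entering
#' as 0 and missing reports excluded. Two consensus rules are used in
#' practice: the median of designated, matured reference laboratories
#' (`"reference_median"`, list-mode-data send-arounds) and the median of all
#' submitting centres (`"all_submitted_median"`, external QA schemes). The
#' vote is positive when the median reaches the positivity threshold.
#'
#' @param reports a report table (see [mrd_reports()]) for a single sample.
#' @param rule which consensus rule the vote represents (provenance label;
#'   the caller selects the contributing laboratories accordingly).
#' @param positivity a [positivity_rule()] deciding the vote's status.
#' @return an object of class `"target_vote"`: `sample_id`, `status`
#'   (`positive`/`negative`), `value_percent` (`NA` when negative),
#'   `n_contributors`, `rule`.
#' @examples
#' r <- mrd_reports(paste0("L", 1:6), "S1",
#'                  rep("pos", 6), c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
#' target_vote(r)$value_percent  # 0.35
#' @export
target_vote <- function(reports,
                        rule = c("reference_median", "all_submitted_median"),
                        positivity = positivity_rule()) {
  rule <- match.arg(rule)
  reports <- validate_reports(reports)
  if (length(unique(reports$sample_id)) > 1L)
    stop_input("target_vote expects reports for a single sample, got %d",
               length(unique(reports$sample_id)))
  use <- reports$status != "missing"
  if (!any(use))
    stop_input("empty consensus: no non-missing report for sample %s",
               reports$sample_id[1])
  vals <- ifelse(reports$status[use] == "positive", reports$value_percent[use], 0)
  med <- stats::median(vals)
  positive <- med >= positivity$threshold_percent
  structure(
    list(sample_id = reports$sample_id[1],
         status = if (positive) "positive" else "negative",
         value_percent = if (positive) med else NA_real_,
         n_contributors = sum(use),
         rule = rule),
    class = "target_vote"
  )
}

#' Consensus target votes for every sample in a report table
#'
#' Applies [target_vote()] sample by sample. With `consensus = "reference"`
#' only reports from `reference_labs` contribute (the send-around convention,
#' where six matured reference laboratories define the target); with
#' `"all"` every submitting laboratory contributes.
#'
#' @param reports a report table covering one or more samples.
#' @param consensus `"reference"` or `"all"`.
#' @param reference_labs character vector of reference laboratory ids
#'   (required when `consensus = "reference"`).
#' @param positivity a [positivity_rule()].
#' @return a `data.frame` with one row per sample: `sample_id`, `status`,
#'   `value_percent`, `n_contributors`, `rule`.
#' @export
target_votes <- function(reports, consensus = c("reference", "all"),
                         reference_labs = NULL,
                         positivity = positivity_rule()) {
  consensus <- match.arg(consensus)
  reports <- validate_reports(reports)
  if (consensus == "reference") {
    if (is.null(reference_labs) || !length(reference_labs))
      stop_input("consensus = 'reference' requires a non-empty reference_labs")
    missing_ref <- setdiff(reference_labs, unique(reports$lab_id))
    if (length(missing_ref))
      stop_input("reference lab(s) absent from reports: %s",
                 paste(missing_ref, collapse = ", "))
    contrib <- reports[reports$lab_id %in% reference_labs, , drop = FALSE]
    rule <- "reference_median"
  } else {
    contrib <- reports
    rule <- "all_submitted_median"
  }
  ids <- unique(reports$sample_id)
  votes <- lapply(ids, function(sid) {
    tv <- target_vote(contrib[contrib$sample_id == sid, , drop = FALSE],
                      rule = rule, positivity = positivity)
    data.frame(sample_id = tv$sample_id, status = tv$status,
               value_percent = tv$value_percent,
               n_contributors = tv$n_contributors, rule = tv$rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, votes)
}

#' @export
print.target_vote <- function(x, ...) {
  val <- if (x$status == "positive") sprintf(" %.4g%%", x$value_percent) else ""
  cat(sprintf("Target vote for sample %s: %s%s (%d contributors, %s)\n",
              x$sample_id, x$status, val, x$n_contributors, x$rule))
  invisible(x)
}

#' Concordance verdict for a reported value against the target vote
#'
#' A reported MRD value is concordant when it lies within the concordance
#' margin — at most `margin_factor` times and at least `1/margin_factor` of
#' the target value (default factor 3, i.e. half a log10 up or down).
#' Reports strictly outside the band are `outlier_high` / `outlier_low`; the
#' exact x3 and /3 boundaries are concordant. A positive report against a
#' negative target is a `false_positive`; a negative report against a
#' positive target a `false_negative`; two negatives are concordant. All
#' four non-concordant categories count as "false assessments" downstream.
#'
#' @param report_status `"positive"`/`"negative"` (a missing report is an error).
#' @param report_value reported percent (required when positive).
#' @param target a `"target_vote"` object, or a list with `status` and
#'   `value_percent`.
#' @param margin_factor multiplicative half-width of the concordance band
#'   (> 1).
#' @return a list with `category` (one of `concordant`, `outlier_high`,
#'   `outlier_low`, `false_positive`, `false_negative`) and `ratio`
#'   (reported/target, defined only when both are positive, else `NA`).
#' @examples
#' tv <- list(status = "positive", value_percent = 0.10)
#' concordance_check("positive", 0.30, tv)$category  # exactly 3x: concordant
#' concordance_check("positive", 0.31, tv)$category  # outlier_high
#' @export
concordance_check <- function(report_status, report_value = NA_real_,
                              target, margin_factor = 3) {
  report_status <- normalize_status(report_status)
  if (report_status == "missing")
    stop_input("cannot score a missing report")
  if (margin_factor <= 1)
    stop_input("margin_factor must be > 1, got %s", format(margin_factor))
  cat_ <- concordance_categories(report_status, report_value,
                                 target$status, target$value_percent,
                                 margin_factor)
  ratio <- if (report_status == "positive" && target$status == "positive")
    report_value / target$value_percent else NA_real_
  list(category = cat_, ratio = ratio)
}

# vectorized kernel: statuses are "positive"/"negative" (missing handled upstream).
# Strict inequalities with a 1e-9 relative guard so the exact x3 and /3
# boundaries stay concordant despite binary-fraction rounding (0.3/0.1 != 3).
concordance_categories <- function(report_status, report_value,
                                   target_status, target_value,
                                   margin_factor = 3) {
  tol <- 1e-9
  out <- character(length(report_status))
  both_pos <- report_status == "positive" & target_status == "positive"
  ratio <- report_value / target_value
  out[both_pos & ratio > margin_factor * (1 + tol)] <- "outlier_high"
  out[both_pos & ratio < (1 / margin_factor) * (1 - tol)] <- "outlier_low"
  out[both_pos & out == ""] <- "concordant"
  out[report_status == "positive" & target_status == "negative"] <- "false_positive"
  out[report_status == "negative" & target_status == "positive"] <- "false_negative"
  out[report_status == "negative" & target_status == "negative"] <- "concordant"
  out
}
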
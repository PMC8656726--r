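# Twinning-maturation acceptance procedure: a trainee laboratory analyses at
# least 25 consecutive local cases under review by an experienced partner
# laboratory; maturation (permission to release MRD results unsupervised) is
# granted once the recent part of the series is free of gross errors.
#
# The guidelines state two completion rules that are not identical:
#  * window:  no gross error in the most recent `clean_window` (12) cases,
#    once at least `min_cases` (25) cases are done;
#  * penalty: each gross error in the second half (case 14 on) requires
#    `penalty_per_error` (3) further consecutive error-free cases.
# Both are implemented; the default `conjunction` grants maturation only
# when both readings are satisfied. First-half errors (cases 1-13) are
# logged and counted in series statistics but never extend the series.

#' Maturation rule configuration
#'
#' @param min_cases minimum series length (default 25 cases).
#' @param clean_window length of the trailing error-free window the `window`
#'   rule requires (default 12, "the most recent half").
#' @param penalty_per_error additional consecutive clean cases required per
#'   second-half gross error under the `penalty` rule (default 3).
#' @param rule_variant `"window"`, `"penalty"` or `"conjunction"` (both).
#' @param second_half_start first case index counted as second half
#'   (default 14).
#' @return an object of class `"maturation_config"`.
#' @export
maturation_config <- function(min_cases = 25, clean_window = 12,
                              penalty_per_error = 3,
                              rule_variant = c("conjunction", "window", "penalty"),
                              second_half_start = 14) {
  rule_variant <- match.arg(rule_variant)
  if (clean_window > min_cases)
    stop_input("clean_window (%d) must not exceed min_cases (%d)",
               clean_window, min_cases)
  if (penalty_per_error < 1)
    stop_input("penalty_per_error must be >= 1")
  structure(list(min_cases = as.integer(min_cases),
                 clean_window = as.integer(clean_window),
                 penalty_per_error = as.integer(penalty_per_error),
                 rule_variant = rule_variant,
                 second_half_start = as.integer(second_half_start)),
            class = "maturation_config")
}

#' Fresh maturation state for a trainee laboratory
#'
#' @param lab_id laboratory identifier.
#' @param lineage `"B"` or `"T"` — series per lineage are tracked
#'   independently.
#' @return an object of class `"maturation_state"`: `lab_id`, `lineage`,
#'   `n_cases`, `error_indices`, `matured`, `matured_at`.
#' @export
maturation_state <- function(lab_id, lineage = c("B", "T")) {
  lineage <- match.arg(lineage)
  structure(list(lab_id = as.character(lab_id), lineage = lineage,
                 n_cases = 0L, error_indices = integer(0),
                 matured = FALSE, matured_at = NA_integer_),
            class = "maturation_state")
}

GROSS_ERROR_TYPES <- c("staining_analysis", "blast_population",
                       "misinterpretation", "misdocumentation")

#' One reviewed case in a maturation series
#'
#' @param index 1-based case number within the series.
#' @param gross_error logical; whether the partner review found a gross error
#'   (inadequate staining/analysis, wrong blast population, gross
#'   misinterpretation or misdocumentation).
#' @param error_type optional label, one of `staining_analysis`,
#'   `blast_population`, `misinterpretation`, `misdocumentation`; only
#'   allowed when `gross_error` is `TRUE`.
#' @return a list of class `"case_outcome"`.
#' @export
case_outcome <- function(index, gross_error = FALSE, error_type = NULL) {
  if (!is.null(error_type)) {
    if (!gross_error)
      stop_input("error_type given for a case without gross_error")
    error_type <- match.arg(error_type, GROSS_ERROR_TYPES)
  }
  structure(list(index = as.integer(index), gross_error = isTRUE(gross_error),
                 error_type = error_type),
            class = "case_outcome")
}

# does a series of length n with errors at `errors` satisfy the rule at n?
rule_satisfied <- function(n, errors, config) {
  if (n < config$min_cases) return(FALSE)
  window_ok <- !any(errors > n - config$clean_window)
  second_half <- errors[errors >= config$second_half_start]
  last2 <- if (length(second_half)) max(second_half) else 0L
  penalty_ok <- n >= max(config$min_cases, last2 + config$penalty_per_error) &&
    !any(errors > n - config$penalty_per_error)
  switch(config$rule_variant,
         window = window_ok,
         penalty = penalty_ok,
         conjunction = window_ok && penalty_ok)
}

#' Advance a maturation state by one reviewed case
#'
#' Appends the case (indices must arrive in order) and, if the configured
#' completion rule first becomes satisfied at this case, marks the state
#' matured at this index.
#'
#' @param state a [maturation_state()], not yet matured.
#' @param outcome a [case_outcome()] with `index == state$n_cases + 1`.
#' @param config a [maturation_config()].
#' @return the updated state.
#' @export
maturation_update <- function(state, outcome, config = maturation_config()) {
  if (state$matured)
    stop_input("laboratory %s already matured at case %d",
               state$lab_id, state$matured_at)
  if (outcome$index != state$n_cases + 1L)
    stop_input("out-of-order case: expected index %d, got %d",
               state$n_cases + 1L, outcome$index)
  state$n_cases <- outcome$index
  if (outcome$gross_error)
    state$error_indices <- c(state$error_indices, outcome$index)
  if (rule_satisfied(state$n_cases, state$error_indices, config)) {
    state$matured <- TRUE
    state$matured_at <- state$n_cases
  }
  state
}

#' Has a trainee laboratory matured?
#'
#' @param state a [maturation_state()].
#' @return logical.
#' @export
is_matured <- function(state) isTRUE(state$matured)

#' @export
print.maturation_state <- function(x, ...) {
  status <- if (x$matured) sprintf("matured at case %d", x$matured_at)
  else "in training"
  cat(sprintf("Lab %s (%s-lineage): %d cases, %d gross error(s), %s\n",
              x$lab_id, x$lineage, x$n_cases, length(x$error_indices), status))
  invisible(x)
}

#' Number of cases needed to reach maturation
#'
#' Replays the state machine over an outcome sequence and returns the first
#' case index at which maturation is granted. An all-clean series matures at
#' exactly `min_cases`; late second-half errors extend the series.
#'
#' @param gross_errors logical vector, one element per consecutive case
#'   (`TRUE` = gross error), or a vector of error case indices via
#'   `error_indices`.
#' @param config a [maturation_config()].
#' @param error_indices alternative specification: indices of error cases
#'   within a series of length `n_cases`.
#' @param n_cases series length when using `error_indices`.
#' @return the maturation case index, or `NA` (with a warning) when the
#'   series ends before maturation.
#' @examples
#' cases_to_maturation(rep(FALSE, 30))            # 25
#' cases_to_maturation(error_indices = 14, n_cases = 40,
#'                     config = maturation_config(rule_variant = "window"))  # 26
#' @export
cases_to_maturation <- function(gross_errors = NULL,
                                config = maturation_config(),
                                error_indices = NULL, n_cases = NULL) {
  if (is.null(gross_errors)) {
    if (is.null(error_indices) || is.null(n_cases))
      stop_input("provide gross_errors, or error_indices with n_cases")
    gross_errors <- seq_len(n_cases) %in% error_indices
  }
  st <- maturation_state("lab")
  for (i in seq_along(gross_errors)) {
    st <- maturation_update(st, case_outcome(i, gross_errors[i]), config)
    if (st$matured) return(st$matured_at)
  }
  warning("series ended before maturation")
  NA_integer_
}

#' Pooled series breakdown across trainee laboratories
#'
#' Pools reviewed cases over all laboratories into the standard reporting
#' windows — main set (cases 1-25), series 1 (1-13), series 2 (14-25),
#' series 3 (14 to the last case of each series) and the full set — and
#' computes failure percentages (1 decimal, half-up) plus an exact 2 x 2
#' test contrasting series 1 with series 3 (early training vs consolidated
#' performance).
#'
#' @param log `data.frame` with columns `lab_id`, `case_index`,
#'   `gross_error` (0/1 or logical); optionally `lineage` (a single series
#'   per lab is assumed within the log).
#' @param config a [maturation_config()] (window boundaries).
#' @return an object of class `"series_breakdown"`: `windows` data.frame
#'   (`window`, `n_results`, `n_failures`, `failure_percent`), `p_value` and
#'   `method` for the series-1 vs series-3 contrast, and `incomplete_labs`
#'   (labs with fewer than `min_cases` cases, excluded from nothing but
#'   flagged).
#' @export
series_breakdown <- function(log, config = maturation_config()) {
  if (!nrow(log)) stop_input("empty maturation log")
  need <- c("lab_id", "case_index", "gross_error")
  if (!all(need %in% names(log)))
    stop_input("log must have columns %s", paste(need, collapse = ", "))
  log$gross_error <- as.logical(as.integer(as.logical(log$gross_error)))
  s2 <- config$second_half_start          # 14
  mid <- s2 - 1L                          # 13
  mc <- config$min_cases                  # 25
  win <- function(label, keep) {
    data.frame(window = label, n_results = sum(keep),
               n_failures = sum(log$gross_error[keep]),
               failure_percent = round_half_up(
                 100 * sum(log$gross_error[keep]) / sum(keep), 1),
               stringsAsFactors = FALSE)
  }
  idx <- log$case_index
  windows <- rbind(
    win(sprintf("main_set_1_%d", mc), idx <= mc),
    win(sprintf("series1_1_%d", mid), idx <= mid),
    win(sprintf("series2_%d_%d", s2, mc), idx >= s2 & idx <= mc),
    win(sprintf("series3_%d_last", s2), idx >= s2),
    win("all_samples", rep(TRUE, nrow(log))))
  s1 <- windows[windows$window == sprintf("series1_1_%d", mid), ]
  s3 <- windows[windows$window == sprintf("series3_%d_last", s2), ]
  tab <- matrix(c(s1$n_failures, s1$n_results - s1$n_failures,
                  s3$n_failures, s3$n_results - s3$n_failures),
                2, byrow = TRUE)
  test <- fisher_2x2(tab)
  n_per_lab <- tapply(log$case_index, log$lab_id, max)
  structure(list(windows = windows,
                 p_value = test$p_value, method = test$method,
                 incomplete_labs = names(n_per_lab)[n_per_lab < mc]),
            class = "series_breakdown")
}

#' @export
print.series_breakdown <- function(x, ...) {
  print(x$windows, row.names = FALSE)
  cat(sprintf("Series 1 vs series 3 failure rates: %s p = %.4g\n",
              x$method, x$p_value))
  if (length(x$incomplete_labs))
    cat("Incomplete series (<min_cases):",
        paste(x$incomplete_labs, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a full maturation log: per-laboratory states plus the breakdown
#'
#' Replays [maturation_update()] over each laboratory's (and lineage's)
#' ordered case log and pools the series statistics.
#'
#' @inheritParams series_breakdown
#' @return an object of class `"maturation_series"`: `states` (list of
#'   final [maturation_state()]s), `summary` (per-lab data.frame with
#'   `lab_id`, `lineage`, `n_cases`, `n_errors`, `matured`, `matured_at`),
#'   `breakdown` ([series_breakdown()]).
#' @examples
#' log <- data.frame(lab_id = "L1", lineage = "B", case_index = 1:25,
#'                   gross_error = 0)
#' fit <- maturation_series(log)
#' fit$summary
#' @export
maturation_series <- function(log, config = maturation_config()) {
  if (is.null(log$lineage)) log$lineage <- "B"
  keys <- unique(log[c("lab_id", "lineage")])
  states <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- log[log$lab_id == keys$lab_id[i] & log$lineage == keys$lineage[i], ,
               drop = FALSE]
    sub <- sub[order(sub$case_index), , drop = FALSE]
    st <- maturation_state(keys$lab_id[i], keys$lineage[i])
    for (j in seq_len(nrow(sub))) {
      if (st$matured) break
      st <- maturation_update(
        st, case_outcome(sub$case_index[j], as.logical(sub$gross_error[j])),
        config)
    }
    states[[i]] <- st
  }
  summary_df <- do.call(rbind, lapply(states, function(s)
    data.frame(lab_id = s$lab_id, lineage = s$lineage, n_cases = s$n_cases,
               n_errors = length(s$error_indices), matured = s$matured,
               matured_at = s$matured_at, stringsAsFactors = FALSE)))
  structure(list(states = states, summary = summary_df,
                 breakdown = series_breakdown(log, config), config = config),
            class = "maturation_series")
}

#' @export
print.maturation_series <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("Maturation series: %d laboratory series, %d matured\n",
              n, sum(x$summary$matured)))
  mat <- x$summary$matured_at[x$summary$matured]
  if (length(mat))
    cat(sprintf("  cases to maturation: median %g, range %d-%d\n",
                stats::median(mat), min(mat), max(mat)))
  invisible(x)
}

#' @export
summary.maturation_series <- function(object, ...) {
  print(object)
  cat("\nPer-laboratory series:\n")
  print(object$summary, row.names = FALSE)
  cat("\nPooled breakdown:\n")
  print(object$breakdown)
  invisible(object)
}
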
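# Ring-trial evaluation: per-laboratory discordance rates and flags, group
# summaries with exact between-group tests, positive/negative diagnostic
# statistics, and sample-level error screening.

#' Performance flag from a laboratory's false-assessment fraction
#'
#' Laboratories reporting false MRD values in more than 10% and up to 25% of
#' assessed cases are flagged with a warning; above 25% the report is
#' considered critical. Exactly 10% passes and exactly 25% is a warning
#' (the thresholds are strict "more than" bounds).
#'
#' @param false_fraction fraction of false assessments in `[0, 1]`; vectorised.
#' @return `"pass"`, `"warning"` or `"critical"`.
#' @examples
#' assign_flag(c(2, 3, 6) / 20)  # pass, warning, critical
#' @export
assign_flag <- function(false_fraction) {
  if (any(is.na(false_fraction)) || any(false_fraction < 0) || any(false_fraction > 1))
    stop_input("false_fraction must lie in [0, 1]")
  ifelse(false_fraction > 0.25, "critical",
         ifelse(false_fraction > 0.10, "warning", "pass"))
}

# join reports to targets and score every non-missing report.
# Returns the report table with target_status, target_value, category, ratio.
score_reports <- function(reports, targets, margin_factor = 3) {
  reports <- validate_reports(reports)
  idx <- match(reports$sample_id, targets$sample_id)
  if (anyNA(idx)) {
    bad <- unique(reports$sample_id[is.na(idx)])
    stop_input("no target vote for sample(s): %s", paste(bad, collapse = ", "))
  }
  out <- reports
  out$target_status <- targets$status[idx]
  out$target_value <- targets$value_percent[idx]
  out$category <- NA_character_
  out$ratio <- NA_real_
  sc <- out$status != "missing"
  out$category[sc] <- concordance_categories(
    out$status[sc], out$value_percent[sc],
    out$target_status[sc], out$target_value[sc], margin_factor)
  bp <- sc & out$status == "positive" & out$target_status == "positive"
  out$ratio[bp] <- out$value_percent[bp] / out$target_value[bp]
  out
}

#' Evaluate one laboratory's ring-trial performance
#'
#' Counts false assessments (any non-concordant verdict: margin outliers in
#' either direction, false positives and false negatives) among the
#' laboratory's non-missing reports and assigns the pass/warning/critical
#' flag. Missing submissions are excluded from the denominator but reported
#' as `n_missing` (a completeness metric).
#'
#' @param reports report table for a single laboratory.
#' @param targets target-vote table as returned by [target_votes()].
#' @param margin_factor concordance-margin factor (default 3).
#' @return a one-row `data.frame`: `lab_id`, `n_assessed`, `n_false`,
#'   `false_fraction`, `n_missing`, `flag`.
#' @export
evaluate_lab <- function(reports, targets, margin_factor = 3) {
  reports <- validate_reports(reports)
  if (length(unique(reports$lab_id)) > 1L)
    stop_input("evaluate_lab expects reports from a single laboratory")
  scored <- score_reports(reports, targets, margin_factor)
  assessed <- scored[scored$status != "missing", , drop = FALSE]
  if (nrow(assessed) == 0L)
    stop_input("laboratory %s assessed no samples", reports$lab_id[1])
  n_false <- sum(assessed$category != "concordant")
  frac <- n_false / nrow(assessed)
  data.frame(lab_id = reports$lab_id[1],
             n_assessed = nrow(assessed),
             n_false = n_false,
             false_fraction = frac,
             n_missing = sum(scored$status == "missing"),
             flag = assign_flag(frac),
             stringsAsFactors = FALSE)
}

#' Diagnostic statistics of positive/negative calls against target votes
#'
#' Cross-tabulates reported versus target positivity over all non-missing
#' report/target pairs and computes sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and overall concordance `(tp+tn)/n`. The reporting view
#' (`print`) rounds to whole percent, half-up, matching how such rates are
#' printed in proficiency-trial summaries.
#'
#' @param reports report table (all laboratories) or `NULL` when `counts`
#'   are given directly.
#' @param targets target-vote table (required with `reports`).
#' @param counts alternatively, a named vector/list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return an object of class `"confusion_stats"`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `concordance` (fractions, full precision).
#' @examples
#' cs <- confusion_stats(counts = c(tp = 1488, fn = 16, tn = 141, fp = 34))
#' print(cs)  # sensitivity 99%, specificity 81%, concordance 97%
#' @export
confusion_stats <- function(reports = NULL, targets = NULL, counts = NULL) {
  if (is.null(counts)) {
    scored <- score_reports(reports, targets)
    scored <- scored[scored$status != "missing", , drop = FALSE]
    if (nrow(scored) == 0L) stop_input("no report/target pairs to tabulate")
    counts <- c(
      tp = sum(scored$status == "positive" & scored$target_status == "positive"),
      fp = sum(scored$status == "positive" & scored$target_status == "negative"),
      tn = sum(scored$status == "negative" & scored$target_status == "negative"),
      fn = sum(scored$status == "negative" & scored$target_status == "positive"))
  }
  counts <- as.list(counts)
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts)))
    stop_input("counts must provide tp, fp, tn, fn")
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0) stop_input("no report/target pairs to tabulate")
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         concordance = (tp + tn) / (tp + fp + tn + fn)),
    class = "confusion_stats"
  )
}

#' @export
print.confusion_stats <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%d%%", round_half_up(100 * v))
  cat(sprintf(
    "Positivity call agreement (n = %d pairs)\n  tp = %d, fp = %d, tn = %d, fn = %d\n  sensitivity %s, specificity %s, concordance %s\n",
    x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn,
    pct(x$sensitivity), pct(x$specificity), pct(x$concordance)))
  invisible(x)
}

#' Outlier summary by laboratory group with a between-group exact test
#'
#' Pools scored verdicts by laboratory group (e.g. long-term reference
#' consortium vs newer associated laboratories), reports submitted counts,
#' outlier counts and percentages (printed 1 decimal, half-up), and tests
#' between-group homogeneity with an exact test: two-sided Fisher for two
#' groups, Freeman-Halton for more.
#'
#' The 2 x k test table has one row per group. With
#' `table_style = "vs_concordant"` the columns are (outliers, concordant) —
#' the statistically standard construction. `"vs_submitted"` uses
#' (outliers, submitted) instead, i.e. the outlier count against the group's
#' full submission total; this reproduces how the headline between-group
#' p-value of the multi-year external-QA evaluation was computed (entering
#' "11 of 487 vs 67 of 1192" directly as table cells). Both are exposed;
#' see the methods vignette for the numerical consequences.
#'
#' @param scored scored report table from [score_reports()] (or the
#'   `verdicts` element of a [ring_trial_eval()]).
#' @param groups `data.frame` with columns `lab_id`, `group` mapping every
#'   laboratory to exactly one group.
#' @param table_style test-table construction, see Details.
#' @return an object of class `"group_summary"`: `by_group` data.frame
#'   (`group`, `n_submitted`, `n_outliers`, `outlier_percent`), `total` row,
#'   `p_value`, `method`, `table_style`.
#' @export
group_outlier_summary <- function(scored, groups,
                                  table_style = c("vs_concordant", "vs_submitted")) {
  table_style <- match.arg(table_style)
  if (!all(c("lab_id", "group") %in% names(groups)))
    stop_input("groups must have columns lab_id, group")
  if (anyDuplicated(groups$lab_id))
    stop_input("a laboratory is mapped to more than one group")
  scored <- scored[scored$status != "missing", , drop = FALSE]
  g <- groups$group[match(scored$lab_id, groups$lab_id)]
  if (anyNA(g)) {
    bad <- unique(scored$lab_id[is.na(g)])
    stop_input("laboratory not mapped to a group: %s", paste(bad, collapse = ", "))
  }
  lv <- unique(groups$group)
  n_sub <- vapply(lv, function(x) sum(g == x), integer(1))
  n_out <- vapply(lv, function(x) sum(g == x & scored$category != "concordant"),
                  integer(1))
  keep <- n_sub > 0
  lv <- lv[keep]; n_sub <- n_sub[keep]; n_out <- n_out[keep]
  by_group <- data.frame(group = lv, n_submitted = n_sub, n_outliers = n_out,
                         outlier_percent = round_half_up(100 * n_out / n_sub, 1),
                         stringsAsFactors = FALSE)
  total <- data.frame(group = "total", n_submitted = sum(n_sub),
                      n_outliers = sum(n_out),
                      outlier_percent = round_half_up(100 * sum(n_out) / sum(n_sub), 1),
                      stringsAsFactors = FALSE)
  tab <- outlier_test_table(n_out, n_sub, table_style)
  test <- if (length(lv) < 2) {
    list(p_value = NA_real_, method = "none")
  } else if (length(lv) == 2) {
    fisher_2x2(tab)
  } else {
    freeman_halton_2xc(t(tab))
  }
  structure(list(by_group = by_group, total = total,
                 p_value = test$p_value, method = test$method,
                 table_style = table_style, test_table = tab),
            class = "group_summary")
}

# rows = groups; columns = (outliers, second column per style)
outlier_test_table <- function(n_out, n_sub, table_style) {
  second <- if (table_style == "vs_concordant") n_sub - n_out else n_sub
  cbind(outliers = n_out, other = second)
}

#' @export
print.group_summary <- function(x, ...) {
  df <- rbind(x$by_group, x$total)
  print(df, row.names = FALSE)
  if (!is.na(x$p_value))
    cat(sprintf("Between-group %s (columns: %s): p = %.4g\n",
                x$method,
                if (x$table_style == "vs_concordant") "outliers vs concordant"
                else "outliers vs submitted totals",
                x$p_value))
  invisible(x)
}

#' Screen for samples misassessed by several centres
#'
#' Samples wrongly assessed by at least `min_centers` laboratories are
#' flagged for error analysis (typical causes: excess hematogones mimicking
#' blasts on regenerating marrow, missing mature-B reference populations,
#' CD34-dim precursors, rare phenotypes, very low MRD near the detection
#' limit). Cause labels are annotations supplied by the reviewer, never
#' inferred.
#'
#' @param scored scored report table from [score_reports()].
#' @param min_centers minimum number of misassessing laboratories (default 3).
#' @return `data.frame` with `sample_id`, `n_errors`, `n_assessed`, sorted by
#'   descending error count; zero rows when nothing is flagged.
#' @export
sample_error_screen <- function(scored, min_centers = 3) {
  if (length(min_centers) != 1L || min_centers < 1)
    stop_input("min_centers must be >= 1")
  assessed <- scored[scored$status != "missing", , drop = FALSE]
  ids <- unique(assessed$sample_id)
  n_err <- vapply(ids, function(s)
    sum(assessed$sample_id == s & assessed$category != "concordant"), integer(1))
  n_ass <- vapply(ids, function(s) sum(assessed$sample_id == s), integer(1))
  out <- data.frame(sample_id = ids, n_errors = n_err, n_assessed = n_ass,
                    stringsAsFactors = FALSE)
  out <- out[out$n_errors >= min_centers, , drop = FALSE]
  out <- out[order(-out$n_errors, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a complete ring trial
#'
#' The central evaluator: computes (or accepts) consensus target votes,
#' scores every report against the concordance margin, summarises each
#' laboratory with its pass/warning/critical flag, tabulates
#' positive/negative call agreement, and — when a group mapping is given —
#' the between-group outlier comparison.
#'
#' @param reports report table covering all laboratories (see [mrd_reports()]
#'   or [read_bundle()]).
#' @param consensus `"reference"` (median of `reference_labs`) or `"all"`
#'   (median of all submitters).
#' @param reference_labs reference laboratory ids for
#'   `consensus = "reference"`.
#' @param targets optional precomputed target-vote table; overrides
#'   `consensus`.
#' @param groups optional `data.frame(lab_id, group)` for the group summary.
#' @param margin_factor concordance-margin factor (default 3).
#' @param positivity a [positivity_rule()].
#' @param min_centers threshold for the sample-level error screen.
#' @return an object of class `"ring_trial_eval"` with elements `labs`
#'   (per-laboratory performance table), `verdicts` (scored reports),
#'   `targets`, `confusion` ([confusion_stats()]), `groups`
#'   ([group_outlier_summary()] or `NULL`), `flagged_samples`,
#'   `margin_factor`.
#' @examples
#' sim <- simulate_ring_trial(n_labs = 8, n_samples = 6, seed = 1)
#' fit <- ring_trial_eval(sim$reports, consensus = "reference",
#'                        reference_labs = sim$reference_labs)
#' summary(fit)
#' @export
ring_trial_eval <- function(reports,
                            consensus = c("reference", "all"),
                            reference_labs = NULL,
                            targets = NULL,
                            groups = NULL,
                            margin_factor = 3,
                            positivity = positivity_rule(),
                            min_centers = 3) {
  reports <- validate_reports(reports)
  if (is.null(targets)) {
    targets <- target_votes(reports, consensus = consensus,
                            reference_labs = reference_labs,
                            positivity = positivity)
  }
  scored <- score_reports(reports, targets, margin_factor)
  labs <- do.call(rbind, lapply(split(reports, reports$lab_id), evaluate_lab,
                                targets = targets, margin_factor = margin_factor))
  labs <- labs[order(labs$lab_id), , drop = FALSE]
  rownames(labs) <- NULL
  grp <- if (!is.null(groups)) group_outlier_summary(scored, groups) else NULL
  structure(
    list(labs = labs, verdicts = scored, targets = targets,
         confusion = confusion_stats(reports, targets),
         groups = grp,
         flagged_samples = sample_error_screen(scored, min_centers),
         margin_factor = margin_factor),
    class = "ring_trial_eval"
  )
}

#' @export
print.ring_trial_eval <- function(x, ...) {
  n_lab <- nrow(x$labs)
  n_rep <- sum(x$verdicts$status != "missing")
  n_false <- sum(x$verdicts$status != "missing" &
                   x$verdicts$category != "concordant")
  cat(sprintf("Ring-trial evaluation: %d laboratories, %d samples, %d assessed reports\n",
              n_lab, nrow(x$targets), n_rep))
  cat(sprintf("  false assessments: %d (%s%%), margin factor %g\n",
              n_false, format(round_half_up(100 * n_false / n_rep, 1)),
              x$margin_factor))
  fl <- table(factor(x$labs$flag, levels = c("pass", "warning", "critical")))
  cat(sprintf("  flags: %d pass, %d warning, %d critical\n",
              fl[["pass"]], fl[["warning"]], fl[["critical"]]))
  invisible(x)
}

#' @export
summary.ring_trial_eval <- function(object, ...) {
  print(object)
  cat("\nPer-laboratory performance:\n")
  print(object$labs, row.names = FALSE)
  cat("\n")
  print(object$confusion)
  if (!is.null(object$groups)) {
    cat("\nGroup comparison:\n")
    print(object$groups)
  }
  if (nrow(object$flagged_samples)) {
    cat("\nSamples misassessed by several centres:\n")
    print(object$flagged_samples, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.ring_trial_eval <- function(x, ...) {
  cols <- c(pass = "#4daf4a", warning = "#ffb300", critical = "#e41a1c")
  frac <- x$labs$false_fraction
  graphics::barplot(100 * frac, names.arg = x$labs$lab_id, las = 2,
                    col = cols[x$labs$flag], border = NA,
                    ylab = "false assessments [%]",
                    main = "Ring-trial performance by laboratory", ...)
  graphics::abline(h = c(10, 25), lty = 2, col = "grey40")
  invisible(x)
}

#' Write ring-trial evaluation tables to disk
#'
#' Emits the per-laboratory table, the per-sample table and a JSON trial
#' summary (flags, confusion counts, group comparison) with deterministic
#' field order, so re-running on identical input produces byte-identical
#' files.
#'
#' @param eval_obj a [ring_trial_eval()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (`labs_summary.csv`,
#'   `samples_summary.csv`, `trial_summary.json`).
#' @export
ring_trial_report <- function(eval_obj, dir) {
  stopifnot(inherits(eval_obj, "ring_trial_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labs_path <- file.path(dir, "labs_summary.csv")
  samples_path <- file.path(dir, "samples_summary.csv")
  json_path <- file.path(dir, "trial_summary.json")
  write_csv_deterministic(eval_obj$labs, labs_path)
  per_sample <- merge(eval_obj$targets,
                      aggregate_sample_errors(eval_obj$verdicts),
                      by = "sample_id", sort = TRUE)
  write_csv_deterministic(per_sample, samples_path)
  summary_list <- list(
    n_labs = nrow(eval_obj$labs),
    n_samples = nrow(eval_obj$targets),
    margin_factor = eval_obj$margin_factor,
    flags = as.list(table(factor(eval_obj$labs$flag,
                                 levels = c("pass", "warning", "critical")))),
    confusion = eval_obj$confusion[c("tp", "fp", "tn", "fn")],
    labs = eval_obj$labs
  )
  if (!is.null(eval_obj$groups)) {
    summary_list$groups <- list(
      by_group = eval_obj$groups$by_group,
      total = eval_obj$groups$total,
      p_value = eval_obj$groups$p_value,
      method = eval_obj$groups$method)
  }
  jsonlite::write_json(summary_list, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(labs_path, samples_path, json_path))
}

aggregate_sample_errors <- function(scored) {
  assessed <- scored[scored$status != "missing", , drop = FALSE]
  ids <- sort(unique(scored$sample_id))
  data.frame(
    sample_id = ids,
    n_assessed = vapply(ids, function(s) sum(assessed$sample_id == s), integer(1)),
    n_errors = vapply(ids, function(s)
      sum(assessed$sample_id == s & assessed$category != "concordant"), integer(1)),
    stringsAsFactors = FALSE)
}
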
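# Day-15 flow-MRD risk classification (FLR/FMR/FHR) and cross-centre
# cohort distribution summaries.

#' Risk-group thresholds for day-15 bone-marrow blast percentage
#'
#' Flow low risk (FLR): blasts at most `flr_max` percent (default 0.1);
#' flow high risk (FHR): at least `fhr_min` percent (default 10);
#' flow medium risk (FMR): in between. Both boundaries are inclusive on the
#' outer classes.
#'
#' @param flr_max upper (inclusive) FLR bound in percent.
#' @param fhr_min lower (inclusive) FHR bound in percent.
#' @return an object of class `"risk_thresholds"`.
#' @export
risk_thresholds <- function(flr_max = 0.1, fhr_min = 10) {
  if (!(flr_max > 0 && flr_max < fhr_min))
    stop_input("need 0 < flr_max < fhr_min, got %g, %g", flr_max, fhr_min)
  structure(list(flr_max = flr_max, fhr_min = fhr_min),
            class = "risk_thresholds")
}

#' Classify day-15 blast percentages into FLR/FMR/FHR
#'
#' No rounding is applied before comparison: the raw flow-cytometric blast
#' percentage is compared directly to the thresholds.
#'
#' @param d15_blast_percent non-negative blast percentage(s) of nucleated
#'   bone-marrow cells at day 15 of induction.
#' @param thresholds a [risk_thresholds()].
#' @return character vector in `{"FLR", "FMR", "FHR"}`.
#' @examples
#' classify_risk(c(0.1, 5, 10))  # FLR, FMR, FHR (boundaries inclusive outward)
#' @export
classify_risk <- function(d15_blast_percent, thresholds = risk_thresholds()) {
  if (any(is.na(d15_blast_percent)) || any(d15_blast_percent < 0))
    stop_input("blast percentages must be non-negative")
  ifelse(d15_blast_percent <= thresholds$flr_max, "FLR",
         ifelse(d15_blast_percent >= thresholds$fhr_min, "FHR", "FMR"))
}

#' Per-centre risk-group distributions and a homogeneity test
#'
#' Tabulates FLR/FMR/FHR counts and fractions per centre and tests whether
#' the centres' distributions are homogeneous. Small tables (total patients
#' at most `exact_max_n`) use the exact conditional test
#' ([stats::fisher.test()] on the r x 3 count table); larger cohorts use the
#' chi-square test of homogeneity. The method used is recorded in the
#' result. Centres with zero patients are excluded with a warning.
#'
#' @param center_id centre identifier per patient.
#' @param risk_class risk class per patient (`"FLR"`, `"FMR"`, `"FHR"`), e.g.
#'   from [classify_risk()].
#' @param exact_max_n largest total count for which the exact test is used.
#' @return an object of class `"cohort_distribution"`: `counts` (centre x
#'   class matrix), `fractions`, `p_value`, `method`.
#' @export
cohort_distribution <- function(center_id, risk_class, exact_max_n = 200) {
  lev <- c("FLR", "FMR", "FHR")
  bad <- setdiff(unique(risk_class), lev)
  if (length(bad))
    stop_input("unknown risk class: %s", paste(bad, collapse = ", "))
  center <- if (is.factor(center_id)) center_id else factor(as.character(center_id))
  counts <- table(center = center, class = factor(risk_class, levels = lev))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("excluding centre(s) with zero patients: ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  counts <- unclass(counts)
  fractions <- counts / rowSums(counts)
  nonzero_cols <- colSums(counts) > 0
  test_tab <- counts[, nonzero_cols, drop = FALSE]
  if (nrow(test_tab) < 2 || ncol(test_tab) < 2) {
    p <- NA_real_; method <- "none"
  } else if (sum(counts) <= exact_max_n) {
    p <- stats::fisher.test(test_tab, workspace = 2e7)$p.value
    method <- "exact_rxc"
  } else {
    p <- suppressWarnings(stats::chisq.test(test_tab)$p.value)
    method <- "chi_square"
  }
  structure(list(counts = counts, fractions = fractions,
                 p_value = p, method = method),
            class = "cohort_distribution")
}

#' @export
print.cohort_distribution <- function(x, ...) {
  cat(sprintf("Risk-group distribution over %d centres (%d patients)\n",
              nrow(x$counts), sum(x$counts)))
  print(round(x$fractions, 3))
  if (!is.na(x$p_value))
    cat(sprintf("Homogeneity: %s p = %.4g\n", x$method, x$p_value))
  invisible(x)
}
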
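test_that("flag thresholds are strict 'more than' bounds", {
  expect_equal(assign_flag(2 / 20), "pass")
  expect_equal(assign_flag(3 / 20), "warning")
  expect_equal(assign_flag(5 / 20), "warning")  # exactly 25%
  expect_equal(assign_flag(6 / 20), "critical")
  expect_error(assign_flag(1.2), "\\[0, 1\\]")
  expect_error(assign_flag(-0.1), "\\[0, 1\\]")
  # monotone non-decreasing in the false fraction
  lv <- c(pass = 0, warning = 1, critical = 2)
  expect_true(all(diff(lv[assign_flag(seq(0, 1, by = 0.01))]) >= 0))
})

test_that("evaluate_lab counts false assessments and excludes missing", {
  targets <- panel_targets()
  clean <- reports_matching_targets("LAB", targets)
  perf <- evaluate_lab(clean, targets)
  expect_equal(perf$n_false, 0L)
  expect_equal(perf$flag, "pass")
  expect_equal(perf$n_assessed, 20L)

  # 3 of 20 reports at 4x the (positive) target: warning
  warn <- clean
  idx <- which(targets$status == "positive")[1:3]
  warn$value_percent[idx] <- targets$value_percent[idx] * 4
  perf_w <- evaluate_lab(warn, targets)
  expect_equal(perf_w$n_false, 3L)
  expect_equal(perf_w$flag, "warning")

  # 6 false positives on negative targets: critical
  crit <- clean
  neg_idx <- which(targets$status == "negative")[1:6]
  crit$status[neg_idx] <- "positive"
  crit$value_percent[neg_idx] <- 0.2
  perf_c <- evaluate_lab(crit, targets)
  expect_equal(perf_c$n_false, 6L)
  expect_equal(perf_c$flag, "critical")

  # missing reports shrink the denominator but are tallied
  miss <- clean
  miss$status[1:4] <- "missing"
  miss$value_percent[1:4] <- NA
  perf_m <- evaluate_lab(miss, targets)
  expect_equal(perf_m$n_assessed, 16L)
  expect_equal(perf_m$n_missing, 4L)

  all_miss <- clean
  all_miss$status <- "missing"
  all_miss$value_percent <- NA
  expect_error(evaluate_lab(all_miss, targets), "assessed no samples")
})

test_that("confusion statistics reproduce their defining ratios", {
  cs <- confusion_stats(counts = c(tp = 1488, fn = 16, tn = 141, fp = 34))
  expect_equal(cs$sensitivity, 1488 / 1504)
  expect_equal(cs$specificity, 141 / 175)
  expect_equal(cs$concordance, 1629 / 1679)
  expect_equal(round_half_up(100 * cs$sensitivity), 99)
  expect_equal(round_half_up(100 * cs$specificity), 81)
  expect_equal(round_half_up(100 * cs$concordance), 97)

  targets <- panel_targets()
  clean <- reports_matching_targets(c("A", "B"), targets)
  cs2 <- confusion_stats(clean, targets)
  expect_equal(cs2$sensitivity, 1)
  expect_equal(cs2$specificity, 1)
  expect_equal(cs2$concordance, 1)
  # counts partition the pairs
  expect_equal(cs2$tp + cs2$fp + cs2$tn + cs2$fn, 40)

  cs3 <- confusion_stats(counts = c(tp = 0, fn = 1, tn = 0, fp = 0))
  expect_equal(cs3$sensitivity, 0)
})

test_that("group outlier summary recovers counts, percents and the exact test", {
  scored <- scored_with_outliers(c(A = 487, B = 1192), c(A = 11, B = 67))
  gs <- group_outlier_summary(scored, group_map(c(A = 1, B = 1)))
  expect_equal(gs$by_group$n_submitted, c(487, 1192))
  expect_equal(gs$by_group$n_outliers, c(11, 67))
  expect_equal(gs$by_group$outlier_percent, c(2.3, 5.6))
  expect_equal(gs$total$outlier_percent, 4.6)
  # outliers-vs-concordant table: matches the reference implementation
  expect_equal(gs$p_value,
               stats::fisher.test(matrix(c(11, 476, 67, 1125), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # outliers-vs-submitted-totals construction
  gs2 <- group_outlier_summary(scored, group_map(c(A = 1, B = 1)),
                               table_style = "vs_submitted")
  expect_equal(gs2$p_value,
               stats::fisher.test(matrix(c(11, 487, 67, 1192), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)

  identical_groups <- scored_with_outliers(c(A = 50, B = 50), c(A = 5, B = 5))
  gs3 <- group_outlier_summary(identical_groups, group_map(c(A = 1, B = 1)))
  expect_equal(gs3$p_value, 1)

  three <- scored_with_outliers(c(A = 12, B = 12, C = 12), c(A = 1, B = 4, C = 8))
  gs4 <- group_outlier_summary(three, group_map(c(A = 1, B = 1, C = 1)))
  tab <- rbind(c(1, 4, 8), c(11, 8, 4))
  expect_equal(gs4$p_value, brute_force_exact_p(tab), tolerance = 1e-10)

  expect_error(group_outlier_summary(scored, group_map(c(A = 1))),
               "not mapped")
})

test_that("per-lab false counts sum to the pooled outlier total", {
  sim <- simulate_ring_trial(n_labs = 12, n_samples = 15, seed = 99)
  fit <- ring_trial_eval(sim$reports, consensus = "reference",
                         reference_labs = sim$reference_labs,
                         groups = sim$groups)
  expect_equal(sum(fit$labs$n_false),
               fit$groups$total$n_outliers)
  expect_equal(sum(fit$labs$n_assessed),
               fit$groups$total$n_submitted)
  # confusion counts partition all assessed pairs
  with(fit$confusion, expect_equal(tp + fp + tn + fn, sum(fit$labs$n_assessed)))
  # flags recompute from fractions
  expect_equal(fit$labs$flag, assign_flag(fit$labs$false_fraction))
})

test_that("sample-level screen flags samples misassessed by several centres", {
  targets <- panel_targets()
  labs <- sprintf("L%02d", 1:41)
  reports <- reports_matching_targets(labs, targets)
  # sample S01 wrong in 6 labs, S02 wrong in 2
  bad1 <- reports$sample_id == "S01" & reports$lab_id %in% labs[1:6]
  reports$value_percent[bad1] <- targets$value_percent[1] * 10
  bad2 <- reports$sample_id == "S02" & reports$lab_id %in% labs[1:2]
  reports$value_percent[bad2] <- targets$value_percent[2] * 10
  scored <- mrdqc:::score_reports(reports, targets)
  flagged <- sample_error_screen(scored, min_centers = 3)
  expect_equal(flagged$sample_id, "S01")
  expect_equal(flagged$n_errors, 6L)
  expect_equal(nrow(sample_error_screen(scored, min_centers = 1)), 2)
  clean_scored <- mrdqc:::score_reports(reports_matching_targets(labs, targets),
                                        targets)
  expect_equal(nrow(sample_error_screen(clean_scored, 3)), 0)
  expect_error(sample_error_screen(scored, min_centers = 0), ">= 1")
})

test_that("ring_trial_report writes deterministic summaries", {
  sim <- simulate_ring_trial(n_labs = 8, n_samples = 10, seed = 5)
  fit <- ring_trial_eval(sim$reports, consensus = "reference",
                         reference_labs = sim$reference_labs,
                         groups = sim$groups)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ring_trial_report(fit, d1)
  ring_trial_report(fit, d2)
  for (f in c("labs_summary.csv", "samples_summary.csv", "trial_summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  js <- jsonlite::read_json(file.path(d1, "trial_summary.json"))
  expect_length(js$labs, 8)
  expect_equal(js$flags$pass + js$flags$warning + js$flags$critical, 8)
})
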
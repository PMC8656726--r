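test_that("maturation state machine reproduces the rule examples", {
  for (variant in c("window", "penalty", "conjunction")) {
    cfg <- maturation_config(rule_variant = variant)
    expect_equal(cases_to_maturation(rep(FALSE, 30), cfg), 25L)
  }
  # single error at case 14: trailing-12-clean first holds at case 26
  win <- maturation_config(rule_variant = "window")
  expect_equal(cases_to_maturation(error_indices = 14, n_cases = 40,
                                   config = win), 26L)
  # single error at case 20 under the +3 rule: min_cases binds (20+3 < 25)
  pen <- maturation_config(rule_variant = "penalty")
  expect_equal(cases_to_maturation(error_indices = 20, n_cases = 40,
                                   config = pen), 25L)
  # first-half errors never extend the series
  expect_equal(cases_to_maturation(error_indices = 5, n_cases = 40,
                                   config = win), 25L)
  expect_equal(cases_to_maturation(error_indices = 5, n_cases = 40,
                                   config = pen), 25L)
  # conjunction requires both readings
  con <- maturation_config()
  expect_equal(cases_to_maturation(error_indices = 20, n_cases = 40,
                                   config = con), 32L)  # window binds: 20+12
})

test_that("is_matured tracks the state and update enforces sequencing", {
  st <- maturation_state("L1")
  expect_false(is_matured(st))
  for (i in 1:25) st <- maturation_update(st, case_outcome(i))
  expect_true(is_matured(st))
  expect_equal(st$matured_at, 25L)
  expect_error(maturation_update(st, case_outcome(26)), "already matured")

  st2 <- maturation_state("L2")
  expect_error(maturation_update(st2, case_outcome(3)), "out-of-order")

  # error at case 25 keeps the window dirty through case 30
  st3 <- maturation_state("L3")
  for (i in 1:30) st3 <- maturation_update(
    st3, case_outcome(i, gross_error = i == 25),
    maturation_config(rule_variant = "window"))
  expect_false(is_matured(st3))
})

test_that("case outcomes validate the error-type contract", {
  expect_error(case_outcome(1, FALSE, "misdocumentation"), "without gross_error")
  expect_silent(case_outcome(1, TRUE, "blast_population"))
})

test_that("window variant equals its closed form over random error patterns", {
  # Iterative closed form: starting from min_cases, each error occurring at
  # or before the provisional maturation case pushes it to error + 12;
  # errors later than that never happen (the series has ended).
  window_closed_form <- function(errs) {
    m <- 25
    for (e in sort(errs)) if (e <= m) m <- max(m, e + 12)
    m
  }
  cfg <- maturation_config(rule_variant = "window")
  set.seed(314)
  for (i in 1:300) {
    errs <- sort(sample(1:45, sample(0:6, 1)))
    expect_equal(cases_to_maturation(error_indices = errs, n_cases = 100,
                                     config = cfg), window_closed_form(errs))
  }
})

test_that("penalty variant matches an independent scan of its definition", {
  cfg <- maturation_config(rule_variant = "penalty")
  # scan candidate completion cases, considering only errors observed so far
  penalty_oracle <- function(errs) {
    for (n in 25:200) {
      seen <- errs[errs <= n]
      second_half <- seen[seen >= 14]
      gate <- if (length(second_half)) max(second_half) + 3 else 0
      if (n >= max(25, gate) && !any(seen > n - 3)) return(n)
    }
    NA_integer_
  }
  set.seed(2718)
  for (i in 1:200) {
    errs <- sort(sample(1:45, sample(0:6, 1)))
    expect_equal(cases_to_maturation(error_indices = errs, n_cases = 200,
                                     config = cfg), penalty_oracle(errs))
  }
})

test_that("an additional error before completion never hastens maturation", {
  cfg <- maturation_config(rule_variant = "window")
  set.seed(161)
  for (i in 1:50) {
    errs <- sort(sample(1:40, sample(0:4, 1)))
    base <- cases_to_maturation(error_indices = errs, n_cases = 150,
                                config = cfg)
    extra <- sample(seq_len(base), 1)
    more <- cases_to_maturation(error_indices = unique(c(errs, extra)),
                                n_cases = 150, config = cfg)
    expect_gte(more, base)
  }
})

test_that("series breakdown pools the reporting windows correctly", {
  log <- table2_style_log()
  bd <- series_breakdown(log)
  w <- bd$windows
  expect_equal(w$n_results, c(550, 286, 264, 396, 682))
  expect_equal(w$n_failures, c(67, 42, 25, 37, 79))
  expect_equal(w$failure_percent, c(12.2, 14.7, 9.5, 9.3, 11.6))
  # series 1 + series 2 partition the main set
  expect_equal(w$n_results[2] + w$n_results[3], w$n_results[1])
  expect_equal(w$n_failures[2] + w$n_failures[3], w$n_failures[1])
  # early-vs-late contrast is an exact 2x2 test
  expect_equal(bd$p_value,
               stats::fisher.test(matrix(c(42, 244, 37, 359), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)

  single <- data.frame(lab_id = "L1", case_index = 1:25, gross_error = 0)
  bd2 <- suppressWarnings(series_breakdown(single))  # all-clean: degenerate test table
  expect_true(all(bd2$windows$failure_percent == 0))
  expect_error(series_breakdown(single[0, ]), "empty")
})

test_that("maturation_series replays whole logs per laboratory", {
  log <- rbind(
    data.frame(lab_id = "L1", lineage = "B", case_index = 1:25, gross_error = 0),
    data.frame(lab_id = "L2", lineage = "B", case_index = 1:40,
               gross_error = as.integer(1:40 == 20)))
  fit <- maturation_series(log)
  expect_equal(fit$summary$matured, c(TRUE, TRUE))
  expect_equal(fit$summary$matured_at[fit$summary$lab_id == "L1"], 25L)
  expect_equal(fit$summary$matured_at[fit$summary$lab_id == "L2"], 32L)
  expect_output(print(fit), "2 matured")
})
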
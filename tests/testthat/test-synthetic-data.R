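test_that("sample simulation honours the negative fraction and the MRD range", {
  all_neg <- simulate_samples(simulation_config(n_samples = 50,
                                                neg_fraction = 1, seed = 3))
  expect_true(all(all_neg$true_mrd_percent == 0))

  cfg <- simulation_config(n_samples = 101, neg_fraction = 53 / 101, seed = 8)
  s <- simulate_samples(cfg)
  n_neg <- sum(s$true_mrd_percent == 0)
  # within 4 binomial SDs of the expectation 53
  expect_lt(abs(n_neg - 53), 4 * sqrt(101 * (53 / 101) * (48 / 101)))
  pos <- s$true_mrd_percent[s$true_mrd_percent > 0]
  expect_true(all(pos >= cfg$mrd_log_range[1] & pos <= cfg$mrd_log_range[2]))
  expect_true(all(s$regeneration_level >= 0 & s$regeneration_level <= 1))

  expect_identical(simulate_samples(cfg), simulate_samples(cfg))
  expect_error(simulation_config(mrd_log_range = c(1e-5, 10)),
               "below positivity threshold")
  expect_error(simulation_config(neg_fraction = 2), "\\[0, 1\\]")
})

test_that("the reporting model has the stated noiseless and degenerate limits", {
  sample_pos <- data.frame(sample_id = "S1", regeneration_level = 0.5,
                           true_mrd_percent = 1.0)
  lab0 <- lab_profile("L0", sigma_log = 0, fp_base = 0, fn_steepness = 50)
  r <- simulate_reports(lab0, sample_pos, seed = 1)
  expect_equal(r$status, "positive")
  expect_equal(r$value_percent, 1.0)

  sample_neg <- data.frame(sample_id = "S2", regeneration_level = 0.9,
                           true_mrd_percent = 0)
  for (seed in 1:10) {
    r2 <- simulate_reports(lab0, sample_neg, seed = seed)
    expect_equal(r2$status, "negative")
  }
})

test_that("expected_discordance is the lognormal closed form", {
  expect_equal(expected_discordance(log(3)), 2 * (1 - stats::pnorm(1)))
  expect_equal(expected_discordance(log(3) / 1.6449), 0.10, tolerance = 1e-4)
  expect_lt(expected_discordance(0.01), 1e-10)  # sigma -> 0 limit
  expect_error(expected_discordance(0), "> 0")
})

test_that("empirical margin discordance matches the closed form at large n", {
  sigma <- 0.5
  n <- 1e5
  lab <- lab_profile("L", sigma_log = sigma, fp_base = 0, fn_steepness = 50)
  samples <- data.frame(sample_id = sprintf("S%06d", 1:n),
                        regeneration_level = 0.5,
                        true_mrd_percent = 1.0)
  r <- simulate_reports(lab, samples, seed = 77)
  ratio <- r$value_percent / samples$true_mrd_percent
  emp <- mean(ratio > 3 | ratio < 1 / 3)
  expected <- expected_discordance(sigma)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(emp - expected), 3 * se)
})

test_that("sigma recovery is accurate and tightens with n", {
  lab <- lab_profile("L", sigma_log = 0.4, fp_base = 0, fn_steepness = 50)
  make_pairs <- function(n, seed) {
    samples <- data.frame(sample_id = sprintf("S%05d", 1:n),
                          regeneration_level = 0.5, true_mrd_percent = 2.0)
    r <- simulate_reports(lab, samples, seed = seed)
    estimate_sigma(r$value_percent, samples$true_mrd_percent)
  }
  expect_lt(abs(make_pairs(500, 5) - 0.4), 0.05)
  err_big <- mean(abs(vapply(1:5, function(s) make_pairs(10000, s), 1) - 0.4))
  expect_lt(err_big, 0.02)

  noiseless <- lab_profile("L", sigma_log = 0, fp_base = 0, fn_steepness = 50)
  samples <- data.frame(sample_id = sprintf("S%03d", 1:50),
                        regeneration_level = 0.5, true_mrd_percent = 1)
  r0 <- simulate_reports(noiseless, samples, seed = 1)
  expect_equal(estimate_sigma(r0$value_percent, samples$true_mrd_percent), 0)
  expect_error(estimate_sigma(1, 1), "positive pairs")
})

test_that("simulated ring trials are deterministic and lab-stable", {
  a <- simulate_ring_trial(n_labs = 41, n_samples = 20, seed = 2)
  expect_equal(nrow(a$reports), 41 * 20)
  b <- simulate_ring_trial(n_labs = 41, n_samples = 20, seed = 2)
  expect_identical(a, b)
  # adding laboratories must not reshuffle existing ones
  small <- simulate_ring_trial(n_labs = 10, n_samples = 20, seed = 2)
  expect_identical(small$reports[small$reports$lab_id == "L03", ],
                   a$reports[a$reports$lab_id == "L03", ])
})

test_that("noiseless laboratories all pass; a high-FP laboratory goes critical", {
  perfect <- lapply(sprintf("P%02d", 1:8), lab_profile,
                    sigma_log = 0, fp_base = 0, fn_steepness = 50)
  sim <- simulate_ring_trial(perfect, config = simulation_config(
    n_labs = 8, n_samples = 20, seed = 4))
  fit <- ring_trial_eval(sim$reports, consensus = "reference",
                         reference_labs = sim$reference_labs)
  expect_true(all(fit$labs$flag == "pass"))
  expect_equal(sum(fit$labs$n_false), 0)

  labs <- c(perfect,
            list(lab_profile("BAD", sigma_log = 0, fp_base = 0.5,
                             fn_steepness = 50)))
  sim2 <- simulate_ring_trial(labs, config = simulation_config(
    n_labs = 9, n_samples = 20, neg_fraction = 0.5, seed = 11),
    reference_lab_ids = sprintf("P%02d", 1:6))
  fit2 <- ring_trial_eval(sim2$reports, consensus = "reference",
                          reference_labs = sim2$reference_labs)
  expect_equal(fit2$labs$flag[fit2$labs$lab_id == "BAD"], "critical")
})

test_that("maturation series follow the learning curve", {
  clean_lab <- lab_profile("C", e0 = 0, e_inf = 0)
  log <- simulate_maturation_series(clean_lab, n_cases = 30, seed = 1)
  expect_true(all(log$gross_error == 0))
  expect_equal(suppressWarnings(maturation_series(log))$summary$matured_at, 25L)

  hopeless <- lab_profile("H", e0 = 1, e_inf = 1)
  log2 <- simulate_maturation_series(hopeless, n_cases = 25, seed = 1)
  expect_true(all(log2$gross_error == 1))
  fit2 <- suppressWarnings(maturation_series(
    log2, maturation_config(rule_variant = "window")))
  expect_false(fit2$summary$matured)

  # pooled early vs late error rates reflect the declining curve
  lab <- lab_profile("T", e0 = 0.147, e_inf = 0.093, tau = 8)
  logs <- do.call(rbind, lapply(1:22, function(i) {
    l <- simulate_maturation_series(lab, n_cases = 40, seed = 100 + i)
    l$lab_id <- sprintf("T%02d", i)
    l
  }))
  early <- mean(logs$gross_error[logs$case_index <= 13])
  late <- mean(logs$gross_error[logs$case_index >= 14])
  expect_gt(early, late)
})
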
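# Fixtures built in code: no data files.

# Report table where every lab reports exactly the target values.
# targets: data.frame(sample_id, status, value_percent)
reports_matching_targets <- function(lab_ids, targets) {
  do.call(rbind, lapply(lab_ids, function(l) {
    data.frame(lab_id = l, sample_id = targets$sample_id,
               status = targets$status,
               value_percent = ifelse(targets$status == "positive",
                                      targets$value_percent, NA_real_),
               stringsAsFactors = FALSE)
  }))
}

# A 20-sample target panel: 12 positive (spread over the reportable range),
# 8 negative.
panel_targets <- function() {
  pos_vals <- signif(exp(seq(log(0.01), log(10), length.out = 12)), 3)
  data.frame(
    sample_id = sprintf("S%02d", 1:20),
    status = c(rep("positive", 12), rep("negative", 8)),
    value_percent = c(pos_vals, rep(NA_real_, 8)),
    n_contributors = 6L, rule = "reference_median",
    stringsAsFactors = FALSE)
}

# Pooled 22-laboratory maturation log whose window counts match the
# published-style series accounting: 682 cases total (10 labs x 25 cases,
# 12 labs x 36 cases), with 42 errors in cases 1-13, 25 in cases 14-25 and
# 12 beyond case 25.
table2_style_log <- function() {
  lens <- c(rep(25L, 10), rep(36L, 12))
  lab_ids <- sprintf("T%02d", seq_along(lens))
  log <- do.call(rbind, lapply(seq_along(lens), function(i) {
    data.frame(lab_id = lab_ids[i], lineage = "B",
               case_index = seq_len(lens[i]), gross_error = 0L,
               stringsAsFactors = FALSE)
  }))
  set_err <- function(log, lab, idx) {
    log$gross_error[log$lab_id == lab & log$case_index %in% idx] <- 1L
    log
  }
  # first half: 2 errors each in labs 1-21 (42 total)
  for (lab in lab_ids[1:21]) log <- set_err(log, lab, c(3, 7))
  # cases 14-25: two errors in each of labs 1-12, one in lab 13 (25 total)
  for (lab in lab_ids[1:12]) log <- set_err(log, lab, c(16, 22))
  log <- set_err(log, lab_ids[13], 20)
  # beyond case 25: one error in each extended lab (labs 11-22, 12 total)
  for (lab in lab_ids[11:22]) log <- set_err(log, lab, 30)
  log
}

# Scored-verdict table with prescribed per-group submission/outlier counts.
# groups: named integer vectors, e.g. n_sub = c(A = 487, B = 1192)
scored_with_outliers <- function(n_sub, n_out) {
  stopifnot(names(n_sub) == names(n_out), n_out <= n_sub)
  do.call(rbind, lapply(names(n_sub), function(g) {
    data.frame(lab_id = paste0("lab_", g),
               sample_id = sprintf("%s_S%04d", g, seq_len(n_sub[[g]])),
               status = "positive",
               category = c(rep("outlier_high", n_out[[g]]),
                            rep("concordant", n_sub[[g]] - n_out[[g]])),
               stringsAsFactors = FALSE)
  }))
}

group_map <- function(n_sub) {
  data.frame(lab_id = paste0("lab_", names(n_sub)), group = names(n_sub),
             stringsAsFactors = FALSE)
}

# Brute-force two-sided exact p for a 2xc table: enumerate every table with
# the observed margins via expand.grid, probabilities from the
# product-binomial form evaluated with stats::dhyper / exact choose().
# Independent of the package's log-space enumeration kernel.
brute_force_exact_p <- function(tab) {
  cs <- colSums(tab); r1 <- sum(tab[1, ]); n <- sum(tab)
  grid <- expand.grid(lapply(cs, function(m) 0:m))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  prob <- apply(grid, 1, function(k)
    prod(choose(cs, k)) / choose(n, r1))
  obs <- prod(choose(cs, tab[1, ])) / choose(n, r1)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# random 2xc table with total at most n_max (at least one count per row)
random_table <- function(n_max, ncol = 3) {
  repeat {
    n <- sample(4:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(1, 2 * ncol)))
    tab <- matrix(cells, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
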
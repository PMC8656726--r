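# Exact contingency-table tests: two-sided Fisher for 2x2 and the
# Freeman-Halton extension to 2xc, by full enumeration of the
# margin-constrained support in log space.
#
# Two-sided convention: "point-probability" (a.k.a. minimum-likelihood) —
# the p-value sums the probabilities of all tables with the observed margins
# whose point probability does not exceed that of the observed table, with a
# 1 + 1e-7 relative guard on the comparison. This is the convention of
# standard exact-test implementations.

PP_TOL <- 1 + 1e-7

# cumulative log-factorial table, grown on demand
.lfact_env <- new.env(parent = emptyenv())
.lfact_env$tab <- 0  # log(0!)

lfact <- function(n) {
  tab <- .lfact_env$tab
  m <- max(n)
  if (m + 1 > length(tab)) {
    old <- length(tab)
    tab <- c(tab, cumsum(log(seq(old, m))) + tab[old])
    .lfact_env$tab <- tab
  }
  tab[n + 1]
}

check_table <- function(table, min_cols = 2) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < min_cols)
    stop_input("expected a 2 x c table with c >= %d, got %d x %d",
               min_cols, nrow(table), ncol(table))
  if (any(is.na(table)) || any(table < 0) || any(table != trunc(table)))
    stop_input("table entries must be non-negative integers")
  table
}

#' Point probability of a 2 x c table under fixed margins
#'
#' Probability of the first-row cell counts `k` under the multivariate
#' hypergeometric distribution induced by conditioning on the table margins:
#' `prod(choose(colsums, k)) / choose(N, rowsum1)`, computed in log space.
#'
#' @param k integer vector, the first-row cell counts.
#' @param col_totals column margins (same length as `k`).
#' @param row_total first-row margin (`sum(k)` for an in-support table).
#' @return the point probability; 0 for out-of-support `k`.
#' @examples
#' hypergeometric_point_prob(2, col_totals = c(4, 4), row_total = 4)  # 18/35
#' @export
hypergeometric_point_prob <- function(k, col_totals, row_total) {
  if (length(k) == 1L && length(col_totals) == 2L)
    k <- c(k, row_total - k)  # 2x2 shorthand: k is the (1,1) cell
  if (length(k) != length(col_totals))
    stop_input("k and col_totals must have the same length")
  if (any(k < 0)) return(0)
  if (any(k < 0) || any(k > col_totals) || sum(k) != row_total) return(0)
  n <- sum(col_totals)
  exp(sum(lfact(col_totals) - lfact(k) - lfact(col_totals - k)) -
        (lfact(n) - lfact(row_total) - lfact(n - row_total)))
}

# shared two-sided summation given log point probabilities of the support
two_sided_from_support <- function(logp, logp_obs) {
  keep <- logp <= logp_obs + log(PP_TOL)
  p <- sum(exp(logp[keep]))
  min(p, 1)
}

#' Two-sided Fisher exact test for a 2 x 2 table
#'
#' Enumerates the hypergeometric support of the (1,1) cell given the margins
#' and sums the probabilities of all tables no more likely than the observed
#' one (point-probability two-sided convention, relative guard 1 + 1e-7).
#'
#' @param table a 2 x 2 matrix of non-negative integer counts.
#' @return a list of class `"mrdqc_exact_test"`: `p_value`, `method`,
#'   `n_tables_enumerated`, `table`.
#' @examples
#' fisher_2x2(matrix(c(11, 476, 67, 1125), 2, byrow = TRUE))$p_value
#' @export
fisher_2x2 <- function(table) {
  table <- check_table(table)
  if (ncol(table) != 2L)
    stop_input("fisher_2x2 requires exactly 2 columns, got %d", ncol(table))
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin (empty row or column): p = 1")
    return(exact_test_result(1, "fisher_2x2", 1L, table))
  }
  n <- sum(table)
  support <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  logp <- lfact(cs[1]) - lfact(support) - lfact(cs[1] - support) +
    lfact(cs[2]) - lfact(rs[1] - support) - lfact(cs[2] - rs[1] + support) -
    (lfact(n) - lfact(rs[1]) - lfact(n - rs[1]))
  logp_obs <- logp[match(table[1, 1], support)]
  exact_test_result(two_sided_from_support(logp, logp_obs),
                    "fisher_2x2", length(support), table)
}

#' Freeman-Halton exact test for a 2 x c table
#'
#' Exact extension of the two-sided Fisher test to two rows and `c` columns:
#' all tables with the observed margins are enumerated over the free cells of
#' the first row, and the probabilities of those no more likely than the
#' observed table are summed (same convention and guard as [fisher_2x2()],
#' to which it reduces exactly when `c = 2`). All-zero columns are dropped
#' before enumeration (they carry no probability).
#'
#' @param table a 2 x c matrix of non-negative integer counts, c >= 2.
#' @param max_tables enumeration cap; tables whose support exceeds it raise a
#'   capacity error rather than being approximated silently.
#' @return a list of class `"mrdqc_exact_test"`: `p_value`, `method`,
#'   `n_tables_enumerated`, `table`.
#' @examples
#' freeman_halton_2xc(matrix(c(19, 4, 8, 24, 8, 0), 2, byrow = TRUE))$p_value
#' @export
freeman_halton_2xc <- function(table, max_tables = 1e7) {
  table <- check_table(table)
  full <- table
  table <- table[, colSums(table) > 0, drop = FALSE]
  if (ncol(table) < 1L || any(rowSums(full) == 0)) {
    warning("degenerate margin (empty row or column): p = 1")
    return(exact_test_result(1, "freeman_halton_2xc", 1L, full))
  }
  if (ncol(table) == 1L)  # single outcome: only one table has these margins
    return(exact_test_result(1, "freeman_halton_2xc", 1L, full))
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) {
    warning("degenerate margin (empty row): p = 1")
    return(exact_test_result(1, "freeman_halton_2xc", 1L, full))
  }
  cap <- prod(pmin(cs, rs[1]) + 1)
  if (cap > max_tables)
    stop_input("support too large to enumerate (bound %g tables > cap %g)",
               cap, max_tables)
  logp <- enumerate_first_row_logp(cs, rs[1])
  log_obs <- log(hypergeometric_point_prob(table[1, ], cs, rs[1]))
  exact_test_result(two_sided_from_support(logp, log_obs),
                    "freeman_halton_2xc", length(logp), full)
}

# log point probabilities of every first row (k1..kc) with sum row_total,
# 0 <= kj <= col_totals[j]; iterative enumeration, ascending in k1 then k2...
enumerate_first_row_logp <- function(col_totals, row_total) {
  nc <- length(col_totals)
  norm <- {
    n <- sum(col_totals)
    lfact(n) - lfact(row_total) - lfact(n - row_total)
  }
  # log binomial mass contributed by column j holding k
  lcell <- function(j, k) lfact(col_totals[j]) - lfact(k) - lfact(col_totals[j] - k)
  rec <- function(j, remaining) {
    if (j == nc) {
      if (remaining <= col_totals[j]) return(lcell(j, remaining))
      return(numeric(0))
    }
    ks <- max(0, remaining - sum(col_totals[(j + 1):nc])):min(col_totals[j], remaining)
    if (!length(ks)) return(numeric(0))
    unlist(lapply(ks, function(k) lcell(j, k) + rec(j + 1, remaining - k)))
  }
  rec(1, row_total) - norm
}

exact_test_result <- function(p, method, n_tables, table) {
  structure(list(p_value = p, method = method,
                 n_tables_enumerated = n_tables, table = table),
            class = "mrdqc_exact_test")
}

#' @export
print.mrdqc_exact_test <- function(x, ...) {
  cat(sprintf("%s: p = %.6g (two-sided, point-probability; %d tables enumerated)\n",
              x$method, x$p_value, x$n_tables_enumerated))
  invisible(x)
}
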
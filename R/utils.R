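# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed rates in proficiency-testing reports use conventional
#' ("half-up") rounding, not the IEC round-half-even rule of [base::round()].
#' Used only in reporting views; computations carry full precision.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round(0.125, 2) gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Stable 31-bit polynomial hash of a string; used to derive per-laboratory
# RNG substreams so adding a laboratory never reshuffles the others.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# seed for lab `lab_id` within the dataset stream seeded by `seed`
lab_substream_seed <- function(seed, lab_id) {
  as.integer((as.numeric(seed) + as.numeric(stable_hash(lab_id))) %% 2147483647)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
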
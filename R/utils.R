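#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
NULL

# error constructor: all package errors carry the "annobench_error" class so
# callers can distinguish harness errors from subject-server failures
abort_bench <- function(message, class = "annobench_error", ...) {
  rlang::abort(message, class = unique(c(class, "annobench_error")), ...)
}

# Deterministic seed derivation: fold indices into a 31-bit LCG state.
# Keeps every derived seed strictly below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in ix) {
    s <- (s * 48271 + as.double(i) * 62089 + 1) %% 2147483629
  }
  as.integer(s)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# 3-significant-figure scientific notation, the convention used by the
# leaderboard export (e.g. 4.58E+06)
format_sci3 <- function(x) {
  out <- toupper(formatC(x, format = "e", digits = 2))
  out[is.na(x)] <- "-"
  out
}
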
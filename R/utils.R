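# Internal helpers: seed derivation, logging, small assertions.

# Deterministic derivation of sub-seeds from a master seed.  Linear
# congruential step (Park-Miller multiplier) over the Mersenne prime
# 2^31 - 1 keeps every derived seed a valid 32-bit R integer and makes the
# subject/null-ensemble seed stream documentable and portable.
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m + k * 48271) %% m
  # 48271 * s mod m computed in doubles stays exact (< 2^53)
  as.integer((48271 * (s + 1)) %% m)
}

clubnet_log <- function(..., verbose = getOption("clubnet.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[clubnet] ", ...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is_square_matrix(m)) stopf("%s must be a square matrix", what)
  if (max(abs(m - t(m))) > tol) stopf("%s must be symmetric", what)
  invisible(TRUE)
}
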
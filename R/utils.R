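# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

# scalar checks used by the config constructors
chk_num <- function(x, name, lo = -Inf, hi = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) ||
      any(x < lo) || any(x > hi)) {
    stop_input(sprintf("invalid `%s`", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-sided band energy of a real segment via the periodogram.
# Returns the summed |X(f)|^2 over band[1] < f <= band[2].
band_energy <- function(x, fs_hz, band) {
  n <- length(x)
  if (n < 4L) return(0)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1L) * fs_hz / n
  half <- seq_len(floor(n / 2) + 1L)
  p <- Mod(X[half])^2
  sum(p[f[half] > band[1] & f[half] <= band[2]])
}

# Runs of TRUE in a logical vector as a two-column matrix (start, end indices).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
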
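# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# stream. A NULL seed evaluates `code` with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

stop_param <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param("`", name, "` must be a single positive finite number")
  invisible(x)
}

# Periodic Hann window of length n (exact spectral nulls at bin offsets >= 2).
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq.int(0L, n - 1L) / n))
}

# FFT-based linear convolution, padded to a 2-3-5 smooth length.
fft_conv <- function(x, y) {
  n_out <- length(x) + length(y) - 1L
  nfft <- stats::nextn(n_out, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  Y <- stats::fft(c(y, numeric(nfft - length(y))))
  z <- Re(stats::fft(X * Y, inverse = TRUE)) / nfft
  z[seq_len(n_out)]
}
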
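# Independent oracles used across tests. These deliberately avoid the
# package's FFT/Welch code paths.

# Naive one-sided Welch PSD by direct DFT summation (O(n^2) per segment;
# for tiny fixtures only). Mirrors the documented estimator definition:
# non-overlapping segments, per-segment demeaning, periodic Hann taper,
# density normalization 2 |X|^2 / (fs * sum(w^2)), Nyquist not doubled,
# DC dropped.
naive_welch <- function(x, fs, segment_length = 0.5, demean = TRUE) {
  L <- round(segment_length * fs)
  n_seg <- floor(length(x) / L)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  n_keep <- L %/% 2
  acc <- numeric(n_keep)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    if (demean) seg <- seg - mean(seg)
    seg <- seg * w
    for (k in seq_len(n_keep)) {
      ph <- -2 * pi * k * (0:(L - 1)) / L
      acc[k] <- acc[k] + sum(seg * cos(ph))^2 + sum(seg * sin(ph))^2
    }
  }
  p <- acc / n_seg * 2 / (fs * sum(w^2))
  if (L %% 2 == 0) p[n_keep] <- p[n_keep] / 2
  list(frequencies = seq_len(n_keep) * fs / L, power = p)
}

# Continuous-time single-segment spectrum of a Hann-tapered waveform by
# direct numerical Fourier integration on a refined time grid.
numeric_waveform_spectrum <- function(fun, length_s, fs_out, freqs,
                                      oversample = 16) {
  dt <- 1 / (fs_out * oversample)
  t <- seq(0, length_s - dt, by = dt)
  taper <- 0.5 * (1 - cos(2 * pi * t / length_s))
  xt <- fun(t) * taper
  vapply(freqs, function(f) {
    re <- sum(xt * cos(2 * pi * f * t)) * dt
    im <- sum(xt * sin(2 * pi * f * t)) * dt
    re^2 + im^2
  }, numeric(1))
}

# Sampled grid matching the package's causal waveform convention.
causal_grid <- function(fs, length_s) seq(0, length_s - 1 / fs, by = 1 / fs)

poisson_train <- function(rate = 40, duration = 200, seed = 1) {
  sample_gamma_train(gamma_interval_spec(1, rate), duration, seed)
}
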
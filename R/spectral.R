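#' Power spectrum container
#'
#' One-sided power spectra on a uniform frequency grid from the estimator
#' resolution (`1/segment_length`) up to the Nyquist frequency. The 0 Hz
#' bin is excluded throughout the package: for point-process pulse trains
#' the mean level is arbitrary, and all downstream operations (peaks,
#' slopes, surrogate bands) are defined on positive frequencies only.
#'
#' @param frequencies Frequencies in Hz.
#' @param power Non-negative power values.
#' @param meta List of estimation metadata (`segment_length_s`, `taper`,
#'   `n_segments`, `source`, ...).
#' @return An object of class `"power_spectrum"`.
#' @keywords internal
new_power_spectrum <- function(frequencies, power, meta = list()) {
  stopifnot(length(frequencies) == length(power))
  structure(
    list(frequencies = as.numeric(frequencies), power = as.numeric(power),
         meta = meta),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d bins, %.4g-%.4g Hz",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (!is.null(x$meta$n_segments))
    cat(sprintf(" (Welch: %d x %g s %s segments)",
                x$meta$n_segments, x$meta$segment_length_s, x$meta$taper))
  cat("\n")
  if (!is.null(x$meta$source)) cat("  source:", x$meta$source, "\n")
  invisible(x)
}

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, power = x$power)
}

taper_window <- function(taper, n) {
  switch(taper,
         hann = hann_window(n),
         rectangular = rep(1, n),
         boxcar = rep(1, n),
         stop_param("unknown taper: ", taper))
}

# Shared Welch engine: average one-sided tapered periodograms over
# non-overlapping segments. Normalization: power spectral density
# P(f) = 2 |X(f)|^2 / (fs * sum(w^2)) (Nyquist bin not doubled), constant
# across the package, so sum(P) * df recovers the (per-segment demeaned)
# signal variance.
welch_core <- function(values, fs, segment_length, taper = "hann",
                       detrend = c("constant", "none"), source = NULL) {
  detrend <- match.arg(detrend)
  seg_n <- round(segment_length * fs)
  if (seg_n < 4) stop_param("segment too short")
  n_seg <- floor(length(values) / seg_n)
  if (n_seg < 1L)
    stop_param("input shorter than one segment (", segment_length, " s)")
  m <- matrix(values[seq_len(n_seg * seg_n)], nrow = seg_n)
  if (detrend == "constant") m <- sweep(m, 2L, colMeans(m))
  w <- taper_window(taper, seg_n)
  spec <- stats::mvfft(m * w)
  n_keep <- seg_n %/% 2L                     # bins 1..floor(n/2), DC dropped
  k <- seq_len(n_keep) + 1L
  p <- rowMeans(abs(spec[k, , drop = FALSE])^2) * 2 / (fs * sum(w^2))
  if (seg_n %% 2L == 0L) p[n_keep] <- p[n_keep] / 2   # Nyquist not doubled
  new_power_spectrum(
    frequencies = seq_len(n_keep) * fs / seg_n,
    power = p,
    meta = list(segment_length_s = seg_n / fs, taper = taper,
                n_segments = n_seg, detrend = detrend,
                sampling_rate = fs, source = source))
}

#' Welch power spectral density estimate
#'
#' Averages the squared amplitude of the Fourier transform over
#' non-overlapping, Hann-tapered segments (default 500 ms, giving 2 Hz
#' resolution at a 1 kHz sampling rate). Each segment is demeaned before
#' tapering by default, which removes leakage of the arbitrary mean level
#' of pulse trains into the lowest frequency bin; set `detrend = "none"`
#' for a raw tapered periodogram average. Deterministic for a given input.
#'
#' @param x A `"pulse_train"`, an `"lfp_signal"`, or a numeric vector (then
#'   `sampling_rate` is required).
#' @param segment_length Segment length in seconds (default 0.5).
#' @param taper `"hann"` (default) or `"rectangular"`.
#' @param detrend `"constant"` (demean each segment; default) or `"none"`.
#' @param sampling_rate Sampling rate in Hz, for numeric input only.
#' @param ... Passed to methods.
#'
#' @return A `"power_spectrum"` on the grid `1/segment_length, ...,`
#'   Nyquist.
#' @examples
#' p <- events_to_pulse(sample_gamma_train(gamma_interval_spec(1, 40),
#'                                         duration = 60, seed = 1))
#' s <- welch_psd(p)
#' s  # flat spectrum: a Poisson train has no preferred frequency
#' @export
welch_psd <- function(x, segment_length = 0.5, taper = "hann",
                      detrend = c("constant", "none"), ...) {
  UseMethod("welch_psd")
}

#' @rdname welch_psd
#' @export
welch_psd.pulse_train <- function(x, segment_length = 0.5, taper = "hann",
                                  detrend = c("constant", "none"), ...) {
  welch_core(x$values, x$sampling_rate, segment_length, taper,
             match.arg(detrend), source = "pulse train")
}

#' @rdname welch_psd
#' @export
welch_psd.lfp_signal <- function(x, segment_length = 0.5, taper = "hann",
                                 detrend = c("constant", "none"), ...) {
  welch_core(x$values, x$sampling_rate, segment_length, taper,
             match.arg(detrend), source = "signal")
}

#' @rdname welch_psd
#' @export
welch_psd.numeric <- function(x, segment_length = 0.5, taper = "hann",
                              detrend = c("constant", "none"),
                              sampling_rate = NULL, ...) {
  if (is.null(sampling_rate))
    stop_param("`sampling_rate` is required for numeric input")
  welch_core(x, sampling_rate, segment_length, taper, match.arg(detrend),
             source = "numeric series")
}

#' Detect local spectral peaks
#'
#' Finds local maxima of a power spectrum that exceed a prominence
#' threshold relative to the local median power (default: 1.5 times the
#' median over a +/- 10-bin neighborhood). Grid endpoints are not eligible.
#' Peaks are returned in ascending frequency; an empty result is valid
#' (e.g. for a flat spectrum).
#'
#' @param s A `"power_spectrum"`.
#' @param min_prominence_ratio Required ratio of peak power to local median
#'   power.
#' @param f_range Optional `c(lo, hi)` in Hz restricting the search.
#' @param neighborhood Half-width, in bins, of the local-median window.
#'
#' @return A data frame with columns `frequency` and `power`.
#' @export
find_spectral_peaks <- function(s, min_prominence_ratio = 1.5,
                                f_range = NULL, neighborhood = 10L) {
  stopifnot(inherits(s, "power_spectrum"))
  p <- s$power
  f <- s$frequencies
  n <- length(p)
  if (n < 3L) return(data.frame(frequency = numeric(0), power = numeric(0)))
  i <- 2:(n - 1L)
  # relative margin so float-level ripple on a constant spectrum never
  # registers as a maximum
  is_max <- p[i] > p[i - 1L] * (1 + 1e-8) & p[i] >= p[i + 1L] & p[i] > 0
  cand <- i[is_max]
  if (!is.null(f_range)) {
    if (length(f_range) != 2L || f_range[1L] >= f_range[2L])
      stop_param("`f_range` must be c(lo, hi) with lo < hi")
    if (!any(f >= f_range[1L] & f <= f_range[2L]))
      stop_param("`f_range` does not overlap the spectrum grid")
    cand <- cand[f[cand] >= f_range[1L] & f[cand] <= f_range[2L]]
  }
  # floor at a tiny fraction of the strongest power in the searched range:
  # floating-point residue around zero must not register as peaks
  floor_p <- 1e-9 * max(p[if (is.null(f_range)) TRUE
                          else f >= f_range[1L] & f <= f_range[2L]])
  keep <- vapply(cand, function(j) {
    win <- p[max(1L, j - neighborhood):min(n, j + neighborhood)]
    p[j] > floor_p && p[j] > min_prominence_ratio * stats::median(win)
  }, logical(1))
  cand <- cand[keep]
  data.frame(frequency = f[cand], power = p[cand])
}

#' Peak-frequency estimate for a noisy spectral bell
#'
#' Locates the mode of a spectrum robustly. A raw argmax at the Welch
#' resolution is unstable when the underlying spectrum is a broad bell
#' (e.g. inherited from a wide-band waveform): many bins lie within the
#' estimator noise of the maximum. The mode is therefore estimated from a
#' locally averaged spectrum whose smoothing half-width adapts to the
#' bell's half-maximum bandwidth (about one sixth of it, at least one
#' bin); edge bins are averaged over their available neighborhood, so
#' monotone low-pass spectra keep their mode at the lowest bin. For a
#' narrow line the adaptive width collapses to +/- 1 bin and the estimate
#' coincides with the raw argmax.
#'
#' @param s A `"power_spectrum"`.
#' @param f_range Optional `c(lo, hi)` restricting the search (Hz).
#'
#' @return The estimated peak frequency in Hz.
#' @export
spectral_mode <- function(s, f_range = NULL) {
  stopifnot(inherits(s, "power_spectrum"))
  f <- s$frequencies
  p <- s$power
  if (!is.null(f_range)) {
    sel <- f >= f_range[1L] & f <= f_range[2L]
    f <- f[sel]
    p <- p[sel]
  }
  if (!length(p)) stop_param("empty frequency range")
  i0 <- which.max(p)
  band <- p >= p[i0] / 2
  # contiguous half-max band around the raw argmax
  lo <- i0
  while (lo > 1L && band[lo - 1L]) lo <- lo - 1L
  hi <- i0
  while (hi < length(p) && band[hi + 1L]) hi <- hi + 1L
  hw <- max(1L, (hi - lo + 1L) %/% 6L)
  sm <- vapply(seq_along(p), function(j)
    mean(p[max(1L, j - hw):min(length(p), j + hw)]), numeric(1))
  f[which.max(sm)]
}

#' Log-log power-law slope of a spectrum
#'
#' Least-squares slope of `log10(power)` against `log10(frequency)` over a
#' frequency range: 0 for a flat spectrum, -2 for the `1/f^2` background
#' produced by RC-filtered white noise.
#'
#' @param s A `"power_spectrum"`.
#' @param f_range `c(lo, hi)` in Hz; must cover at least 5 bins, all with
#'   strictly positive power.
#'
#' @return The slope (a single number).
#' @export
fit_loglog_slope <- function(s, f_range) {
  stopifnot(inherits(s, "power_spectrum"))
  if (length(f_range) != 2L || f_range[1L] >= f_range[2L])
    stop_param("`f_range` must be c(lo, hi) with lo < hi")
  sel <- s$frequencies >= f_range[1L] & s$frequencies <= f_range[2L]
  if (sum(sel) < 5L) stop_param("need at least 5 frequency bins in range")
  p <- s$power[sel]
  if (any(p <= 0)) stop_param("zero or negative power in the fit range")
  unname(stats::coef(stats::lm(log10(p) ~ log10(s$frequencies[sel])))[2L])
}
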
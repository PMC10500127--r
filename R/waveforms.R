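#' Single-event waveforms (impulse-response functions)
#'
#' A waveform is the finite, sampled voltage deflection induced by one
#' neural event. Four parametric families are provided: the alpha synaptic
#' response, real-valued Morlet (Gabor) wavelets for spikes and spindles,
#' single-cycle Hann pulses, and the impulse response of a passive RC
#' membrane filter. All are sampled over a fixed trace length (default
#' 500 ms) and hard-truncated there.
#'
#' Each waveform carries its time-origin convention in the `origin` field
#' (the 1-based sample aligned with the event time during convolution):
#' alpha, Hann and RC waveforms are causal (origin at the first sample);
#' Morlet wavelets are centered mid-trace so that a zero Gaussian mean
#' places the envelope peak at the event time.
#'
#' @name waveforms
#' @seealso [waveform_spectrum()], [convolve_train()]
NULL

new_waveform <- function(values, sampling_rate, length_s, family, params,
                         origin) {
  structure(
    list(values = as.numeric(values), sampling_rate = sampling_rate,
         length = length_s, family = family, params = params,
         origin = as.integer(origin)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  par_str <- paste(names(x$params),
                   vapply(x$params, format, character(1)),
                   sep = " = ", collapse = ", ")
  cat(sprintf("Waveform [%s]: %g s at %g Hz (%d samples); %s\n",
              x$family, x$length, x$sampling_rate, length(x$values), par_str))
  invisible(x)
}

waveform_time_axis <- function(sampling_rate, length_s, centered = FALSE) {
  n <- round(length_s * sampling_rate)
  t <- seq.int(0L, n - 1L) / sampling_rate
  if (centered) t <- t - length_s / 2
  t
}

#' @describeIn waveforms Alpha synaptic response
#'   `A(t) = H(t) t exp(-t / tau)` (Heaviside `H`): zero at the event time,
#'   peaking at `t = tau`, decaying exponentially; spectral energy
#'   concentrated at low frequency.
#' @param tau Time constant in seconds (synaptic default 5.6 ms; RC membrane
#'   default 35 ms).
#' @param sampling_rate Sampling rate in Hz.
#' @param length Trace length in seconds.
#' @return A `"waveform"` object.
#' @export
alpha_waveform <- function(tau = 0.0056, sampling_rate = 1000, length = 0.5) {
  check_positive(tau, "tau")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(length, "length")
  t <- waveform_time_axis(sampling_rate, length)
  new_waveform(t * exp(-t / tau), sampling_rate, length, "alpha",
               list(tau = tau), origin = 1L)
}

#' @describeIn waveforms Real Morlet (Gabor) wavelet: a sinusoid multiplied
#'   by a Gaussian envelope,
#'   `W(t) = exp(-(t - mu)^2 / (2 sigma^2)) sin((t - t0) 2 pi / p)`,
#'   on a time axis centered mid-trace (so `mu = 0` centers the envelope).
#'   Its spectrum is concentrated at the sinusoid frequency `1/p` with
#'   bandwidth inversely proportional to `sigma`.
#' @param sigma Gaussian envelope standard deviation in seconds.
#' @param t0 Sinusoid phase offset in seconds.
#' @param p Sinusoid period in seconds.
#' @param mu Gaussian envelope mean in seconds (0 = centered).
#' @export
morlet_waveform <- function(sigma, t0 = 0, p, mu = 0, sampling_rate = 1000,
                            length = 0.5) {
  check_positive(sigma, "sigma")
  check_positive(p, "p")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(length, "length")
  t <- waveform_time_axis(sampling_rate, length, centered = TRUE)
  v <- exp(-(t - mu)^2 / (2 * sigma^2)) * sin((t - t0) * 2 * pi / p)
  new_waveform(v, sampling_rate, length, "morlet",
               list(sigma = sigma, t0 = t0, p = p, mu = mu),
               origin = which.min(abs(t)))
}

#' @describeIn waveforms Single Hann cycle (one raised-cosine cycle of a
#'   sinusoid) of period `p` at the start of the trace, zero elsewhere;
#'   optionally inverted (trough-first, as used for theta-like field
#'   deflections) and scaled.
#' @param inverted Multiply the cycle by -1.
#' @param scale Amplitude scale factor (> 0).
#' @export
hann_waveform <- function(p, inverted = FALSE, scale = 1,
                          sampling_rate = 1000, length = 0.5) {
  check_positive(p, "p")
  check_positive(scale, "scale")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(length, "length")
  if (p > length) stop_param("`p` must not exceed the trace length")
  t <- waveform_time_axis(sampling_rate, length)
  v <- ifelse(t <= p, 0.5 * (1 - cos(2 * pi * t / p)), 0)
  v <- v * scale * if (inverted) -1 else 1
  new_waveform(v, sampling_rate, length, "hann",
               list(p = p, inverted = inverted, scale = scale), origin = 1L)
}

#' @describeIn waveforms Impulse response of a passive RC (resistive-
#'   capacitive) membrane filter, `F(t) = (1 / tau) exp(-t / tau)`: a causal
#'   unit-area decaying exponential (up to truncation). White noise filtered
#'   with it acquires the characteristic `1/f^2` high-frequency spectrum.
#' @export
rc_impulse <- function(tau = 0.035, sampling_rate = 1000, length = 0.5) {
  check_positive(tau, "tau")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(length, "length")
  t <- waveform_time_axis(sampling_rate, length)
  new_waveform(exp(-t / tau) / tau, sampling_rate, length, "rc",
               list(tau = tau), origin = 1L)
}

#' Power spectrum of a single waveform
#'
#' Tapers the full waveform trace with a Hann window and takes the squared
#' amplitude of its Fourier transform: a single-segment, one-sided spectrum
#' with frequency resolution `1/length` (2 Hz at the 500 ms default). The
#' segment is not demeaned (waveforms are transient) and no amplitude
#' normalization is applied beyond the package-wide density constant, so
#' scaling a waveform by `c` scales its spectrum by `c^2`.
#'
#' @param w A `"waveform"` object.
#' @return A `"power_spectrum"` object.
#' @export
waveform_spectrum <- function(w) {
  stopifnot(inherits(w, "waveform"))
  welch_core(w$values, w$sampling_rate, segment_length = w$length,
             taper = "hann", detrend = "none",
             source = sprintf("waveform spectrum [%s]", w$family))
}
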
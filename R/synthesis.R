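#' Sampled voltage-like signals
#'
#' An `"lfp_signal"` is a uniformly sampled real series representing a
#' voltage trace: the result of convolving a timing pulse train with a
#' waveform, filtered background noise, or a sum of such components.
#'
#' @param values Numeric sample values.
#' @param sampling_rate Sampling rate in Hz.
#' @param provenance List of component descriptions.
#' @return An object of class `"lfp_signal"`.
#' @keywords internal
new_lfp_signal <- function(values, sampling_rate, provenance = list()) {
  structure(
    list(values = as.numeric(values), sampling_rate = sampling_rate,
         duration = length(values) / sampling_rate,
         provenance = provenance),
    class = "lfp_signal"
  )
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("Signal: %d samples at %g Hz (%g s), sd %.4g\n",
              length(x$values), x$sampling_rate, x$duration,
              stats::sd(x$values)))
  if (length(x$provenance))
    cat("  components:", length(x$provenance), "\n")
  invisible(x)
}

#' Convolve a timing pulse train with an event waveform
#'
#' Builds the shot-noise signal of a recurring neural event: each pulse
#' contributes one copy of the waveform, aligned so the waveform's event
#' origin (first sample for causal alpha/Hann/RC waveforms, trace center
#' for Morlet wavelets) coincides with the event sample. Linear FFT
#' convolution, truncated to the pulse train's length; no wrap-around.
#' The operation is exactly linear in the waveform amplitude.
#'
#' @param pulse A `"pulse_train"`.
#' @param w A `"waveform"` with the same sampling rate.
#'
#' @return An `"lfp_signal"` of the same duration as `pulse`.
#' @examples
#' tr <- event_train(0.1, duration = 1)
#' s <- convolve_train(events_to_pulse(tr), alpha_waveform(tau = 0.0056))
#' which.max(s$values) / 1000  # peaks tau seconds after the event
#' @export
convolve_train <- function(pulse, w) {
  stopifnot(inherits(pulse, "pulse_train"), inherits(w, "waveform"))
  if (pulse$sampling_rate != w$sampling_rate)
    stop_param("pulse train and waveform sampling rates differ")
  z <- fft_conv(pulse$values, w$values)
  out <- z[w$origin + seq_len(length(pulse$values)) - 1L]
  new_lfp_signal(out, pulse$sampling_rate,
                 provenance = list(list(kind = "shot-noise",
                                        timing = pulse$provenance,
                                        waveform = w$family,
                                        params = w$params)))
}

#' Sum component signals
#'
#' Element-wise sum of signals sharing sampling rate and duration, modeling
#' the superposition of independent neural sources in the field potential.
#' For independent components the power spectrum of the sum approaches the
#' sum of the component spectra.
#'
#' @param parts A list of `"lfp_signal"` objects (or several signals passed
#'   as `...`).
#' @param ... Signals, if `parts` is not a list.
#'
#' @return An `"lfp_signal"` with concatenated provenance.
#' @export
sum_signals <- function(parts, ...) {
  if (inherits(parts, "lfp_signal")) parts <- c(list(parts), list(...))
  if (!length(parts) || !all(vapply(parts, inherits, logical(1), "lfp_signal")))
    stop_param("`parts` must be lfp_signal objects")
  fs <- unique(vapply(parts, `[[`, numeric(1), "sampling_rate"))
  ns <- unique(vapply(parts, function(p) length(p$values), integer(1)))
  if (length(fs) != 1L || length(ns) != 1L)
    stop_param("all signals must share sampling rate and duration")
  new_lfp_signal(Reduce(`+`, lapply(parts, `[[`, "values")), fs,
                 provenance = do.call(c, lapply(parts, `[[`, "provenance")))
}

#' RC-filtered white-noise background
#'
#' Models desynchronized background synaptic activity: unit-variance
#' Gaussian white noise convolved with the truncated RC impulse response
#' [rc_impulse()]. The resulting spectrum is flat below the RC corner
#' frequency `1/(2 pi tau)` and falls off as `1/f^2` above it.
#'
#' @param tau RC time constant in seconds (default 35 ms).
#' @param duration Duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @param sd Standard deviation of the white-noise input (default 1; 0
#'   yields a zero signal).
#' @param length Impulse-response trace length in seconds.
#'
#' @return An `"lfp_signal"`.
#' @export
rc_background_noise <- function(tau = 0.035, duration = 1000,
                                sampling_rate = 1000, seed = NULL, sd = 1,
                                length = 0.5) {
  check_positive(tau, "tau")
  check_positive(duration, "duration")
  check_positive(sampling_rate, "sampling_rate")
  if (sd < 0) stop_param("`sd` must be non-negative")
  n <- round(duration * sampling_rate)
  white <- with_seed(seed, stats::rnorm(n, sd = sd))
  h <- rc_impulse(tau, sampling_rate, length)
  new_lfp_signal(fft_conv(white, h$values)[seq_len(n)], sampling_rate,
                 provenance = list(list(kind = "rc-background", tau = tau,
                                        sd = sd, seed = seed)))
}
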
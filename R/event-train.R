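#' Gamma inter-event-interval specification
#'
#' Parameterizes a gamma renewal process by its interval shape `a` and its
#' mean event rate `f` (events/second). The gamma scale parameter is always
#' derived as `b = 1 / (a * f)`, so that the mean inter-event interval is
#' `a * b = 1/f` and the interval coefficient of variation is `1/sqrt(a)`.
#' The process is Poisson for `a = 1`, sub-Poissonian (more regular than
#' Poisson, interval CV < 1, count Fano factor < 1) for `a > 1`, and
#' super-Poissonian (burstier than Poisson) for `a < 1`.
#'
#' @param shape Gamma shape parameter `a` (dimensionless, > 0).
#' @param rate Mean event rate `f` in events per second (> 0).
#'
#' @return An object of class `"gamma_interval_spec"` with fields `shape`,
#'   `rate` and the derived `scale` (seconds).
#' @examples
#' spec <- gamma_interval_spec(shape = 10^1.5, rate = 40)
#' spec$scale            # 1 / (a * f)
#' 1 / sqrt(spec$shape)  # interval CV ~ 0.178: a regular, sub-Poissonian train
#' @export
gamma_interval_spec <- function(shape, rate) {
  check_positive(shape, "shape")
  check_positive(rate, "rate")
  structure(
    list(shape = shape, rate = rate, scale = 1 / (shape * rate)),
    class = "gamma_interval_spec"
  )
}

#' @export
print.gamma_interval_spec <- function(x, ...) {
  regime <- if (x$shape == 1) "Poisson"
            else if (x$shape > 1) "sub-Poissonian"
            else "super-Poissonian"
  cat(sprintf(
    "Gamma interval spec: a = %g, f = %g Hz (b = %.6g s) [%s, interval CV = %.3g]\n",
    x$shape, x$rate, x$scale, regime, 1 / sqrt(x$shape)))
  invisible(x)
}

#' Event train objects
#'
#' An event train is the realization of a point process: a sorted vector of
#' event times (seconds) on `[0, duration)` together with the recording
#' duration and a provenance record of how it was generated.
#'
#' @param times Numeric vector of event times in seconds, each in
#'   `[0, duration)`. Sorted internally.
#' @param duration Positive duration of the observation window in seconds.
#' @param provenance Optional list describing the generating process (kept
#'   verbatim; may be empty for user-supplied trains).
#'
#' @return An object of class `"event_train"`.
#' @seealso [sample_gamma_train()], [periodic_train()], [compound_train()],
#'   [modulated_train()], [read_event_times()]
#' @export
event_train <- function(times, duration, provenance = list()) {
  check_positive(duration, "duration")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop_param("event times must be finite numbers")
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) && (times[1L] < 0 || times[length(times)] >= duration))
    stop_param("event times must lie in [0, duration)")
  structure(
    list(times = times, duration = duration, provenance = provenance),
    class = "event_train"
  )
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("Event train: %d events over %g s (rate %.4g events/s)\n",
              length(x$times), x$duration,
              length(x$times) / x$duration))
  if (!is.null(x$provenance$kind))
    cat("  generated by:", x$provenance$kind, "\n")
  invisible(x)
}

# Draw i.i.d. gamma intervals until the cumulative time exceeds `duration`.
# Chunked so the expected number of draws is made once in the common case.
sample_renewal_times <- function(duration, mean_interval, draw) {
  n_chunk <- max(64L, ceiling(duration / mean_interval * 1.05 +
                                4 * sqrt(duration / mean_interval)))
  times <- cumsum(draw(n_chunk))
  while (times[length(times)] < duration) {
    times <- c(times, times[length(times)] + cumsum(draw(n_chunk)))
  }
  times[times < duration]
}

#' Simulate a gamma renewal event train
#'
#' Generates an event train whose successive inter-event intervals are
#' independent draws from the gamma density
#' `P(t) = 1 / (b^a Gamma(a)) t^(a-1) exp(-t / b)` with `b = 1/(a f)`.
#' The process starts at time 0; the first event occurs after the first
#' sampled interval and generation stops at the first event at or beyond
#' `duration` (that event is excluded). Interval statistics follow directly
#' from the gamma moments: mean interval `1/f`, CV `1/sqrt(a)`.
#'
#' @param spec A [gamma_interval_spec()].
#' @param duration Simulated duration in seconds (default 1000 s).
#' @param seed Optional integer seed; the same seed reproduces the identical
#'   train without disturbing the caller's RNG stream.
#'
#' @return An [event_train()].
#' @examples
#' tr <- sample_gamma_train(gamma_interval_spec(1, 40), duration = 100, seed = 1)
#' length(tr$times) / tr$duration  # close to 40 events/s
#' @export
sample_gamma_train <- function(spec, duration = 1000, seed = NULL) {
  stopifnot(inherits(spec, "gamma_interval_spec"))
  check_positive(duration, "duration")
  times <- with_seed(seed, sample_renewal_times(
    duration, 1 / spec$rate,
    function(n) stats::rgamma(n, shape = spec$shape, scale = spec$scale)))
  event_train(times, duration,
              provenance = list(kind = "gamma", shape = spec$shape,
                                rate = spec$rate, seed = seed))
}

#' Perfectly periodic event train
#'
#' Events at `phase_offset + k / rate` for `k = 0, 1, ...` while within the
#' duration. The inter-event interval variance is exactly zero; the power of
#' the resulting pulse train concentrates at the rate and its harmonics.
#'
#' @param rate Event rate in events per second.
#' @param duration Duration in seconds.
#' @param phase_offset Offset of the first event in seconds, in
#'   `[0, 1/rate)`. Spectrally irrelevant (power is phase-invariant).
#'
#' @return An [event_train()].
#' @export
periodic_train <- function(rate, duration = 1000, phase_offset = 0) {
  check_positive(rate, "rate")
  check_positive(duration, "duration")
  if (phase_offset < 0 || phase_offset >= 1 / rate)
    stop_param("`phase_offset` must lie in [0, 1/rate)")
  k <- seq.int(0L, floor((duration - phase_offset) * rate) + 1L)
  times <- phase_offset + k / rate
  event_train(times[times < duration], duration,
              provenance = list(kind = "periodic", rate = rate,
                                phase_offset = phase_offset))
}

#' Event train with a mixture (compound) interval distribution
#'
#' Each successive interval is drawn by first selecting one mixture component
#' with probability proportional to its weight and then sampling that
#' component's gamma interval density, so the interval distribution of the
#' output is the weighted mixture of the component densities. Combining a
#' Poisson component with regular (sub-Poissonian) components of distinct
#' rates produces an interval histogram with modes on top of an exponential
#' decay, and a spectrum with local maxima near the regular components'
#' rates.
#'
#' @param components List of two or more [gamma_interval_spec()] objects
#'   (a single component degenerates to [sample_gamma_train()]).
#' @param weights Non-negative mixture weights, normalized internally.
#'   Default: equal weights.
#' @param duration Duration in seconds.
#' @param seed Optional integer seed.
#'
#' @return An [event_train()].
#' @export
compound_train <- function(components, weights = NULL, duration = 1000,
                           seed = NULL) {
  if (!is.list(components) || length(components) == 0L ||
      !all(vapply(components, inherits, logical(1), "gamma_interval_spec")))
    stop_param("`components` must be a non-empty list of gamma_interval_spec")
  k <- length(components)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    stop_param("`weights` must be non-negative, one per component")
  check_positive(duration, "duration")
  weights <- weights / sum(weights)
  shapes <- vapply(components, `[[`, numeric(1), "shape")
  scales <- vapply(components, `[[`, numeric(1), "scale")
  mean_interval <- sum(weights / vapply(components, `[[`, numeric(1), "rate"))
  times <- with_seed(seed, sample_renewal_times(
    duration, mean_interval,
    function(n) {
      comp <- sample.int(k, n, replace = TRUE, prob = weights)
      stats::rgamma(n, shape = shapes[comp], scale = scales[comp])
    }))
  event_train(times, duration,
              provenance = list(kind = "compound", shapes = shapes,
                                rates = vapply(components, `[[`, numeric(1), "rate"),
                                weights = weights, seed = seed))
}

#' Phase-modulated (cross-frequency-coupled) event train
#'
#' Models fast activity nested in a slower rhythm, e.g. theta-nested gamma:
#' a gamma-renewal carrier train is generated, and only those carrier events
#' are retained whose phase within the current modulator cycle — the latency
#' from the most recent modulator event divided by the length of that cycle
#' (the interval to the next modulator event, or `modulator_period` after
#' the last one) — falls inside the `keep` window. Carrier events preceding
#' the first modulator event are dropped. With the inverted (trough-first)
#' cycle convention used by [hann_waveform()], the first half of each cycle
#' is the downward phase, so the default `keep = c(0, 0.5)` drops events
#' occurring during the upward phase. A full `keep = c(0, 1)` window
#' reduces to the unmodulated carrier restricted to times after the first
#' modulator event, and the retained event rate is approximately the
#' carrier rate times the width of the keep window.
#'
#' The dropped latencies impose the modulator's periodicity on the surviving
#' event timing, adding power at the modulation frequency (and its harmonics)
#' to the carrier's spectrum.
#'
#' @param carrier [gamma_interval_spec()] of the fast carrier process.
#' @param modulator [event_train()] of the slow modulating rhythm.
#' @param modulator_period Nominal cycle length of the modulator in seconds,
#'   used for the trailing partial cycle after the last modulator event.
#' @param keep Numeric length-2 vector `c(lo, hi)` with
#'   `0 <= lo < hi <= 1`: the retained fraction-of-cycle window.
#' @param duration Duration in seconds.
#' @param seed Optional integer seed for the carrier.
#'
#' @return An [event_train()] of the retained carrier events.
#' @export
modulated_train <- function(carrier, modulator, modulator_period,
                            keep = c(0, 0.5), duration = 1000, seed = NULL) {
  stopifnot(inherits(carrier, "gamma_interval_spec"),
            inherits(modulator, "event_train"))
  if (length(modulator$times) == 0L)
    stop_param("`modulator` must contain at least one event")
  check_positive(modulator_period, "modulator_period")
  if (length(keep) != 2L || keep[1L] < 0 || keep[2L] > 1 || keep[1L] >= keep[2L])
    stop_param("`keep` must be c(lo, hi) with 0 <= lo < hi <= 1")
  full <- sample_gamma_train(carrier, duration, seed)
  t <- full$times
  mt <- modulator$times
  cycle_len <- c(diff(mt), modulator_period)
  idx <- findInterval(t, mt)
  ok <- idx >= 1L
  frac <- rep(NA_real_, length(t))
  frac[ok] <- (t[ok] - mt[idx[ok]]) / cycle_len[idx[ok]]
  kept <- ok & !is.na(frac) & frac >= keep[1L] & frac < keep[2L]
  event_train(t[kept], duration,
              provenance = list(kind = "modulated",
                                carrier_shape = carrier$shape,
                                carrier_rate = carrier$rate,
                                modulator_period = modulator_period,
                                keep = keep, seed = seed))
}
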
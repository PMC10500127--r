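#' Inter-event interval histogram
#'
#' Normalized density histogram of the successive inter-event intervals of a
#' train, truncated at `max_interval`. Normalization is by the total number
#' of intervals, so the histogram integrates to 1 minus the mass beyond the
#' truncation point.
#'
#' @param train An [event_train()] with at least two events.
#' @param bin_width Bin width in seconds.
#' @param max_interval Truncation point in seconds.
#'
#' @return An object of class `"interval_histogram"` with fields
#'   `bin_edges` (length nbins + 1) and `density` (per-second probability
#'   density per bin).
#' @export
interval_histogram <- function(train, bin_width = 0.002, max_interval = 0.2) {
  stopifnot(inherits(train, "event_train"))
  check_positive(bin_width, "bin_width")
  check_positive(max_interval, "max_interval")
  if (length(train$times) < 2L)
    stop_param("interval histogram needs at least 2 events")
  intervals <- diff(train$times)
  edges <- seq(0, max_interval + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < max_interval) edges <- c(edges, max_interval)
  counts <- tabulate(findInterval(intervals, edges,
                                  rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges,
         density = counts / (length(intervals) * diff(edges))),
    class = "interval_histogram"
  )
}

#' @export
print.interval_histogram <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  cat(sprintf(
    "Interval histogram: %d bins over [0, %g] s; mode near %.4g s; mass %.3f\n",
    length(x$density), x$bin_edges[length(x$bin_edges)],
    mids[which.max(x$density)],
    sum(x$density * diff(x$bin_edges))))
  invisible(x)
}

#' Descriptive statistics of an event train
#'
#' Empirical rate, interval mean and coefficient of variation, and the Fano
#' factor (variance / mean of event counts in non-overlapping windows). For
#' a Poisson process the count variance equals the rate, so the Fano factor
#' is 1; sub-Poissonian (regular) trains give Fano < 1 and interval CV < 1,
#' super-Poissonian (bursty) trains the reverse.
#'
#' @param train An [event_train()].
#' @param count_window Window length in seconds for the Fano factor; the
#'   duration must cover at least 10 windows.
#'
#' @return A list with `n_events`, `rate`, `interval_mean`, `interval_cv`,
#'   `fano`, `count_window`.
#' @export
train_statistics <- function(train, count_window = 1) {
  stopifnot(inherits(train, "event_train"))
  check_positive(count_window, "count_window")
  if (train$duration < 10 * count_window)
    stop_param("duration must be at least 10 count windows")
  t <- train$times
  n_win <- floor(train$duration / count_window)
  counts <- tabulate(
    findInterval(t[t < n_win * count_window], count_window * seq_len(n_win - 1L)) + 1L,
    nbins = n_win)
  intervals <- if (length(t) >= 2L) diff(t) else numeric(0)
  list(
    n_events = length(t),
    rate = length(t) / train$duration,
    interval_mean = if (length(intervals)) mean(intervals) else NA_real_,
    interval_cv = if (length(intervals) >= 2L)
      stats::sd(intervals) / mean(intervals) else NA_real_,
    fano = if (mean(counts) > 0) stats::var(counts) / mean(counts) else NA_real_,
    count_window = count_window
  )
}

#' Analytic power spectrum of a gamma renewal process
#'
#' Closed-form (Bartlett) spectrum of a stationary renewal point process
#' with gamma-distributed intervals:
#' `S(f) = rate * Re[(1 + phi(f)) / (1 - phi(f))]`, where
#' `phi(f) = (1 - i 2 pi f b)^(-a)` is the characteristic function of the
#' interval density. For `a = 1` (Poisson) the spectrum is exactly flat at
#' the event rate; for `a > 1` it is suppressed at low frequency, peaks near
#' the process rate, and flattens to the rate at high frequency; for `a < 1`
#' it decays monotonically from an elevated low-frequency level. Serves as
#' the independent oracle against which Welch estimates of simulated pulse
#' trains are checked.
#'
#' @param spec A [gamma_interval_spec()].
#' @param frequencies Strictly positive frequencies in Hz (the 0 Hz atom of
#'   the point-process spectrum is excluded).
#'
#' @return A `"power_spectrum"` object (analytic; `meta$estimator`
#'   is `"analytic-renewal"`). Units: events/second (one-sided density up to
#'   the estimator's normalization constant).
#' @export
analytic_renewal_psd <- function(spec, frequencies) {
  stopifnot(inherits(spec, "gamma_interval_spec"))
  if (length(frequencies) == 0L || any(!is.finite(frequencies)) ||
      any(frequencies <= 0))
    stop_param("`frequencies` must be positive (the DC atom is excluded)")
  phi <- (1 - 1i * 2 * pi * frequencies * spec$scale)^(-spec$shape)
  s <- spec$rate * Re((1 + phi) / (1 - phi))
  new_power_spectrum(
    frequencies, s,
    meta = list(estimator = "analytic-renewal", shape = spec$shape,
                rate = spec$rate,
                source = "Bartlett spectrum of a gamma renewal process"))
}
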
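#' Discretize an event train to a timing pulse train
#'
#' Produces the sampled event-timing pulse train: a series with value 1 at
#' the sample nearest each event time and 0 everywhere else. Two events that
#' round to the same sample collapse to a single 1 (binary convention); the
#' number of collapsed events is recorded in the `collisions` field. With
#' `counts = TRUE` the samples hold event counts instead of being clipped
#' to 1.
#'
#' @param train An [event_train()].
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param counts If `TRUE`, return per-sample event counts instead of a
#'   binary train.
#'
#' @return An object of class `"pulse_train"` with fields `values`,
#'   `sampling_rate`, `duration`, `collisions` and `provenance`.
#' @examples
#' tr <- event_train(c(0.1, 0.2), duration = 1)
#' p <- events_to_pulse(tr, 1000)
#' which(p$values == 1)  # samples 101 and 201 (times 0.100 s and 0.200 s)
#' @export
events_to_pulse <- function(train, sampling_rate = 1000, counts = FALSE) {
  stopifnot(inherits(train, "event_train"))
  check_positive(sampling_rate, "sampling_rate")
  n <- round(train$duration * sampling_rate)
  if (n < 1) stop_param("duration shorter than one sample")
  if (length(train$times) && any(train$times >= train$duration))
    stop_param("event times at or beyond the train duration")
  # 0-based sample index by rounding; events rounding up to the sample just
  # past the end are clipped into the final sample.
  idx <- pmin(round(train$times * sampling_rate), n - 1L) + 1L
  tab <- tabulate(idx, nbins = n)
  collisions <- sum(pmax(tab - 1L, 0L))
  values <- if (counts) as.numeric(tab) else as.numeric(pmin(tab, 1L))
  structure(
    list(values = values, sampling_rate = sampling_rate,
         duration = train$duration, collisions = collisions,
         provenance = train$provenance),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %d samples at %g Hz (%g s), %d event samples, %d collision(s)\n",
    length(x$values), x$sampling_rate, x$duration,
    sum(x$values > 0), x$collisions))
  invisible(x)
}
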
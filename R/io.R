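#' Read event timestamps from a plain-text file
#'
#' One event time in seconds per line (floating point, `.` decimal);
#' lines starting with `#` and blank lines are ignored. Times are sorted.
#' Useful for analyzing detected event trains from real recordings with
#' [welch_psd()] and [poisson_surrogate_band()].
#'
#' @param path File path.
#' @param duration Observation duration in seconds. Defaults to the
#'   smallest whole second strictly beyond the last event time.
#' @return An [event_train()] with file-source provenance.
#' @export
read_event_times <- function(path, duration = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_param("no event times found in ", path)
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) stop_param("non-numeric event time in ", path)
  if (is.null(duration)) duration <- floor(max(times)) + 1
  event_train(times, duration, provenance = list(kind = "file",
                                                 source = path))
}

#' Write event timestamps to a plain-text file
#'
#' @param train An [event_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_times <- function(train, path) {
  stopifnot(inherits(train, "event_train"))
  writeLines(c(sprintf("# event times in seconds; duration %g s",
                       train$duration),
               format(train$times, digits = 12, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Export a power spectrum (optionally with a surrogate band) as CSV
#'
#' Writes columns `frequency_hz, power` plus `lower, upper` when a band is
#' supplied, and a `<path>.json` sidecar with the estimation metadata.
#'
#' @param s A `"power_spectrum"`.
#' @param path Output CSV path.
#' @param band Optional `"surrogate_band"` on the same grid.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path, band = NULL) {
  stopifnot(inherits(s, "power_spectrum"))
  df <- as.data.frame(s)
  meta <- s$meta
  if (!is.null(band)) {
    stopifnot(inherits(band, "surrogate_band"))
    if (length(band$frequencies) != nrow(df) ||
        any(abs(band$frequencies - df$frequency_hz) > 1e-9))
      stop_param("band grid does not match the spectrum grid")
    df$lower <- band$lower
    df$upper <- band$upper
    meta$surrogate <- list(n_surrogates = band$n_surrogates,
                           alpha = band$alpha)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Export / import a waveform as two-column text with a JSON sidecar
#'
#' The text file holds `time_s value` pairs; the `<path>.json` sidecar
#' carries the waveform family, parameters, sampling rate and event-origin
#' sample, so the waveform round-trips exactly.
#'
#' @param w A `"waveform"`.
#' @param path Output path.
#' @return `write_waveform()`: `path`, invisibly. `read_waveform()`: a
#'   `"waveform"`.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  t <- waveform_time_axis(w$sampling_rate, w$length,
                          centered = w$family == "morlet")
  utils::write.table(data.frame(time_s = t, value = w$values), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  jsonlite::write_json(
    list(family = w$family, params = w$params,
         sampling_rate = w$sampling_rate, length_s = w$length,
         origin = w$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(path, header = TRUE)
  new_waveform(tab$value, side$sampling_rate, side$length_s, side$family,
               as.list(side$params), side$origin)
}

#' Export a signal as two-column text
#'
#' Writes `time_s value` pairs with a JSON sidecar recording the sampling
#' rate, duration and provenance. Intended for modest excerpts; a full
#' 1000 s trace at 1 kHz makes a large text file.
#'
#' @param x An `"lfp_signal"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "lfp_signal"))
  t <- seq.int(0L, length(x$values) - 1L) / x$sampling_rate
  utils::write.table(data.frame(time_s = t, value = x$values), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate = x$sampling_rate, duration = x$duration,
         provenance = x$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build an event train from a serialized process configuration
#'
#' Reads a YAML or JSON configuration with keys `process.kind` (one of
#' `gamma`, `periodic`, `compound`, `modulated`), `process.shape`,
#' `process.rate` (plus kind-specific fields), `duration_s` and `seed`,
#' and generates the corresponding train. `compound` expects parallel
#' arrays `process.shapes`, `process.rates` and optional `process.weights`;
#' `modulated` expects `process.modulator` (a nested gamma process spec),
#' `process.modulator_period_s` and optional `process.keep`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return An [event_train()].
#' @export
train_from_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- cfg$process
  if (is.null(pr$kind)) stop_param("config lacks process.kind")
  duration <- cfg$duration_s %||% 1000
  seed <- cfg$seed
  switch(as.character(pr$kind),
    gamma = sample_gamma_train(gamma_interval_spec(pr$shape, pr$rate),
                               duration, seed),
    periodic = periodic_train(pr$rate, duration,
                              phase_offset = pr$phase_offset %||% 0),
    compound = compound_train(
      Map(gamma_interval_spec, pr$shapes, pr$rates),
      weights = pr$weights, duration = duration, seed = seed),
    modulated = {
      mod <- sample_gamma_train(
        gamma_interval_spec(pr$modulator$shape, pr$modulator$rate),
        duration, (seed %||% 0) + 1L)
      modulated_train(gamma_interval_spec(pr$shape, pr$rate), mod,
                      pr$modulator_period_s,
                      keep = pr$keep %||% c(0, 0.5),
                      duration = duration, seed = seed)
    },
    stop_param("unknown process.kind: ", pr$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
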
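test_that("the Welch estimator matches a direct-DFT oracle bin for bin", {
  set.seed(31)
  x <- stats::rnorm(2000) + sin(2 * pi * 30 * (0:1999) / 1000)
  s <- welch_psd(x, sampling_rate = 1000)
  oracle <- naive_welch(x, 1000)
  expect_equal(s$frequencies, oracle$frequencies)
  expect_equal(s$power, oracle$power, tolerance = 1e-9)
  expect_equal(s$meta$n_segments, 4)

  raw <- welch_psd(x, sampling_rate = 1000, detrend = "none")
  oracle_raw <- naive_welch(x, 1000, demean = FALSE)
  expect_equal(raw$power, oracle_raw$power, tolerance = 1e-9)
})

test_that("Welch estimates are deterministic, reject short input, and keep zeros", {
  x <- stats::rnorm(5000)
  expect_identical(welch_psd(x, sampling_rate = 1000),
                   welch_psd(x, sampling_rate = 1000))
  expect_error(welch_psd(numeric(400), sampling_rate = 1000), "segment")
  expect_true(all(welch_psd(numeric(5000), sampling_rate = 1000)$power == 0))
  expect_error(welch_psd(x), "sampling_rate")
})

test_that("a pure sinusoid concentrates all Welch power at its frequency", {
  t <- (0:99999) / 1000
  s <- welch_psd(sin(2 * pi * 40 * t), sampling_rate = 1000)
  in_band <- abs(s$frequencies - 40) <= 2
  expect_gte(sum(s$power[in_band]) / sum(s$power), 0.99)
  # Parseval at the package normalization: sum(P) * df = variance
  expect_equal(sum(s$power) * 2, stats::var(sin(2 * pi * 40 * t)),
               tolerance = 0.01)
})

test_that("one-sided power integrates to the variance for broadband signals", {
  set.seed(12)
  x <- stats::rnorm(2e5)
  s <- welch_psd(x, sampling_rate = 1000)
  expect_equal(sum(s$power) * 2, stats::var(x), tolerance = 0.02)
  # for smooth spectra the ratio is a fixed constant across realizations
  # (sub-resolution power below the first bin is excluded by design)
  ratios <- vapply(1:4, function(k) {
    y <- rc_background_noise(0.035, 100, 1000, seed = k)
    sum(welch_psd(y)$power) * 2 / stats::var(y$values)
  }, numeric(1))
  expect_lt(stats::sd(ratios) / mean(ratios), 0.1)
})

test_that("per-bin estimator variance scales inversely with the segment count", {
  v_few <- apply(vapply(1:15, function(k) {
    set.seed(k); welch_psd(stats::rnorm(5000), sampling_rate = 1000)$power
  }, numeric(250)), 1, stats::var)
  v_many <- apply(vapply(1:15, function(k) {
    set.seed(100 + k); welch_psd(stats::rnorm(20000), sampling_rate = 1000)$power
  }, numeric(250)), 1, stats::var)
  ratio <- stats::median(v_few / v_many)  # 10 vs 40 segments: expect ~ 4
  expect_gt(ratio, 2.3)
  expect_lt(ratio, 7)
})

test_that("Welch spectra of simulated pulse trains match the analytic renewal spectrum", {
  # count trains (not binary) so burst collisions do not bias low frequency;
  # shape-normalized by the 100-480 Hz mean; the lowest bin (demeaning
  # bias) and the Nyquist bin (one-sided halving) are excluded
  for (shape in c(0.1, 1, 10)) {
    spec <- gamma_interval_spec(shape, 40)
    tr <- sample_gamma_train(spec, 1000, seed = round(10 * shape) + 1L)
    pulse <- events_to_pulse(tr, counts = TRUE)
    # per-bin SE estimated empirically from 10 disjoint 100 s blocks
    # (burst-count marks make the bursty train heavier-tailed than the
    # chi-square approximation)
    blocks <- vapply(1:10, function(b) {
      idx <- ((b - 1) * 1e5 + 1):(b * 1e5)
      welch_psd(pulse$values[idx], sampling_rate = 1000)$power
    }, numeric(250))
    an <- analytic_renewal_psd(spec, seq(2, 500, by = 2))
    keep <- an$frequencies >= 4 & an$frequencies <= 480
    hi <- an$frequencies >= 100 & an$frequencies <= 480
    pw <- rowMeans(blocks)
    w_n <- pw / mean(pw[hi])
    a_n <- an$power / mean(an$power[hi])
    se <- apply(blocks, 1, stats::sd) / sqrt(10) / mean(pw[hi])
    z <- (w_n[keep] - a_n[keep]) / se[keep]
    expect_lt(mean(abs(z) > 3), 0.03)
    expect_lt(stats::median(abs(w_n[keep] / a_n[keep] - 1)), 0.03)
  }
})

test_that("Poisson pulse trains have flat spectra; periodic trains have pure harmonics", {
  s_pois <- welch_psd(events_to_pulse(poisson_train(40, 500, seed = 2)))
  expect_lt(abs(fit_loglog_slope(s_pois, c(4, 500))), 0.05)
  expect_equal(nrow(find_spectral_peaks(s_pois, min_prominence_ratio = 2)), 0)

  s_per <- welch_psd(events_to_pulse(periodic_train(40, 500)))
  in_harm <- (s_per$frequencies %% 40) %in% c(0, 2, 38)
  expect_gte(sum(s_per$power[in_harm]) / sum(s_per$power), 0.99)
  pk <- find_spectral_peaks(s_per)
  expect_equal(pk$frequency[1:3], c(40, 80, 120))
})

test_that("moderately regular trains peak at their rate without harmonics", {
  s <- welch_psd(events_to_pulse(
    sample_gamma_train(gamma_interval_spec(10^1.5, 40), 500, seed = 7)))
  pk <- find_spectral_peaks(s)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$frequency - 40), 4)
})

test_that("peak detection respects range, prominence and the flat-spectrum case", {
  flat <- analytic_renewal_psd(gamma_interval_spec(1, 40), seq(2, 500, 2))
  expect_equal(nrow(find_spectral_peaks(flat, min_prominence_ratio = 0.1)), 0)
  s_per <- welch_psd(events_to_pulse(periodic_train(40, 100)))
  pk <- find_spectral_peaks(s_per, f_range = c(60, 130))
  expect_equal(pk$frequency, c(80, 120))
  expect_error(find_spectral_peaks(s_per, f_range = c(130, 60)), "f_range")
})

test_that("log-log slopes recover 0, -1 and the RC -2 power law", {
  flat <- analytic_renewal_psd(gamma_interval_spec(1, 40), seq(2, 500, 2))
  expect_equal(fit_loglog_slope(flat, c(4, 500)), 0, tolerance = 1e-12)

  f <- seq(2, 500, by = 2)
  one_over_f <- structure(
    list(frequencies = f, power = 1 / f, meta = list()),
    class = "power_spectrum")
  expect_equal(fit_loglog_slope(one_over_f, c(2, 500)), -1, tolerance = 1e-12)

  rc <- welch_psd(rc_background_noise(0.035, 200, 1000, seed = 3))
  expect_equal(fit_loglog_slope(rc, c(20, 200)), -2, tolerance = 0.2)

  zero <- structure(list(frequencies = f, power = numeric(length(f)),
                         meta = list()), class = "power_spectrum")
  expect_error(fit_loglog_slope(zero, c(2, 500)), "zero or negative")
  expect_error(fit_loglog_slope(flat, c(4, 8)), "5 frequency bins")
})
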
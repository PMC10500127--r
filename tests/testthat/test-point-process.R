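test_that("gamma interval spec derives its scale and validates parameters", {
  spec <- gamma_interval_spec(shape = 10, rate = 40)
  expect_equal(spec$scale, 1 / (10 * 40))
  expect_error(gamma_interval_spec(0, 40), "positive")
  expect_error(gamma_interval_spec(10, -1), "positive")
  expect_error(sample_gamma_train(spec, duration = -5), "positive")
})

test_that("gamma renewal trains are seed-deterministic and leave the caller's RNG alone", {
  spec <- gamma_interval_spec(10^1.5, 40)
  set.seed(777)
  before <- .Random.seed
  a <- sample_gamma_train(spec, duration = 50, seed = 42)
  expect_identical(.Random.seed, before)
  b <- sample_gamma_train(spec, duration = 50, seed = 42)
  expect_identical(a$times, b$times)
  expect_false(identical(
    a$times, sample_gamma_train(spec, duration = 50, seed = 43)$times))
  expect_true(all(diff(a$times) > 0))
  expect_true(all(a$times >= 0 & a$times < 50))
})

test_that("interval moments follow the gamma law: mean 1/f, CV 1/sqrt(a)", {
  # Oracle: moments of the interval density by direct numerical integration.
  for (shape in c(0.1, 1, 10, 10^1.5)) {
    spec <- gamma_interval_spec(shape, 40)
    dens <- function(t) t^(shape - 1) * exp(-t / spec$scale) /
      (spec$scale^shape * gamma(shape))
    m1 <- stats::integrate(function(t) t * dens(t), 0, Inf,
                           rel.tol = 1e-9)$value
    m2 <- stats::integrate(function(t) t^2 * dens(t), 0, Inf,
                           rel.tol = 1e-9)$value
    cv_true <- sqrt(m2 - m1^2) / m1
    expect_equal(m1, 1 / 40, tolerance = 1e-6)
    expect_equal(cv_true, 1 / sqrt(shape), tolerance = 1e-6)

    tr <- sample_gamma_train(spec, duration = 1000, seed = round(1000 * shape))
    ivl <- diff(tr$times)
    n <- length(ivl)
    # mean within 3 standard errors; CV within ~4 delta-method SEs
    # (kurtosis of the gamma interval density is 6/a)
    expect_lt(abs(mean(ivl) - m1), 3 * stats::sd(ivl) / sqrt(n))
    cv_hat <- stats::sd(ivl) / mean(ivl)
    cv_se_rel <- sqrt((6 / shape + 2) / (4 * n)) + cv_true / sqrt(n)
    expect_lt(abs(cv_hat - cv_true) / cv_true, 4 * cv_se_rel)
  }
})

test_that("a = 1 gives exponential intervals (Poisson train)", {
  tr <- sample_gamma_train(gamma_interval_spec(1, 40), 1000, seed = 5)
  ivl <- diff(tr$times)
  expect_lt(abs(mean(ivl) - 0.025), 3 * stats::sd(ivl) / sqrt(length(ivl)))
  expect_equal(stats::sd(ivl) / mean(ivl), 1, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(ivl, stats::pexp, rate = 40))
  expect_gt(ks$p.value, 0.001)
})

test_that("periodic trains are an exact arithmetic progression with zero interval variance", {
  tr <- periodic_train(40, duration = 1, phase_offset = 0)
  expect_equal(tr$times, seq(0, 0.975, by = 0.025))
  expect_equal(stats::var(diff(tr$times)), 0)
  off <- periodic_train(40, duration = 1, phase_offset = 0.01)
  expect_equal(length(off$times), 40)
  expect_error(periodic_train(40, 1, phase_offset = 0.025), "phase_offset")
})

test_that("periodic pulse-train power is invariant to the phase offset", {
  s0 <- welch_psd(events_to_pulse(periodic_train(40, 100, 0)))
  s1 <- welch_psd(events_to_pulse(periodic_train(40, 100, 0.01)))
  expect_equal(s1$power, s0$power, tolerance = 1e-10)
})

test_that("a degenerate single-component mixture reproduces the gamma renewal law", {
  comp <- list(gamma_interval_spec(1, 50))
  tr <- compound_train(comp, weights = 1, duration = 500, seed = 9)
  ivl <- diff(tr$times)
  ks <- suppressWarnings(stats::ks.test(ivl, stats::pexp, rate = 50))
  expect_gt(ks$p.value, 0.001)
  expect_error(compound_train(list(), duration = 10), "non-empty")
})

test_that("compound mixtures show component modes over an exponential decay", {
  comps <- list(gamma_interval_spec(1, 50),
                gamma_interval_spec(20, 80),
                gamma_interval_spec(40, 20))
  tr <- compound_train(comps, duration = 1000, seed = 2)
  h <- interval_histogram(tr, bin_width = 0.002, max_interval = 0.15)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  # analytic mixture density as the oracle
  mix_dens <- function(t) Reduce(`+`, lapply(comps, function(cp)
    stats::dgamma(t, shape = cp$shape, scale = cp$scale))) / 3
  expect_lt(max(abs(h$density - mix_dens(mids))) / max(mix_dens(mids)), 0.15)
  # the two regular components put modes near their mean intervals
  near_12 <- mids > 0.008 & mids < 0.018
  near_50 <- mids > 0.040 & mids < 0.060
  expect_gt(max(h$density[near_12]), max(h$density[mids > 0.02 & mids < 0.04]))
  expect_gt(max(h$density[near_50]), max(h$density[mids > 0.065 & mids < 0.09]))
})

test_that("cycle-phase modulation keeps only events in the retained window", {
  theta <- sample_gamma_train(gamma_interval_spec(10^1.5, 7), 300, seed = 1)
  carrier <- gamma_interval_spec(10^1.5, 80)
  mod <- modulated_train(carrier, theta, 1 / 7, keep = c(0, 0.5),
                         duration = 300, seed = 2)
  # recompute each retained event's cycle phase independently
  cyc <- c(diff(theta$times), 1 / 7)
  idx <- findInterval(mod$times, theta$times)
  expect_true(all(idx >= 1))
  phase <- (mod$times - theta$times[idx]) / cyc[idx]
  expect_true(all(phase >= 0 & phase < 0.5))

  # a full keep window reduces to the carrier after the first modulator event
  full <- sample_gamma_train(carrier, 300, seed = 2)
  all_kept <- modulated_train(carrier, theta, 1 / 7, keep = c(0, 1),
                              duration = 300, seed = 2)
  expect_identical(all_kept$times, full$times[full$times >= theta$times[1]])

  # retained rate ~ carrier rate x keep-window width
  expect_equal(length(mod$times) / mod$duration, 80 * 0.5, tolerance = 0.03)
  expect_error(modulated_train(carrier, event_train(numeric(0), 10), 1 / 7),
               "at least one event")
})

test_that("event trains discretize to binary pulse trains with collision logging", {
  tr <- event_train(c(0.1, 0.2), duration = 1)
  p <- events_to_pulse(tr, 1000)
  expect_equal(which(p$values == 1), c(101, 201))
  expect_equal(sum(p$values), 2)
  expect_equal(p$collisions, 0)

  empty <- events_to_pulse(event_train(numeric(0), 1), 1000)
  expect_equal(sum(empty$values), 0)

  close_pair <- event_train(c(0.1000, 0.1003), duration = 1)
  pc <- events_to_pulse(close_pair, 1000)
  expect_equal(sum(pc$values), 1)
  expect_equal(pc$collisions, 1)
  expect_equal(sum(events_to_pulse(close_pair, 1000, counts = TRUE)$values), 2)
})

test_that("count statistics separate super-Poissonian, Poisson and sub-Poissonian trains", {
  st_super <- train_statistics(
    sample_gamma_train(gamma_interval_spec(0.1, 40), 1000, seed = 11))
  st_pois <- train_statistics(
    sample_gamma_train(gamma_interval_spec(1, 40), 1000, seed = 12))
  st_sub <- train_statistics(
    sample_gamma_train(gamma_interval_spec(10^1.5, 40), 1000, seed = 13))
  expect_gt(st_super$fano, 1)
  expect_equal(st_pois$fano, 1, tolerance = 0.15)
  expect_lt(st_sub$fano, 1)
  expect_gt(st_super$interval_cv, 1)
  expect_lt(st_sub$interval_cv, 1)
  expect_error(train_statistics(event_train(0.5, 5), count_window = 1),
               "10 count windows")
})

test_that("interval histograms integrate to one and locate the interval mode", {
  per <- interval_histogram(periodic_train(40, 100), 0.002, 0.2)
  mids <- (per$bin_edges[-1] + per$bin_edges[-length(per$bin_edges)]) / 2
  expect_equal(sum(per$density * diff(per$bin_edges)), 1, tolerance = 1e-9)
  expect_true(abs(mids[which.max(per$density)] - 0.025) <= 0.002)

  pois <- interval_histogram(poisson_train(40, 1000, seed = 3), 0.002, 0.2)
  expect_lt(max(abs(pois$density - 40 * exp(-40 * mids))) / 40, 0.06)

  sub <- interval_histogram(
    sample_gamma_train(gamma_interval_spec(10^1.5, 40), 500, seed = 4),
    0.002, 0.2)
  expect_true(abs(mids[which.max(sub$density)] - 0.025) <= 0.004)
  expect_error(interval_histogram(event_train(0.3, 1)), "at least 2")
})

test_that("the analytic renewal spectrum is flat for Poisson and peaked for regular trains", {
  f <- seq(2, 500, by = 2)
  flat <- analytic_renewal_psd(gamma_interval_spec(1, 40), f)
  expect_equal(flat$power, rep(40, length(f)))

  sub <- analytic_renewal_psd(gamma_interval_spec(10^1.5, 40), f)
  expect_true(abs(f[which.max(sub$power)] - 40) <= 6)
  expect_equal(
    analytic_renewal_psd(gamma_interval_spec(10^1.5, 40), 5000)$power, 40,
    tolerance = 0.02)

  super <- analytic_renewal_psd(gamma_interval_spec(0.1, 40), f)
  expect_true(all(diff(super$power) < 0))
  expect_error(analytic_renewal_psd(gamma_interval_spec(1, 40), c(0, 10)),
               "DC")
})
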
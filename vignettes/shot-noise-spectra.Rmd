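---
title: "Modeling neural field-potential spectra as generalized shot noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural field-potential spectra as generalized shot noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(shotnoise)
```

## The model

The local field potential (LFP) is the superposition of voltage
deflections caused by discrete, recurring neural events — synaptic
responses, action potentials, synaptic barrages. `shotnoise` models a
single class of recurring event as *generalized shot noise*:

$$x(t) = \sum_k h(t - t_k) = (h * s)(t),$$

where $\{t_k\}$ is a point process (the event *timing train*, represented
on a sampling grid as a binary pulse train $s$) and $h$ is the fixed
*waveform* (impulse-response function) of one event. Because convolution
in time is multiplication in frequency, the power spectrum of such a
process factorizes,

$$S_x(f) \;=\; S_{\text{timing}}(f)\,\lvert H(f)\rvert^2,$$

and the spectrum of a recording that sums several independent processes
approaches the sum of their spectra. Every simulation and diagnostic in
the package is an instance of these two facts.

### Event timing

Except for perfectly periodic trains, inter-event intervals are drawn
i.i.d. from a gamma density with shape $a$ and scale $b = 1/(a f)$, so
the mean interval is $1/f$ (event rate $f$) and the interval coefficient
of variation is $1/\sqrt{a}$:

* $a = 1$: Poisson timing — flat spectrum, count Fano factor 1;
* $a > 1$: *sub-Poissonian* (regular) — suppressed low-frequency power
  and a spectral peak near $f$, with harmonics emerging as $a$ grows;
* $a < 1$: *super-Poissonian* (bursty) — power concentrated at low
  frequencies.

Some texts attach "sub/super-Poissonian" to the opposite inequality on
$a$; this package follows the count-variance definition (sub-Poissonian
= Fano factor below 1, i.e. $a > 1$), which is what the simulations
reproduce. The renewal process starts at $t = 0$ with the first event at
the first sampled interval; no equilibrium-distribution correction is
applied, a negligible end effect at the 1000 s default duration.

The closed-form (Bartlett) spectrum of a gamma renewal process,
$S(f) = f\,\mathrm{Re}\!\left[(1+\varphi)/(1-\varphi)\right]$ with
$\varphi(f) = (1 - i 2\pi f b)^{-a}$, is available as
`analytic_renewal_psd()` and serves as an independent oracle for the
simulation-plus-Welch pipeline in the test suite.

Two further timing constructions cover non-renewal cases: interval
*mixtures* (`compound_train()`: each interval drawn from a
weight-selected gamma component; equal weights by default) and
*cycle-phase modulation* (`modulated_train()`: carrier events retained
only inside a phase window of the current modulator cycle). For
modulation, the phase of a carrier event is its latency from the most
recent modulator event divided by the length of that cycle (the nominal
period is used only after the last modulator event). This makes a full
keep window exactly reproduce the carrier, and the retained rate equal
the carrier rate times the window width — neither would hold if the
phase were normalized by a fixed period, since for a quasi-periodic
modulator roughly half the cycles are longer than the nominal period.
The "upward phase" of the inverted (trough-first) cycle is its second
half; the default `keep = c(0, 0.5)` therefore drops upward-phase
events.

### Waveforms

Four families, all sampled over a hard-truncated 500 ms trace (no fade):

| family | formula | default | event origin |
|---|---|---|---|
| alpha | $t e^{-t/\tau}$ | $\tau$ = 5.6 ms | first sample |
| Morlet | $e^{-(t-\mu)^2/2\sigma^2}\sin\!\big(2\pi (t-t_0)/p\big)$ | presets below | trace center |
| Hann | one raised-cosine cycle of period $p$ | — | first sample |
| RC | $\tau^{-1} e^{-t/\tau}$ | $\tau$ = 35 ms | first sample |

Morlet presets mimic a spike ($\sigma$ = 1.7 ms, $t_0$ = 3.7 ms,
$p$ = 6.7 ms), a spindle ($\sigma$ = 66.7 ms, $t_0$ = 0, $p$ = 66.7 ms)
and a nearby-unit spike used in the summation scenario ($\sigma$ =
3.3 ms, $t_0$ = 7.3 ms, $p$ = 13.3 ms). The Morlet time axis is centered
mid-trace so $\mu = 0$ genuinely means "centered"; convolution aligns
each family's origin sample with the event time, so causal families
start at the event and Morlet events are symmetric around it.

Two spectral facts about these families matter for interpretation and
are asserted in the tests: the Morlet spectrum is centered at $1/p$ with
bandwidth inversely proportional to $\sigma$, while the single Hann
cycle (like the alpha and RC kernels) is *low-pass* — its tapered
spectrum is maximal at the lowest bin and decays to roughly the $1\%$
level by $2/p$. A strict phase-invariance of Morlet power under carrier
offset $t_0$ holds only in the narrowband regime ($\sigma \gtrsim p$);
for the broadband spike wavelet the $\pm 1/p$ spectral lobes of the real
wavelet overlap and interfere, so only the peak location is
phase-stable.

### Spectral estimation

`welch_psd()` averages one-sided squared Fourier amplitudes over
non-overlapping 500 ms segments tapered with a (periodic) Hann window:
2 Hz resolution at the 1 kHz default, 2000 segments at the 1000 s
default. Normalization is the one-sided density
$P(f) = 2\lvert X\rvert^2 / (f_s \sum w^2)$ (Nyquist bin not doubled),
constant package-wide, so $\sum P \,\Delta f$ recovers the per-segment
variance; all peak, slope and band diagnostics are invariant to this
constant.

Two numerical choices deserve note:

* **The 0 Hz bin is excluded everywhere.** For a pulse train the mean
  level is an arbitrary function of the discretization, not of the
  process.
* **Segments are demeaned before tapering** (`detrend = "constant"`,
  the default). The Hann mainlobe spans ±2 bins, so an un-removed mean
  leaks into the lowest retained bin — for a 40 Hz binary train this
  inflates the 2 Hz bin roughly fourfold and would register as a
  spurious low-frequency peak. `detrend = "none"` reproduces the raw
  tapered average.

Discretization maps events to their nearest sample; simultaneous events
collapse to a single 1 in the binary convention (a logged *collision*).
Collisions are rare for regular trains but frequent for bursty ones
($a = 0.1$ puts over half its intervals below 1 ms), which audibly
suppresses low-frequency power of the *binary* train relative to the
point process. The count-train option (`events_to_pulse(counts = TRUE)`)
preserves the process exactly; the test suite uses it when checking
simulated spectra against the analytic renewal spectrum.

### Peaks, slopes, surrogates

`find_spectral_peaks()` reports local maxima exceeding 1.5× the median
power of a ±10-bin neighborhood (ties broken leftward; grid endpoints
ineligible; a relative floor keeps float-level ripple on flat spectra
from registering). `fit_loglog_slope()` is an ordinary least-squares
slope of $\log_{10} P$ on $\log_{10} f$; the RC background is fit over
20–200 Hz, above the RC corner $1/(2\pi\tau) \approx 4.5$ Hz and below
the Nyquist roll-off.

`spectral_mode()` addresses a subtler point: the spectrum a broadband
waveform imprints on a Poisson train is a wide, flat-topped bell (the
75 Hz spike bell is within 1% of its maximum from 70–82 Hz), so the raw
argmax bin wanders several bins between realizations. The mode is
therefore located on a locally averaged spectrum whose half-width adapts
to the bell's half-maximum bandwidth (about a sixth of it); for narrow
lines it collapses to the raw argmax. Experiment summaries use this
estimator for waveform-inherited peaks, and the raw argmax elsewhere.

`poisson_surrogate_band()` implements the count-matched randomization
test: each surrogate redraws the same number of events uniformly over
the recording, is discretized and Welch-estimated identically to the
input, and the band is the per-bin empirical $(\alpha/2, 1-\alpha/2)$
quantile envelope (95% at the defaults, 1000 surrogates). Count
matching — rather than rate matching — makes the band conditional on
the observed event count, so exceedances reflect timing structure only.
Calibration is checked in the tests: fresh Poisson inputs fall outside
the band at close to the nominal rate.

## The canonical experiments

`run_experiment()` regenerates each simulation scenario from its
parameter table (see `?run_experiment` for the full list): the
point-process taxonomy and its regularity sweep, waveform inheritance
under Poisson and periodic timing, the waveform-width sweep, the
RC-background-plus-spike summation, the interval-mixture train, and
theta with theta-nested gamma. Default seeds are fixed per experiment
name so published artifacts reproduce; both are overridable.

```{r experiment, eval = FALSE}
ex <- run_experiment("s5")       # theta + theta-nested gamma, 1000 s
ex$summary$theta_peak_frequency  # 6 (the 2 Hz bin adjacent to 7 Hz)
ex$summary$modulated_lowest_peak # 6: modulation adds low-frequency power
```

A small worked example at reduced duration:

```{r worked}
tr <- sample_gamma_train(gamma_interval_spec(shape = 10^1.5, rate = 40),
                         duration = 60, seed = 1)
train_statistics(tr)[c("rate", "interval_cv", "fano")]
s <- welch_psd(events_to_pulse(tr))
find_spectral_peaks(s)
```

## What the simulations do and do not show

The generator reproduces the idealized study conditions: stationary
rates, identical waveforms for every event of a process, independent
components, Gaussian white background input. Real recordings violate
all of these — waveform amplitude and shape vary event to event, rates
are non-stationary, sources are spatially filtered and can be
phase-locked (summation then need not be additive in power). Passing
tests therefore validate the estimation and reasoning machinery, not
any claim that cortical data are gamma-renewal shot noise. The
surrogate-band test is the one tool designed for real data, and it is
deliberately conditional on event count alone.

Known limitations, by construction: no equilibrium renewal correction;
no amplitude/shape variability of waveforms; no multitaper or
overlapping-segment estimators; no time-frequency analysis; binary
discretization loses sub-millisecond burst structure (use count trains
where that matters). The spindle Morlet ($\sigma$ = 66.7 ms) is visibly
truncated by the 500 ms trace (envelope ~9 × 10⁻⁴ at the edges); no
compensation is applied.

## Problem sizes and reproducibility

All headline quantities are computed at the full study scale — 1000 s
at 1 kHz ($10^6$ samples, 2000 Welch segments) — which takes on the
order of a second per experiment. Unit and property tests run the same
code at 20–1000 s as appropriate for the statistic under test, with
Monte-Carlo tolerances derived from the realized number of intervals or
segments. Every stochastic function takes an explicit seed and restores
the caller's RNG state; experiment defaults are name-derived constants.
`scripts/acceptance.R` regenerates the headline numbers end-to-end from
a single base seed.
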
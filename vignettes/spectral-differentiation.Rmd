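---
title: "Spectral differentiation of spiking activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral differentiation of spiking activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdiff)
```

## The quantity being measured

Neurophysiological differentiation (ND) asks how many distinct activity
states a neural population visits over an interval of time. The premise is
that distinct subjective percepts must map onto distinct physiological
states of whichever population supports perception, so a region whose
activity is differentiated in register with the meaningfulness of the
stimulus is a candidate substrate of perception, whereas a region that
merely encodes stimulus information need not be.

`specdiff` implements the *spectral* flavor of this metric for spiking
data. The computation, window by window:

1. Spike times of each unit are binarized in 5 ms bins (sampling rate
   `f = 200` Hz) — a bin is 1 if it contains at least one spike — and
   convolved with a truncated Gaussian kernel (SD 10 ms, cut off at
   ±25 ms, renormalized to unit mass) to give smoothed firing rates in
   spikes/s.
2. The rate matrix is tiled with non-overlapping analysis windows of
   length `W` (default 3 s), each split into `floor(W/S)` state windows of
   length `S` (default 300 ms, so 10 states per window).
3. Within each state, the power spectral density of every unit's rate is
   computed (unnormalized forward DFT, squared magnitude, non-negative
   frequencies only, resolution `1/S` Hz) and the per-unit spectra are
   concatenated into one state vector of length
   `N * (floor(f*S/2) + 1)`.
4. The spectral differentiation of the window is the **median Euclidean
   distance over all unordered pairs of state vectors**. With an even
   number of pairs we take the mean of the two middle values.

### Normalization

Raw differentiation grows quadratically with signal amplitude (scaling all
rates by `Q` scales every PSD entry, hence every distance, by `Q^2`) and
with state-vector dimensionality. To compare across ensembles we:

* divide all rates by the *ensemble mean rate* — one scalar, the mean over
  all units of the analyzed class across the whole session — before the
  PSD step;
* divide the median distance by `sqrt(N)` (each unit contributes a fixed
  block of dimensions, and under approximately equal per-dimension spread
  the distance grows as the square root of the ensemble size); and
* divide by `S^2`, because total Fourier power grows with the square of
  the number of samples `f*S`.

So `ND = ND_raw(FR / mean(FR)) * N^-0.5 * S^-2`. The normalized value is
exactly invariant under uniform rescaling of all rates, and flat in
ensemble size for ensembles of exchangeable units (verified to ±15 % on
i.i.d. Poisson ensembles of 10–60 units in the test suite).

Each Fourier coefficient of a signal of amplitude at most `A` over `f*S`
samples is at most `A*f*S`, each PSD entry at most `A^2 f^2 S^2`, and the
normalized metric is bounded by `A^2 f^2`, independent of `N` and `S`.
Mean-normalized firing rates rarely exceed ~50, putting a practical
ceiling of `(50 * 200 Hz)^2 = 1e8 s^-2` on ND; the bound is re-checked on
every pipeline run (`bound_check_passed` in the run summary). Strictly the
metric is unbounded — a lone spike in an otherwise silent ensemble can
make the normalized amplitude arbitrarily large — which is degenerate
rather than informative, and one reason for the 10-unit minimum ensemble
size (`min_units`).

A simpler control metric, mean-firing-rate differentiation (`mfrd`), is
the variance across states of the ensemble-mean normalized rate. Here each
unit is normalized by its *own* session-mean rate (the two normalizations
deliberately differ: the spectral metric uses one ensemble scalar so that
relative rate differences between units remain part of the signal, the
control metric removes them entirely), and the variance is the population
variance (divide by the number of states).

## Timescales

The state length `S` sets the timescale of observation, and the behavior
of ND as a function of `S` depends on the characteristic timescale (CT)
of the underlying signal:

* **dense** signals (changing throughout the window) have flat ND below
  their CT and a power-law decay above it;
* **sparse** signals (mostly constant within a window, like most spike
  trains) have an interior ND optimum near their CT, since ever shorter
  states increasingly find identical (empty) activity;
* **ensembles** lose the single-unit optimum: jitter and offsets between
  units keep short-timescale states distinct, so ND keeps rising down to
  the shortest probed state length. Four high-rate virtual neurons —
  jittered copies of one spike train — already show this "loss of
  optimality", which the test suite reproduces.

For piecewise-constant signals the CT is measured directly as the mean
duration of maximal constant runs, excluding the first and last runs
(possibly truncated by the recording edges). The alternating full-field
flash stimulus (1.75 s gray, 0.25 s black or white) therefore has CT
`(1.75 + 0.25) / 2 = 1` s when the generated movie contains whole cycles
— which is why the generator emits whole cycles and the measured value is
exactly 1 s.

For everything else the CT comes from the autocorrelation of the rate
(biased `1/n` estimator, unit value at lag zero). The log-autocorrelation
is fit with a continuous two-phase decay,

```
log ac(x) = -a - x/t1                      for x <  c
log ac(x) = -a - c/t1 - (x - c)/t2         for x >= c
```

with box constraints `0 < t1 <= 1.5` s (fast timescale, the reported CT),
`0.5 <= t2 <= 20` s (slow timescale), `0.03 <= c <= 0.2` s (transition
lag) and `a >= 0`. Two numerical choices matter here:

* **Weights.** We minimize a weighted least-squares loss with weights
  `ac^2`. For an estimated autocorrelation the sampling variance of
  `log(ac_hat)` is approximately `var(ac_hat)/ac^2`, so `ac^2` weighting
  is the inverse-variance choice; it also prevents the long, nearly
  information-free tail of fast-decaying autocorrelations (where the
  bounded slow branch cannot follow the data) from biasing `t1`. With
  uniform weights a pure exponential with a 0.2 s timescale is recovered
  as `t1 = 0.14`; with `ac^2` weights as `0.18`, and curves actually
  generated by the two-phase model are recovered exactly.
* **Masking and multi-start.** Non-positive autocorrelation values are
  masked before taking logs; the bounded optimizer (L-BFGS-B) is run from
  five fixed starting points spanning the `t1` box, so the fit is
  deterministic without any seed. Fits that end on a box edge are flagged
  `at_boundary` — for a single-exponential input the flag fires because
  `t2` pins at its lower edge, which is exactly the right diagnostic.

Timescale surveys (`nd_vs_state_length`) use 20 log-spaced state lengths
from 10 ms (one sample below which nothing can be probed at 200 Hz) to
3 s, each snapped to an integer number of samples, with `W` held at 3 s.
Power-law decays are summarized by the slope of `log(ND)` on `log(S)`
above a caller-chosen `S_min`.

## Group comparisons

Window-level ND samples are compared across stimulus categories (or
areas, layers, behavioral states) with the Games–Howell pairwise
procedure: a Welch-type statistic per pair with Welch–Satterthwaite
degrees of freedom, referred to the studentized-range distribution with
`k` means. It is implemented directly (base R supplies the studentized
range distribution but not the test) and validated in the test suite
against an independent reference implementation to `1e-6`. Families of
p-values are corrected with the Benjamini–Hochberg step-up procedure
(delegated to `stats::p.adjust`), with significance stars at the
adjusted-p thresholds 0.01 / 0.001 / 0.0001.

Evoked, trial-locked differentiation uses 300 ms post-event windows with
60 ms states (five states per event) — long enough for a median of ten
pairwise distances, short enough to isolate the immediate response.
Hit/miss behavioral contrasts use a Welch two-sample test per ensemble
with BH correction across ensembles at FDR 0.01, alongside an identical
contrast on the window-mean firing rate, since elevated firing is the
obvious confound a differentiation effect must be distinguished from.
Running/stationary partitions threshold the window-mean running speed at
2 cm/s by default (a conventional rodent locomotion threshold; the split
itself, not the exact value, is the substantive choice), with ties
labeled running.

## The synthetic generator, and what passing tests do not show

No spiking dataset ships with the package; a generator module produces
every input the pipeline reads, with the statistical structure the
analyses assume:

* piecewise-constant signals and stimulus movies with stated timescales
  (gratings/Gabors 250 ms, shuffled movies 1/30 s, flashes 1.75 s/0.25 s,
  a constant gray screen), plus a naturalistic surrogate — shared
  low-rank spatial factors with AR(1) temporal correlation (0.5 s default
  correlation time) — standing in for natural movies, which cannot be
  redistributed. The surrogate targets only the property the analyses
  rely on: strong temporal correlation giving lower pixel-wise
  differentiation than gratings at the 300 ms timescale.
* inhomogeneous Poisson spike trains by thinning against the rate
  maximum; virtual-neuron ensembles as jittered or offset copies of a
  seed train, clipped (not wrapped) at session edges;
* change-detection sessions: images flashed every 750 ms (250 ms on), a
  change every fourth flash, outcomes drawn as hit/miss with probability
  0.5, and on hits a multiplicative rate transient in the 300 ms
  post-change window (amplitude 1, i.e. momentary rate doubling, decaying
  with a 150 ms time constant; 40 units with 2–15 spikes/s baselines and
  30 change trials per session by default). A rate transient is the
  simplest mechanism that produces both elevated firing and elevated
  evoked ND on hits, mirroring the empirically observed pattern. Session
  sizes were chosen as typical of a single-probe recording and keep a
  full simulated session under a second of compute.

Every generator is a pure function of its parameters and seed.

Passing the property suite on these inputs shows that the *metric* does
what its derivation says: quadratic amplitude scaling, exact
normalization invariances, the analytic bound, orthogonal non-additivity
across ensembles, the dense/sparse/ensemble timescale phenomenology, and
type-I/power behavior of the statistics under a known ground truth. It
does not show anything about biology: real cortical populations are
correlated across units, non-Poisson, and nonstationary in ways the
generator deliberately omits (no shared slow state fluctuations, no
oscillations, no refractoriness), and the published area/layer effect
sizes live in a dataset this package does not ingest.

## Numerical and design choices

* Bin edges are half-open `[t, t + 5 ms)`, time zero-based; multiple
  spikes in a bin collapse to 1 (at cortical rates this affects <2 % of
  spikes).
* The smoothing kernel is renormalized after truncation so constant
  inputs map to constant outputs; convolution is zero-padded,
  "same"-length.
* Units at exactly the 0.4 ms waveform-width threshold classify as RS
  (the RS definition is the non-strict complement of FS).
* `f*S` is snapped to the nearest integer sample count (an error is
  raised only when `S` falls below one sample); windows never straddle
  epoch boundaries and incomplete trailing windows are dropped.
* The Tukey taper (shape 1, i.e. a Hann window) is applied per state
  segment before the DFT, with segment boundaries unchanged; per-window
  ND with and without the taper agrees at Spearman > 0.9 on sessions
  with real between-window dynamic range. On a statistically stationary
  session the rank order across windows is itself mostly noise, so no
  taper-stability statement should be expected there.
* The per-unit spectrum has `floor(f*S/2) + 1` entries (DC through
  Nyquist); descriptions of the state-vector dimension as `100*N*S` are
  the same count up to the DC/Nyquist bookkeeping.
* CSV outputs are written with 10 significant digits, making repeated
  seeded runs byte-identical; every run writes its resolved configuration
  and a hash of it beside the outputs.
* Test problem sizes (60–120 s synthetic sessions, 100–200 simulated
  behavioral sessions, 500 null simulations for the statistics) were
  chosen so the full suite exercises every claim at desk scale in about
  a minute.

## Limitations

* The spectral metric quantifies temporal differentiation only; it is
  blind to spatial structure and deliberately excludes any integration
  measure.
* ND at a given `S` is a *relative* quantity, meaningful for comparisons
  at a fixed timescale — not an absolute count of states, and not
  expected to peak at a perceptually relevant timescale for ensembles.
* The mixed-effects modeling used for layer-resolved population analyses
  in the source literature is out of scope here; `compare_groups` covers
  the pairwise machinery, and users with hierarchical designs should fit
  those models with a dedicated package (e.g. lme4) on the exported
  window tables.
* The NWB/HDF5 ingestion path for public electrophysiology datasets is
  not implemented; inputs arrive as delimited text tables.
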
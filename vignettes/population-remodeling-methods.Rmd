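---
title: "Methods: quantifying pregnancy-induced remodeling of a hypothalamic parenting population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pregnancy-induced remodeling of a hypothalamic parenting population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galpop)
```

## Scope and rationale

`galpop` implements the quantitative core of a study design in which
galanin-expressing neurons of the medial preoptic area (MPOA-Gal) — a hub of
the parenting circuit — are characterized across reproductive states
(virgin, late pregnancy at day 18, post-partum) at three levels:

1. **behavior** — bout-level ethograms, retrieval-latency survival analysis,
   and behavior-to-behavior transition matrices;
2. **intrinsic and synaptic physiology** — features extracted from
   whole-cell voltage/current traces (baseline firing, resting potential,
   silent-cell classification, depolarization block, action-potential
   half-width, spontaneous postsynaptic currents);
3. **population activity** — event-aligned calcium-trace analysis
   (activated fractions, onset latencies, onset-ordered clustering), tuning
   and selectivity statistics, and stimulus separability in linear
   discriminant (LDA) space quantified by the Rand Index.

Because the original recordings are not bundled, every analysis is exercised
end-to-end on a synthetic-data generator that emulates the recording
structure and returns the planted ground truth alongside the data. The
generator is first-class, tested code: the package's validation strategy is
planted-parameter recovery, exhaustive small-`n` oracles, and null
calibration, not comparison to archived recordings.

## The synthetic-data generator

`generate_population_session()` builds a neuron-by-time fluorescence matrix
plus the event table of stimulus/behavior bouts used. Its model choices:

* **Calcium transients** are an instantaneous rise followed by a
  single-exponential decay (`calcium_decay_tau`, default 1.5 s). Rise
  kinetics are deliberately omitted: onset-latency semantics are preserved
  by the instantaneous rise, and every downstream latency statistic is
  defined relative to threshold crossings, not waveform shape.
* **Silent neurons** (fraction `silent_fraction`) carry noise only. They
  are chosen by a seeded shuffle rather than by leading index, so clustering
  and ordering tests cannot pass by index accident.
* **Evoked amplitudes** are lognormal around the neuron-by-stimulus
  `tuning_matrix` mean with CV `amplitude_cv` (default 0.3): nonnegative,
  realistically right-skewed, and mean-anchored so selectivity anchors are
  exact in expectation.
* **Latencies** are truncated-normal (>= 0) around `response_latency_mean`
  with SD fixed at 20% of the mean, which lets a shorter-latency state be
  planted and detected.
* **Bout layout**: bouts are placed on equal time slots with a 10 s lead-in
  and onset jitter capped at 2 s, guaranteeing every bout a clean pre-onset
  baseline window. The slot structure (rather than fully Poisson bout
  times) is a simplification; real assays have heavier-tailed inter-bout
  intervals. `snap_bouts = TRUE` additionally frame-locks onsets, which
  removes frame-phase variability and is used for exact definitional
  fixtures.

Defaults (20 Hz frame rate, 400-600 s sessions, 8 bouts per stimulus, 20 kHz
patch sampling) are stated in the configs and used consistently; they are
choices of this package, exposed for override.

`generate_ethogram()` draws a Markov chain over behavior labels with
exponential dwell times and merges consecutive identical labels (bout-level
ethograms leave self-transitions undefined). `generate_patch_record()`
plants triangular spikes whose width at the detection-threshold level is the
config's `ap_base_width_ms`, so the analytic half-width is exactly half that
value — an oracle for the half-width estimator. PSCs rise instantaneously
and decay exponentially; the sign convention (negative deflection = EPSC at
the modeled holding potential) is recorded in outputs.

Planted events are separated by small refractory margins (10 ms for spikes,
50 ms for PSCs) so that "recall of planted events" is well-defined; recovery
tests therefore compare against the *realized* planted trains, not the
nominal Poisson rates.

**What passing tests do and do not show.** The generator emulates the
recording *structure* (silent fractions, tuned transients, Markov bouts,
spiking and PSC waveforms), not photophysics (no bleaching, no motion, no
neuropil contamination, no crosstalk) and not real behavioral dependence
between bouts. Recovery on this substrate validates the estimators'
correctness and calibration; it does not certify performance on raw
miniscope movies, which enter this pipeline only after source extraction.

## Event-aligned population analysis

Traces are Z-scored per neuron against all samples outside any event window
padded by 2 s; zero-variance neurons are flagged constant and set to Z = 0
rather than erroring. Windows default to 2 s pre / 5 s post onset with a
0-3 s response window.

Two transient detectors serve two different questions:

* `detect_transients()` — threshold crossing at `k` baseline SDs (default 3)
  sustained for 0.2 s, with a hysteresis floor (`k_end = 0.5` SD) that
  prevents noise re-crossings on a decay tail from being counted as fresh
  events. This is the *detection* criterion behind the detected (non-silent)
  neuron count.
* `detect_transient_onsets()` — local maxima of a boxcar rise signal
  (forward minus backward 0.25 s means) above 5 robust SDs. Because
  transients rise near-instantaneously, a fresh onset is visible even on the
  tail of the previous transient, so overlapping events are counted
  separately. This is the *rate* estimator used for baseline activity;
  threshold-crossing counting would merge any event arriving within a few
  decay constants and bias rates down.

A neuron is **activated** by an event type when a one-sided paired
sign-permutation test of per-event response-minus-baseline means yields
p < 0.05 *and* the mean effect is at least 0.5 Z. All `2^n` sign patterns
are enumerated when `n` events allow; otherwise 10,000 seeded draws make the
decision deterministic. The explicit permutation scheme with a minimum
effect is this package's reproducible operationalization of an evoked
response; type-I control is verified on 500 null neurons in the test suite.

**Activated fractions** divide by the session's detected (non-silent)
count — the same notion as the detected-neuron statistic, keeping the
fraction well-defined per session. Onset latency is the first post-onset
time the mean trace holds >= 1 Z for 0.25 s. Response profiles are clustered
on unit-normalized mean traces (correlation distance, average linkage); the
cluster count maximizes the mean silhouette over 2..min(8, n-1), and
clusters are renumbered and ordered by mean onset, with ties broken by
neuron id so input order never matters.

## Tuning and selectivity

The tuning index is
`TI = (mu_resp - mu_base) / (|mu_resp| + |mu_base| + 1e-9)`, with both terms
mean rectified window Z across bouts — bounded in [-1, 1], symmetric, and
monotone in evoked amplitude, which is all its downstream use requires. The
ratio saturates when either term dominates, so rank resolution is best when
baseline activity is non-negligible; the test suite's rank-recovery oracle
plants amplitudes on a common positive baseline for that reason.

The pairwise selectivity score is `S = A_pup / (A_pup + A_other)` with
rectified evoked amplitudes, and `S = 0.5` when both are zero: 1 means
activation only during pup investigation, 0 only during the comparison
stimulus, 0.5 non-selective. Rectification keeps `S` in [0, 1] and makes
suppressed neurons non-selective rather than undefined; antisymmetry
`S(a,b) = 1 - S(b,a)` and scale invariance are tested properties.

Baseline-tuning regressions are ordinary least squares on min-max-normalized
values, with neurons pooled; animal-level grouping is out of scope and
flagged in the result so users reach for a mixed model when they need
group-aware inference.

## Stimulus separability

One sample per (neuron, bout) with temporal-bin features (mean Z per 0.5 s
bin over a 0-4 s bout-aligned window) feeds a Fisher discriminant with the
within-class scatter shrunk toward its diagonal. The shrinkage weight is
chosen by exact leave-one-out Gaussian log-likelihood over a small grid
(feature dimension is small, so exact refits are cheap; the LOO set is
capped at 200 deterministic samples for large sessions), and increased
automatically if the scatter is singular. Axis signs are fixed by making
each axis's largest-magnitude loading positive, so embeddings are
reproducible. An alternative sample definition (population vectors per
temporal bin) is available as `sample_mode = "population_bins"`.

Separability is the Rand Index between bout stimulus labels and a k-means
partition of the embedding (k = number of stimuli, fixed seed, 50 restarts,
best inertia). The choice of k-means for the partition is recorded in the
result config; the Rand Index itself is verified against brute-force pair
enumeration exhaustively for n <= 5 and on thousands of sampled partition
pairs for n = 6..8. By default the samples come from detected (non-silent)
neurons — the recorded population of an in-vivo session; silent-neuron
noise samples would otherwise dilute the partition. Per-stimulus 95%
confidence ellipsoids use the chi-square quantile of the squared
Mahalanobis radius; their coverage is verified at n = 10,000.

## Behavioral statistics

Assay summaries right-censor retrieval latency at the assay end (default
600 s, configurable). Transition matrices merge consecutive identical bouts,
then row-normalize counts; rows without outgoing transitions stay zero and
are flagged rather than renormalized. Per-edge group comparisons use the
two-sided Mann-Whitney U test — exact null when both groups have at most 8
animals, normal approximation with tie correction otherwise — and flag edges
at raw p < 0.05 by default, with an optional Benjamini-Hochberg switch that
is off by default to match the flagging convention of transition diagrams.
Kaplan-Meier curves and the log-rank test are delegated to the `survival`
package; the wrapper adds censoring bookkeeping and returns tidy curves.

## Numerical choices and degenerate inputs

* Zero-variance neurons, all-constant matrices, single-bout ethograms,
  all-censored survival groups, and zero-denominator fractions all return
  flagged results instead of raising, because they occur in real sparse
  sessions.
* The depolarization-block rule — per-step spike counts dropping below 50%
  of the maximum across lower steps while mean step voltage sits >= 5 mV
  above the spiking steps — is this package's operationalization; cells
  with fewer than 2 spikes at every step are reported indeterminate.
* The silent-cell criterion is < 0.05 Hz over the baseline window, i.e. no
  spike in 20 s.
* PSC detection requires a fast rise (half the amplitude threshold within
  1 ms) and a single-exponential decay with a time constant inside
  configurable bounds, which rejects both slow drifts and re-crossings on
  decay tails; a 0.5 ms boxcar pre-smoothing suppresses single-sample noise.
* Problem sizes in the tests (60-500 neurons, 200-400 s sessions, 20-40 s
  patch records, 20 seeds per recovery suite) were chosen so each planted
  parameter's recovery error is a few standard errors wide at most —
  sufficient for 3 SE acceptance bands without redundancy.

## Known limitations

* No cross-session registration of neuron identity: sessions are analyzed
  independently, so longitudinal statements are population-level.
* No deconvolution to spikes; all calcium statistics are transient-level.
* No mechanistic channel models behind silencing or depolarization block;
  pharmacological and knockout conditions are plain group labels.
* The tuning-index formula and activation criterion are explicit
  operationalizations; studies with access to their own criteria should set
  the corresponding parameters rather than assume equivalence.
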
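---
title: "Ventral-horn MEA analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventral-horn MEA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhmea)
```

## The scientific problem

In the severe mouse model of spinal muscular atrophy (SMA), ventral-horn
motor neurons degenerate within the first post-natal week. Planar
multi-electrode arrays (MEAs) such as the MED64 — an 8×8 grid of 64
electrodes at 75 µm pitch — record extracellular voltage simultaneously
across a spinal-cord slice positioned so that only the ventral horn lies
over the grid. Three quantities summarize each slice: how many electrodes
record spiking at all, how fast the active sites fire, and how many
distinct neurons ("units") each active electrode picks up. `vhmea`
implements the full analysis chain for such recordings — preprocessing,
spike detection, active-electrode classification, spike sorting and
group statistics — together with a synthetic recording generator that
plants known activity, so that every stage can be validated by parameter
recovery instead of relying on tissue data.

## The analysis chain

### Preprocessing

Raw traces are sampled at 20 kHz in 50-s segments. Each electrode is
band-pass filtered between 85 Hz and 2.5 kHz and then linearly detrended
by least squares. The filter family and order are free choices (the
recording protocol prescribes only the cutoffs); we use a 4th-order
Butterworth high-pass cascaded with a 4th-order Butterworth low-pass,
each applied forward–backward so the passband group delay is zero and
spike timing is preserved. Coefficients come from `signal::butter`; the
forward–backward application is compiled code with odd-reflection padding
of roughly six high-pass time constants at each segment end, so onset
transients never reach the detector. Filtering before detrending follows
the order in which the two steps are conventionally described; a
`detrend_first` flag swaps them (the result is indistinguishable for
in-band signals, since the filter itself removes almost all linear
trend).

### Spike detection

The noise scale δ of each preprocessed trace is its plain sample standard
deviation — not a robust estimate; a median-based alternative sits behind
the `robust` flag — and the detection threshold is ±4.5 δ, applied to the
absolute trace so positive- and negative-going spikes form one event
stream. One event is emitted per supra-threshold excursion, timestamped
at its extremum; events closer than a 1 ms dead time merge, keeping the
larger extremum. A 64-sample (3.2 ms) snippet is cut around each
extremum, re-aligned to the sub-sample peak located by cubic-spline
interpolation. The re-alignment matters: without it the ±1-sample
discretization of peak position splits each unit's waveforms into two
shift families that clustering then mistakes for separate units.

An electrode is *active* when it records at least 50 spikes in a 50-s
segment (equivalently ≥ 1 Hz); the boundary is exact — 50 is active, 49
is not. Firing frequency is reported per 25-s window, two observations
per electrode per segment. δ is computed once per 50-s segment (not per
25-s half), and activity is classified per segment.

### Spike sorting

Sorting is per electrode: the full 4-level orthonormal Haar decomposition
of each aligned snippet (64 coefficients), a Lilliefors-type
deviation-from-normality score per coefficient across spikes — the
Kolmogorov–Smirnov distance from a normal with the sample's own mean and
SD, which is largest for multimodal (i.e. unit-discriminating)
coefficients — and the ten highest-scoring coefficients as features.
Clustering is superparamagnetic: spikes become q = 20-state Potts spins
on a symmetrized 11-nearest-neighbour graph with couplings
$J_{ij} = \frac{1}{\hat K} \exp(-d_{ij}^2 / 2a^2)$ (a = mean neighbour
distance, $\hat K$ = mean degree), simulated by Swendsen–Wang dynamics
over a temperature grid of 0–0.20 in steps of 0.01 (20 burn-in plus 100
measurement sweeps per temperature); pairs with spin–spin correlation
above 0.5 are linked, and connected components of the linked graph are
the clusters. All of these values are the published defaults of the
wavelet/superparamagnetic sorting family and are configurable through
`spc_config()`.

**Working-temperature rule.** The cited clustering method leaves the
temperature-selection heuristic open, so the rule here is pinned
explicitly and covered by tests: the scan passes from a ferromagnetic
phase (one merged cluster) through a superparamagnetic window (the
natural groups, stable over many temperatures) to a paramagnetic phase
(fragments below the minimum cluster size). The count of clusters with at
least `min_cluster_size` (= 15) members is therefore constant across the
superparamagnetic window and volatile outside it; we take the *longest
temperature plateau of constant positive cluster count* and use its first
temperature, where cohesion — and with it the fraction of assigned
spikes — is greatest. Variants that chase the highest temperature with
large clusters systematically land in the melting regime and undercount.
Spikes in clusters smaller than 15 stay unassigned (label 0); unassigned
spikes are excluded from unit counts but retained in all frequency
computations, which are electrode-level and pre-sorting. Noise clusters
are thereby never counted as neurons.

### Slice and condition statistics

Per slice we report the active-electrode count, the mean of the 25-s
frequency observations over active electrodes, and total spikes per
minute summed over active electrodes. Frequency distributions pool the
25-s observations across a condition's slices with each slice normalized
to total mass one, binned at 0.5 Hz (left-closed). The pooled
distributions are fitted with a K = 3 univariate Gaussian mixture by EM
(10 kmeans++-style seeded restarts, variance floor $10^{-6}\,
\mathrm{var}(x)$, convergence at a log-likelihood gain below $10^{-8}$
per observation or 500 iterations; a BIC mode over K = 1..5 exists but is
off by default). Between-condition location shifts are tested with the
tie-corrected Kruskal–Wallis test at α = 0.01 on the raw pooled
observations (slice-normalized weights are used only for the histograms),
and the per-slice summary quantities with one-way ANOVA at α = 0.05.
Reported dispersions are SEMs, and are labelled as such in every output.

## The synthetic recording generator

Because no raw recordings are deposited for this preparation, validation
uses synthetic MED64-style segments with planted ground truth. The
generator emulates:

* an 8×8 grid with a tissue mask of 36 electrodes (the 6×6 corner
  sub-grid — "just over half the grid"); any mask of ≥ 25 sites works;
* stationary Gaussian background noise (default SD 5 µV) plus slow drift:
  a 0.5 Hz sinusoid (100 µV, random phase per electrode) and a linear
  ramp (≤ 50 µV per segment, random slope) — both far below the 85 Hz
  high-pass cutoff, existing precisely so that preprocessing has
  something consequential to remove;
* per-electrode spiking units: biphasic templates (Gaussian main lobe,
  opposite-polarity rebound, cosine edge taper) with distinct amplitude
  (8–15× noise SD), width (0.3–0.72 ms FWHM), rebound fraction and
  polarity; per-spike multiplicative amplitude jitter of 5%;
* refractory Poisson spike trains (2 ms dead time). The configured rate
  is the *effective* rate: the exponential intensity is inflated to
  $r/(1 - r\tau)$ so the expected count over the segment is exactly
  rate × duration.

Condition presets fix, per slice, the number of active electrodes, units
per active electrode and the aggregate per-electrode rate, at the
reported group statistics: control basal 15 electrodes / 5 units /
6.08 Hz; SMA basal 6 / 4 / 5.48 Hz; control serotonin 25 / 7 / 10.20 Hz;
SMA serotonin 11 / 5 / 6.98 Hz; and the acetylcholine, bicuculline and
GABA rows from the corresponding pharmacology table. Unit counts in
presets are integers (the reports give averages of 5, 4 and 7), and each
active electrode receives exactly that many units with rates summing to
the aggregate — the simplest planted truth consistent with the summary
statistics. Whether the reported per-electrode "spike frequency"
aggregates all units on the electrode is not stated in the source
reports; the simulator assumes it does. Drug effects are modelled purely
as preset changes in planted activity — no receptor kinetics — because
only activity outcomes are measured. Inactive tissue electrodes receive
one sub-criterion background unit (0.3 Hz), and planted counts are
re-drawn in the (astronomically rare) event that an active electrode
would fall below, or an inactive one reach, the 50-spike criterion, so
activity recovery is well-posed by construction.

What the generator deliberately does **not** model: conductance-based
neuron dynamics, electrode-distance amplitude decay, cross-electrode
spike correlation, bursting or rate non-stationarity, electrode artifact
or line noise. Passing recovery tests therefore shows that the analysis
chain is correct and well-calibrated for threshold-clearing,
template-stable units over Gaussian noise — not that it would meet the
same numbers on real tissue, where waveform drift and overlapping bursts
degrade any sorter.

## Numerical choices and degenerate inputs

* Zero-variance traces are a detection error (`degenerate signal`), not a
  silent zero threshold; constant feature sets cluster into a single unit
  without error.
* Excursions too close to a segment edge for a full snippet are dropped
  from both the event table and the waveform matrix (their count is
  negligible: ~3 ms out of 50 s).
* The EM variance floor prevents component collapse; components are
  reported sorted by mean. Ties in Kruskal–Wallis use mid-ranks with the
  standard tie correction; an all-tied sample is defined as H = 0, p = 1.
  A degenerate ANOVA with zero between- and within-group variance is
  defined as F = 0.
* Swendsen–Wang dynamics draw from R's RNG; clustering saves and restores
  the caller's RNG state and is bit-reproducible given `spc_config(seed)`.
  Because randomness is consumed in data order, permuting spikes
  reproduces the same units but may flip a small fraction of
  borderline spikes between assigned and unassigned.
* At T = 0 the bond probability is taken as 1 (the zero-temperature limit),
  making the first scan point exactly the connected components of the
  neighbour graph.

## Problem sizes used in validation

The recovery experiments simulate full-scale segments (64 electrodes ×
50 s × 20 kHz): 12 control-basal slices, 11 SMA-basal slices and 12
control-serotonin slices for activity and frequency recovery — matching
the reported group sizes — and 4 control-basal slices (~60 active
electrodes) for units-per-electrode recovery, where each electrode is an
independent sorting problem and additional slices only replicate the
same measurement. Property tests run on smaller segments (1–10 s) where
the tested invariant does not depend on segment length; the activity
criterion is pro-rated (1 Hz) for such segments.

## Known limitations

* The sorter is per-electrode; the same neuron seen by two electrodes is
  counted twice, as in the underlying experimental analysis.
* No overlap decomposition: two units firing within the 1 ms dead time
  merge into one event (~1% of spikes at 6 Hz aggregate rates), which is
  why detector recall is validated at ≥ 99% rather than 100%.
* The Gaussian-mixture fit fixes K = 3 by default to match the observed
  firing-rate distributions; on data with fewer modes the extra
  components share weight rather than degenerate, thanks to the variance
  floor.
* Statistical significance patterns (e.g. which condition contrasts pass
  α = 0.01) are reproduced in direction only; exact p-values depend on
  sample constructions that are not fully specified in the source
  reports.
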
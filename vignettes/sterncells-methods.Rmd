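---
title: "Methods: permutation-based cell selection for Sternberg working-memory sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based cell selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterncells)
```

## The data model

A session is one run of either the screening task or the Sternberg
working-memory task by one subject. The Sternberg trial consists of a
fixation cross (900–1000 ms), sequential encoding of 1–3 images ("load",
1 s each, separated by 1–200 ms blanks), a blank maintenance delay
(2.5–2.8 s), and a probe image that stays up until the subject answers
whether it was part of the encoded set. Sessions have 108 or 135 trials over
5 images. The screening task shows 54–64 images six times each for 1 s with
a 16–200 ms inter-stimulus interval.

All timestamps live on one session clock in seconds. Trials use 1-based
picture ids with 0 meaning "absent"; the stimulus template collection uses
0-based indices where index 5 is the null image referenced for absent
encoding slots (at +10 ms offsets to keep presentation timestamps strictly
increasing). The adapter owns this mapping (template index = picture id − 1)
so downstream code sees only the 1-based convention — keeping both
conventions out of the analysis code is the cheapest way to avoid
off-by-one errors.

Event streams are hardware TTL markers. The Sternberg grammar per trial is
fixation (11) → picture onsets (1, 2, 3) separated by transitions (5) →
end-of-encoding/delay onset (6) → probe onset (7) → response (8), framed by
61/60 experiment markers; screening uses picture on/off (1/3) and
control-question responses (4). The parser is a strict state machine: any
out-of-grammar code is a parse error carrying the zero-based stream offset,
because silently resynchronising a corrupted event stream would
misalign every downstream rate estimate.

## Windows and rates

All response windows are half-open `[t0, t1)`, so adjacent windows partition
time and every spike is counted exactly once. The windows are:

| period      | window                        | default |
|-------------|-------------------------------|---------|
| baseline    | from fixation onset           | 0.5 s   |
| encoding    | after each image onset        | 0.2–1.0 s |
| maintenance | after delay onset             | 0–2.5 s |
| probe       | after probe onset             | 0.2–1.0 s |

The baseline is taken as the *first* 500 ms of the fixation period
(fixation lasts 900–1000 ms, so the first and last 500 ms differ; a
`baseline_last` flag selects the alternative). Absent encoding periods
yield `NA` rates, never zeros — zero-filling would bias every load-1/2
contrast. PSTHs use 50 ms bins and Gaussian smoothing whose width parameter
is interpreted as the kernel SD of 75 ms (`smooth_as_fwhm` selects the FWHM
reading); raw binned counts are kept alongside and conserve the spike
count. The session mean rate divides by the task event span (first to last
TTL), not the wall-clock recording length.

## Permutation tests

Both test statistics are classical — the one-way ANOVA F over image groups,
and the difference of sample means for two-sample comparisons — but their
null distributions come from uniform label permutation, which makes no
distributional assumption about firing rates. Monte-Carlo p-values use the
add-one convention `p = (1 + #{permuted ≥ observed}) / (n_perm + 1)`
(n_perm defaults to 1000), so p is never zero, is bounded below by
`1/(n_perm+1)`, and is exactly reproducible from the seed. For small
samples, `exact = TRUE` enumerates every distinct assignment of
observations to groups and reports the exact permutation p (the identity
assignment counts itself, so this is a valid p-value). Ties are compared
with a `1e-12` slack so that exact ties count as "at least as extreme",
the conservative convention.

Seeds for each unit's tests are derived from the analysis seed and the
*unit id* (not its list position), which makes classification invariant to
unit ordering and lets reruns reproduce individual units.

## Cell selection

**Concept cells** (visual selectivity): a permutation ANOVA of the
stimulus-window rates with image identity as the factor — x groups, where
x is the number of unique images in the session (5 for Sternberg, 54–64
for screening) — followed, if significant, by a one-sided permutation
t-test that responses to the empirically maximal ("preferred") image exceed
the pooled responses to all other images. Both must pass at α = 0.05. The
preferred image is determined from encoding presentations, with exact ties
resolved to the lowest image id. By default the ANOVA pools encoding
presentations (all positions) with probe presentations, since the probe is
a full-contrast presentation of a known image; `concept_pool_probe = FALSE`
restricts to encoding. Two deliberate properties are worth noting: the
pooled max-vs-rest test admits cells selective for *more than one* image
(such a cell is visually selective, which is the construct being measured),
and testing the empirically maximal image introduces a selection bias that
is accepted as-is to mirror the published procedure — no correction is
applied, and no multiple-testing correction is applied across units
(selection is reported per cell at α = 0.05).

**Maintenance cells** (content-invariant delay activity): a one-sided
permutation test that maintenance-window rates exceed baseline rates across
trials. A unit that is also a concept cell must additionally show the
elevation restricted to trials *not* containing its preferred image;
without this, every strongly persistent concept cell would automatically
classify as a maintenance cell, conflating content-carrying and
content-invariant delay activity.

**Probe cells**: two separate one-sided permutation t-tests — probe-window
rates against the pooled encoding-window rates of all encoding periods, and
against maintenance-window rates. Both must pass.

The three labels are not mutually exclusive. In particular a concept cell
whose preferred image appears as the probe on ~20% of trials has a
genuinely elevated mean probe rate and can pass the probe criteria; this is
a property of the published selection scheme, not a defect of the
implementation.

**Persistent activity** across the concept-cell population is quantified as
each concept cell's mean maintenance rate on trials whose encoding set
contains its preferred image versus trials without it, compared with a
paired one-sided t-test across cells (a parametric test is appropriate here
because the paired cell means are averages over many trials).

**Screening image selection** reproduces the procedure used to pick the 5
Sternberg images: units are scored by the permutation ANOVA; the preferred
images of significant units, ranked by F and deduplicated, are chosen; any
remaining slots are filled by the images with the largest across-unit peak
mean response.

### Null calibration

Under the null, the ANOVA and the equal-window t-tests reject at almost
exactly α (the residual deviation is the `floor((n_perm+1)α)/(n_perm+1)`
granularity plus rare exact ties). One caveat is documented rather than
hidden: the maintenance test compares a 2500 ms window with a 500 ms
window, whose rate estimates have unequal variances and skewness under the
null even at equal trial counts. With equal group sizes the permutation
mean-difference test is asymptotically valid regardless, but at 108 trials
its measured one-sided type-I error is ≈5.5–6% rather than exactly 5%.
This is a property of the published window choice; the acceptance checks
therefore gauge all null rates against the exact binomial 95% band around
5% at 1000 units (≤ 6.4%).

## Spike-train and sorting-quality metrics

- **ISI violations**: percentage of consecutive inter-spike intervals below
  3 ms (undefined below 2 spikes).
- **CV2**: mean over consecutive ISI pairs of `2|a−b|/(a+b)`; 0 for a
  regular train, and exactly 1 in expectation for iid exponential ISIs
  (for X, Y iid exponential, `E[2|X−Y|/(X+Y)] = 1`), which the tests verify
  by simulation at 10⁵ ISIs.
- **Clustering features** per spike: energy (Σx²), signed peak amplitude,
  total area (Σ|x|), and the scores on the first five principal components
  of the energy-normalized waveforms, with the PCA fit on all spikes of an
  electrode pooled so that units on one wire share a basis.
- **Isolation distance**: the squared Mahalanobis distance — under the
  cluster's own mean and covariance — of the n-th closest non-member spike,
  n being the cluster size. The "noise" set for a unit is every
  same-electrode spike assigned to another cluster; the metric is undefined
  when there are fewer noise events than cluster spikes (which includes
  every unit alone on its wire) or when the cluster covariance is singular.
  Values are reported on the squared scale, the convention of the metric.
- **Projection test**: both clusters are projected onto the line joining
  their means; the separation of the projected means is reported in units
  of the pooled within-cluster SD of the projections. It is symmetric and
  invariant under rigid motions of the feature space.
- **SNR**: the noise SD is the SD of waveform residuals (waveform minus the
  unit's mean waveform) pooled over samples and spikes; `snr_peak` divides
  the peak of the mean waveform by it, `snr_mean` averages `|mean|/SD` over
  samples. The peak-SNR reading (signal over noise, giving values around
  6–7 for clean units) is used throughout; the inverse ratio would produce
  values well below 1 and is inconsistent with reported magnitudes.

## The synthetic session generator

The generator emulates exactly the statistical structure the analyses
assume: the trial grammar and TTL streams above (timings drawn uniformly
from the task's ranges), loads drawn with equal probabilities (the task
describes pseudo-random selection without stating ratios), probe in/out
balanced 50/50 with the probe drawn uniformly from the eligible set, and
behavioural responses with `p_correct = 0.89` and per-load shifted
lognormal RTs (medians 0.70/0.80/0.90 s, shift 0.2 s, σ_log = 0.3) — values
chosen to produce the observed ~89% accuracy and the load-dependent RT
slowing of this task family. Encoding repeats within a trial are off by
default (a flag enables them).

Units are inhomogeneous Poisson processes with an absolute refractory dead
time of 3 ms, simulated per piecewise-constant rate segment and pruned
sequentially; pruning shrinks a nominal rate r to approximately
`r/(1 + r·dt)`, i.e. ~3% at 10 Hz, which the recovery tests account for.
Class rate profiles: null units fire at the 2 Hz baseline everywhere;
concept units elevate to 10 Hz from 200 ms after every onset of their
preferred image (the latency matches the analysis window start and is
configurable); maintenance units elevate to 8 Hz through every delay
period; probe units to 8 Hz after every probe onset. `concept_persistent`
adds 6 Hz delay-period firing on preferred trials only, the substrate of
the persistence contrast — and because that persistence is content-locked,
such units must *fail* the maintenance-cell invariance test, which the
suite checks. Waveforms are a biphasic template scaled to ~66 µV peak plus
white noise of 10 µV SD (peak SNR ≈ 6.6, a typical clean-unit value); two
template shapes alternate across the two units placed on each electrode so
that same-wire cluster metrics are exercised.

What the generator does *not* emulate: rate drift and non-stationarity,
bursting and serial ISI correlation, overlapping spikes and sorting errors,
correlated noise across units, realistic image content, or LFP/broadband
signals. Passing the suite therefore demonstrates the statistical machinery
is correct and calibrated under the task's design — not that real
recordings satisfy the Poisson or stationarity assumptions.

## Problem sizes and numerical choices

The calibration and recovery studies run at: 1000 null units (10 sessions
× 100), 200 planted units per class (20 sessions × 10) at 108 trials and
1000 permutations — sizes at which every per-condition cell count exceeds
20 presentations and the binomial bands are tight enough to be meaningful,
while a full run stays in the minutes range on one CPU. Exhaustive
permutation enumeration is used up to ~10 observations; the brute-force
Mahalanobis oracle up to 500 points. Reals round-trip the plain-text
fixture format via 17-significant-digit decimal; degenerate inputs
(all-identical responses, zero-energy waveforms, singular covariances,
zero-length spans) return defined answers (`p = 1`, flagged rows, `NA`
with a reason) rather than errors wherever the quantity has a sensible
value.

## Known limitations

- The NWB adapter reads and writes the session group layout described
  above; it does not validate or emit standards-compliant NWB metadata.
- Dataset-level replication of published selective-cell proportions
  requires the released recordings (a multi-gigabyte archive download) and
  is out of scope for the test suite; the pipeline (`run_pipeline`) applies
  unchanged to such sessions once converted.
- The repeated-measures ANOVA aggregates sessions to subjects (mean of
  per-session medians) before testing, matching the convention implied by
  its degrees of freedom in this literature; it handles complete tables
  only and performs no imputation.
- Whether published RT medians pool incorrect trials is not stated in this
  task family; both modes are provided (`correct_only`), with pooling as
  the default.
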
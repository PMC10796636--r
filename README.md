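# sterncells

Analysis machinery for **human single-neuron recordings during an image-based
Sternberg working-memory task**, the paradigm used in intracranial
depth-electrode studies of the medial temporal lobe (MTL: hippocampus,
amygdala) and medial frontal cortex (MFC: dACC, pre-SMA, vmPFC). Each session
comprises sorted single units (spike times and extracellular waveforms), a raw
TTL event stream, a trials table, and the presented image stimuli; a preceding
*screening* session (54–64 images, six presentations each) identifies the five
images used in that subject's Sternberg session.

The package is aimed at electrophysiologists working with this kind of data:
it parses the event streams into trials, computes the behavioural statistics,
selects functional cell classes with permutation tests, and computes the
standard spike-sorting quality metrics — all exercised end-to-end on a
ground-truth-labelled synthetic session generator, so every stage is testable
without any data download.

## What it computes

**Cell selection** (all tests are label-permutation tests at per-cell
α = 0.05, firing rates in fixed windows):

- *Concept cells* — visually selective units. A one-way permutation ANOVA of
  the stimulus-window rate (200–1000 ms after image onset) with image identity
  as the factor (x groups, x = number of unique images), **and** a one-sided
  permutation t-test that the preferred (maximal) image's responses exceed all
  other images' responses pooled.
- *Maintenance cells* — delay-period activity regardless of content: rate in
  the maintenance window (0–2500 ms after delay onset) exceeds the fixation
  baseline (500 ms), one-sided. A concept cell must additionally show the
  elevation on trials *not* containing its preferred image.
- *Probe cells* — rate after probe onset (200–1000 ms) exceeds both the
  encoding and the maintenance rates (two one-sided tests).
- *Persistent activity* — across concept cells, a paired one-sided t-test of
  delay-period rate on preferred vs non-preferred trials.

Monte-Carlo p-values use the add-one convention
`p = (1 + #{permuted ≥ observed}) / (n_perm + 1)`; `exact = TRUE` enumerates
all group assignments on small samples.

**Behaviour** — per-load accuracy and median reaction time (RT measured from
probe onset), and a one-way repeated-measures ANOVA of per-subject median RTs
(`F = MS_load / MS_subject×load`, df = (k−1), (k−1)(n−1)).

**Spike metrics** — windowed rates (half-open windows), PSTHs (50 ms bins,
75 ms Gaussian smoothing), ISI refractory violations (< 3 ms), CV2, and
session mean rate.

**Sorting quality** — per-spike clustering features (energy, peak amplitude,
total area, first five PCs of energy-normalized waveforms, fit per
electrode), isolation distance (squared Mahalanobis radius containing as many
same-wire non-member spikes as the cluster has members), the projection test
(mean separation of two same-wire clusters in pooled projected-SD units), and
waveform SNR (peak and mean).

## Worked example

```r
library(sterncells)

cfg <- generator_config(n_trials = 108, seed = 7,
                        n_units = c(concept = 2, maintenance = 2,
                                    probe = 2, null = 2))
s <- generate_sternberg_session(cfg)
print(s)
#> <wm_session> sternberg task, subject S007 (P17XX)
#>   8 units on 8 electrodes | 108 trials | 778 events | 432 presentations
#>   ground truth: concept=2, maintenance=2, null=2, probe=2

behavior_by_load(s$trials)
#> Behaviour over 108 trials: 91.67% correct
#>  load n_trials accuracy_pct median_rt_s
#>     1       34     91.17647   0.6851858
#>     2       30     93.33333   0.7590460
#>     3       44     90.90909   0.8936297

cl <- classify_cells(s, analysis_config(n_perm = 1000, rng_seed = 1))
summary(cl)
#> Cell classification over 8 units
#>  region n_units n_concept pct_concept n_maintenance pct_maintenance n_probe pct_probe
#>     MTL       4         2          50             2              50       1        25
#>     MFC       4         0           0             0               0       2        50

summary(unit_quality(s))
#> Spike-sorting quality over 8 units (mean, SD, median, n defined)
#>                       mean      sd   median n
#> pct_isi_below_3ms    0.000   0.000    0.000 8
#> mean_rate_hz         2.718   0.666    2.558 8
#> cv2                  0.998   0.012    0.996 8
#> snr_peak             6.429   1.396    6.103 8
#> ...
```

The two planted concept cells, both maintenance cells and both probe cells
are recovered, and the null units are not flagged. (One MTL concept cell is
*also* flagged as a probe cell: it fires to probe presentations of its
preferred image, and the selection criteria are not mutually exclusive —
see the methods vignette.) `run_pipeline()` applies the same stages to a
directory of
sessions (plain-text fixtures via `save_fixture()`/`load_fixture()`, or
NWB-style HDF5 via `load_nwb_session()`) and aggregates a dataset summary
with MTL/MFC selective-cell proportions.

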
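---
title: "Models, statistics and design choices in restalpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in restalpha}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`restalpha` implements a complete sensor-to-source EEG group analysis for
longitudinal brain-computer interface (BCI) studies built around the
*intentional rest* control condition: participants move a cursor down by
voluntarily clearing their minds, and the question is whether an
intervention group (mindfulness-based stress reduction, MBSR) changes the
underlying alpha-band physiology differently from waitlist controls across
training.

The analysis chain is

1. **Preprocessing** — zero-phase 1–100 Hz band-pass, 1 kHz to 250 Hz
   resampling, spherical-spline interpolation of bad channels, common
   average reference, template-matched ICA removal of exactly two ocular
   components, extraction of the final 1 s of each feedback period, and
   automated variance-based trial rejection.
2. **Spectral analysis** — single-window Hann-taper power, 1–50 Hz in 1-Hz
   steps, per trial then trial-averaged; plus an offline re-creation of the
   online control signal (Burg maximum-entropy AR amplitude of the
   small-Laplacian C3/C4 signals in a 3 Hz bin around 12 Hz, z-normalized,
   updated every 40 ms).
3. **Source localization** — DICS: a band-limited sensor cross-spectral
   density (CSD), unit-gain minimum-variance spatial filters
   `A = (L' C⁻¹ L)⁻¹ L' C⁻¹` from the real part of the regularized CSD,
   dominant-orientation reduction, and noise-normalized source power maps.
4. **Connectivity** — orthogonalized power-envelope correlation between the
   analytic band signals of 90 ROI centroids (4,005 unique pairs), the
   leakage-robust stationary coupling measure.
5. **Group statistics** — the interaction contrast
   MBSR(last−first) vs control(last−first), tested by (a) a cluster
   permutation test with spatial-spectral adjacency at the sensor level and
   spatial adjacency at the source level, and (b) the network-based
   statistic (NBS) on connectivity edges; plus Pearson correlations of
   neural change with practice minutes and with the change in percent valid
   correct (PVC = hits / (hits + misses)).

Everything runs against a synthetic cohort generator with machine-readable
ground truth, so each stage is testable end to end without any data
download.

# The statistical machinery

## Interaction contrast and element tests

Each subject contributes one difference map (last session − first session)
of log₁₀ power per (channel, frequency) element, or of envelope correlation
per ROI pair. Two-sample pooled-variance t statistics compare the groups
element-wise (Welch available behind a flag). Log power is the default
scale: EEG band power is approximately log-normal across subjects, and on
the raw scale a handful of high-power subjects dominate every element's
variance, costing most of the test's sensitivity. The raw scale remains
available (`power_log = FALSE`).

## Cluster permutation test

Elements with |t| above the two-sided α = 0.05 quantile are split by sign
and joined into connected components under the adjacency graph: Delaunay
triangulation edges of the azimuthal-equidistant sensor projection define
spatial neighbours, and bins 1 Hz apart are spectral neighbours. A
sensor-frequency cluster must span at least two distinct channels *and* two
distinct frequency bins; source-grid clusters (points within 1.25 grid
spacings adjacent) must contain at least two points. Cluster mass is the
summed t. The null distribution is the maximum absolute admissible cluster
mass over label permutations that preserve group sizes, with
`p = (1 + #{null ≥ |mass|}) / (1 + n_perm)`, so p is never zero. Both tails
are compared against the same max-|mass| null and declared significant at
p < 0.05 (per-tail α splitting is available via `tail_split`).

## Network-based statistic

Edge-wise t tests on the 4,005 pairs are pruned at p < 0.005 per sign; the
connected components of the surviving ROI graph are scored by edge count
and compared against the permutation null of the maximum component size.
A single suprathreshold edge is a valid component of size 1.

## Degenerate inputs and tie-breaking

Elements with zero variance in both groups get t = 0 and a flag. Component
labeling is deterministic (lexicographic by lowest member index), as is the
Delaunay triangulation: grid-like layouts contain exactly cocircular
quadruples, which an index-keyed jitter of order 1e-7 resolves
reproducibly; either diagonal of such a quad is an equally valid adjacency.

# The synthetic world

The generator commits to one cohort model, fixed a priori:

* **Background**: 30 broadband 1/f (exponent 1.0) sources at random grid
  points plus pink sensor noise (2 µV), projected through an analytic
  single-sphere head model (exact Legendre-series dipole potentials,
  electrodes at radius 1, sources inside radius 0.85).
* **Alpha sources**: band-limited (9–15 Hz) Gaussian noise — i.e.
  amplitude-modulated narrowband noise, not sinusoids — with per-trial
  log-normal envelopes (SD 0.4 on the log scale). Ten target grid points
  sit under a frontal anchor; six posterior distractors and the eight
  coupled ROI-centroid sources run at half the target amplitude so that the
  designated sensors carry the injected effect rather than bystander
  oscillators.
* **Power effect**: each subject's latent log alpha-power change is
  `σ_w (z_i + m_g)`, `z_i ~ N(0,1)`, `σ_w = 0.45` (between-session alpha
  drift of ~45%, within the empirically typical range), and `m_g` set so
  that the *measured sensor-level* standardized group × session difference
  at the 8 designated channels equals `power_effect_size`: the group mean
  is divided by the mean share of target-source band power at those
  channels, compensating leadfield dilution. The ground truth lists the
  designated channels × 9–15 Hz bins as the expected-suprathreshold
  elements.
* **Envelope coupling**: a fixed connected 10-edge subgraph over eight
  frontolimbic ROIs (LIM/DMN/FPN networks, maximum degree 3). Each member
  source's log envelope mixes per-edge shared factors with weight `w`, so
  adjacent members correlate ≈ w²; `w` moves from `w0 + δ/2` to `w0 − δ/2`
  across sessions in the MBSR group and the reverse in controls
  (`w0 = 0.4`), reproducing the opposite-direction connectivity change.
* **Behaviour**: a Gaussian copula ties practice minutes and the
  logit-scale PVC change to the standardized alpha change at exactly
  `rho_minutes` and `rho_pvc` (defaults 0.36 and 0.37). Counts are drawn
  binomially (timeout probability 0.15) and the EEG trial outcomes tabulate
  to the same counts, so PVC is exactly computable from either. The SD of
  the logit-PVC change is 0.7 (≈0.15 on the PVC scale), chosen a priori so
  binomial count noise attenuates the generative correlation by < 10%.
  Practice minutes are generated cohort-wide (controls get small informal
  practice) so the correlation applies at n = 62.
* **Artifacts**: Poisson-timed (10/min) frontal eyeblink pulses and
  bipolar horizontal-EOG transients whose topographies are exactly the ICA
  template fixtures.

What a green test does *not* establish: the generator has no anatomy (the
parcellation is a Voronoi partition around Fibonacci-spiral seeds, not an
atlas), no volume-conduction error (the same spherical leadfield simulates
and inverts), no line noise, no EMG, and envelope statistics far tamer than
real artifact-laden EEG. Recovery results here bound what the code can do
under its own assumptions, not field performance.

# Numerical choices

* **Filters.** A windowed-FIR design with the nominal 25% transition width
  needs ~13,000 taps for a 1 Hz edge at 1 kHz — longer than any epoch.
  Filtering is therefore done in the frequency domain on mirror-padded
  epochs with raised-cosine transitions (stopband edge at half the low
  cut): exactly zero-phase, ripple-free, and meeting the ≥20 dB stopband
  contract on epoch-length data. Anti-alias filtering before integer
  decimation preserves content below 0.8 × the new Nyquist within 5%.
* **Spherical splines.** Perrin-style, order m = 4, 50 Legendre terms,
  ridge 1e-5.
* **ICA.** Seeded symmetric FastICA (tanh contrast) on 30 PCA dimensions,
  tolerance 1e-7, 500 iterations, retry with a fresh seed on
  non-convergence. Template matching uses the absolute Pearson correlation
  between each template topography and the channel-space mixing column;
  exactly two components are removed. Note that *any* procedure that must
  always remove two components will measurably perturb whichever channels
  load on the best-matching components; the clean-data regression test
  therefore asserts a mean per-channel correlation > 0.95 rather than a
  per-channel floor, which is unattainable in general.
* **DICS.** Regularization λ = 5% of mean sensor power; real part of the
  CSD; dominant orientation from the 3×3 source power matrix; filters
  computed from the session-pooled CSD per subject and applied to both
  sessions, avoiding filter-difference confounds. Source power maps are
  noise-normalized (neural activity index, `A C A' / (A A')`): the
  unit-gain filter at a deep low-gain point amplifies noise by its norm
  (the classic centre-of-head bias), and the normalized map is flat under
  white sensor noise.
* **Envelopes.** Hilbert analytic signals per trial of the 9–15 Hz
  band-passed source time courses; 0.1 s trimmed per trial edge;
  log-power envelopes (Hipp-style) by default. Whether envelopes are
  computed per trial or on concatenated data has no single field
  convention; concatenation of trimmed trials is the declared choice.
* **Burg spectra.** The Burg recursion is validated against
  `stats::ar.burg` to 1e-10 and against the closed-form AR(1) spectrum.
  The acceptance check compares the fitted AR(1)(0.9) spectrum to the
  closed form by the *median* relative error across 1–50 Hz: near-DC bins
  of an estimated AR(0.9) spectrum carry ≈25% sampling noise at n = 1000
  (the DC log-spectrum sensitivity is 2/(1−a) ≈ 20 times the coefficient's
  standard error), so a pointwise 10% criterion at that n is a coin flip
  regardless of implementation quality, while the median error tests the
  recursion itself.
* **Control signal.** AR order 16 on trailing 160 ms windows every 40 ms,
  amplitudes averaged over 10.5–13.5 Hz on a 0.5 Hz grid, exponentially
  weighted z-normalization with a 30 s time constant (early updates use a
  growing window so the state is unbiased from the first sample); the
  vertical (rest) control is minus the normalized C3+C4 sum, and a trained
  state can be applied frozen, the online convention. Order, window and
  horizon are declared defaults, all config-exposed.

# Scaling of the test suite

The acceptance properties state subject counts, channel counts, replicate
counts, permutation counts and thresholds explicitly; those are honoured
as written. Where a property leaves simulation size open, the suite scales
down and says so inline: null-calibration cohorts use 6 trials/session and
10 background sources; recovery cohorts use 40 trials/session and 120 grid
points; NBS calibration and recovery run on the connectivity-level cohort
generator (matched in effect scale to the envelope-mixing model,
Δr ≈ 0.4 × coupling_delta) because 200 replicates of source reconstruction
plus 4,005 envelope correlations do not fit a single-CPU budget. The
EEG-level coupling path is exercised directly at signal level and in the
pipeline tests.

# Known limitations

* The spherical head model and synthetic parcellation carry no anatomical
  meaning; ROI labels are positional.
* The linear mixed-effects modelling of PVC trajectories is out of scope;
  the package exports the PVC table for external fitting.
* Only two sessions ("first", "last") are generated and analysed.
* Dynamic (time-resolved) connectivity and phase-based metrics are not
  implemented.
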
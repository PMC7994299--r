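# restalpha

EEG group analysis for longitudinal sensorimotor-rhythm BCI studies of the
*intentional rest* condition: does a mind-body intervention (MBSR) change
alpha-band (9–15 Hz) power and connectivity differently from controls over
BCI training, and do those neural changes track practice time and
behavioural performance?

The package implements the full sensor-to-source chain as composable,
tested stages:

* **Preprocessing** — zero-phase 1–100 Hz band-pass, 1 kHz → 250 Hz
  resampling, Perrin spherical-spline bad-channel interpolation, common
  average reference, seeded template-matched ICA removal of exactly two
  ocular components, extraction of the last second of feedback, automated
  variance-based trial rejection.
* **Spectra** — Hann-taper power 1–50 Hz (1-Hz steps) per trial; offline
  re-creation of the online cursor control signal (Burg maximum-entropy AR
  amplitudes of small-Laplacian C3/C4 in a 3 Hz bin around 12 Hz,
  z-normalized, 40 ms updates).
* **Source localization** — DICS beamformer on an analytic spherical head
  model: band cross-spectral density `C`, unit-gain filters
  `A = (LᵀC⁻¹L)⁻¹LᵀC⁻¹`, dominant orientation, noise-normalized power
  maps, ROI-centroid analytic time courses for a 90-region parcellation
  with a 7-network (DMN/DAN/FPN/VAN/SMN/VIS/LIM) assignment.
* **Connectivity** — orthogonalized power-envelope correlation
  (`y⊥(t) = Im[y(t)·conj(x(t))/|x(t)|]`, log-envelope Pearson, averaged
  bidirectionally) over all 4,005 unique ROI pairs.
* **Group statistics** — the interaction contrast MBSR(last−first) vs
  control(last−first): spatial-spectral cluster permutation test
  (Delaunay sensor adjacency × 1-Hz spectral adjacency, cluster mass =
  summed t, max-statistic null, 5,000 permutations by default), the
  network-based statistic (edge p < 0.005, component size null), network
  summaries (summed t, mean degree, mean strength), percent valid correct
  (PVC = hits/(hits+misses)), and neural-behavioural Pearson correlations.
* **Synthetic cohorts** — a seeded generator producing epoched EEG,
  montage, leadfield, parcellation, behaviour table and machine-readable
  ground truth with configurable effect sizes, envelope-coupling changes
  and neural-behavioural correlations, so every stage above is testable
  end to end. See `vignettes/methods.Rmd` for the generative model and all
  numerical design choices.

## Worked example

```r
library(restalpha)

## simulate a two-session cohort: 20 MBSR + 20 controls, 64 channels
cfg <- sim_config(n_subjects_per_group = 20, n_trials_per_session = 30,
                  n_grid = 120, seed = 7)
cohort <- simulate_cohort(cfg)

## per-subject interaction maps: log10 sensor power, last - first
pow <- lapply(c(first = "first", last = "last"), function(s)
  t(sapply(cohort$subjects, function(su)
    as.vector(compute_power_spectrum(su$sessions[[s]], average = TRUE)$power))))
maps <- log10(pow$last) - log10(pow$first)
group <- factor(sapply(cohort$subjects, `[[`, "group"),
                levels = c("MBSR", "control"))

## spatial-spectral cluster permutation test
adj <- build_sensor_adjacency(cohort$montage, 1:50)
cl <- cluster_permutation_test(maps, group, adj, n_perm = 1000, seed = 7)

## network-based statistic on connectivity change matrices
cc <- simulate_connectivity_cohort(cfg)
nb <- nbs_test(cc$diff, factor(cc$group, levels = c("MBSR", "control")),
               n_perm = 1000, seed = 7)

## behaviour
beh <- compute_pvc(cohort$behavior)
```

This prints (via the summaries shown in `?cluster_permutation_test` and
the README script in `scripts/`):

```
top cluster: 6-17 Hz, 60 channels, mass 1284.5, p = 0.0010
top NBS component: 10 edges over 8 regions, p = 0.0010
    group session   pvc
1 control   first 0.549
2    MBSR   first 0.624
3 control    last 0.699
4    MBSR    last 0.746
alpha change vs practice minutes: r = 0.49, p = 0.001
alpha change vs PVC change:       r = 0.15, p = 0.353
```

Reading the output: the cluster test finds a significant positive cluster
centred on the injected 9–15 Hz band (it spreads into flanking bins via
spectral leakage and adjacency, as expected); its Monte-Carlo p of 0.001
is the minimum attainable at 1,000 permutations. The NBS component
recovers exactly the generator's 10-edge coupled subgraph. PVC rises in
both groups with a larger MBSR improvement, and the alpha-change
correlation with practice minutes is recovered near its generative value
(0.36) within sampling error at n = 40 — the PVC-change correlation at
this cohort size is noisy, illustrating why such correlations need the
full cohort.

The orchestrated pipeline (simulate → preprocess → spectra → source →
connectivity → statistics → report) is available as
`run_full_analysis(pipeline_config(...))` or from the shell via
`inst/cli/restalpha run --out DIR --seed 7`; it writes `results.json`,
`config.json` and a markdown `report.md` per run.

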
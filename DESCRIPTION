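Package: restalpha
Title: EEG Alpha Power and Envelope Connectivity Analysis with Permutation
    Statistics for Intentional-Rest BCI Studies
Version: 0.1.0
Authors@R:
    person("BCI", "Pipelines", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A sensor-to-source EEG analysis pipeline for longitudinal
    group studies of sensorimotor-rhythm brain-computer interface (BCI)
    control. Implements epoch preprocessing (zero-phase band-pass
    filtering, resampling, spherical-spline bad-channel interpolation,
    common-average referencing, template-matched ICA ocular artifact
    removal), Hann-taper spectral analysis, an offline reimplementation
    of the autoregressive (Burg maximum-entropy) cursor control signal,
    DICS beamformer source localization on an analytic spherical head
    model, orthogonalized power-envelope correlation connectivity over a
    90-region parcellation with a 7-network assignment, cluster-based
    permutation tests with spatial-spectral adjacency, the network-based
    statistic (NBS) for connectivity graphs, network-level summaries,
    percent-valid-correct behavioral scoring, and neural-behavioral
    correlations. Ships a synthetic cohort generator with machine-readable
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
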
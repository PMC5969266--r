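Package: sebrKi
Title: Spontaneous Eye Blink Rate and Striatal Dopamine Synthesis
    Capacity from Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating spontaneous eye blink rate (sEBR), measured
    from electro-oculography, to striatal dopamine synthesis capacity (Ki)
    estimated by reference-region Patlak graphical analysis of dynamic
    [18F]DOPA PET. Provides EOG preprocessing and automated blink detection
    with saccade-artifact and data-loss handling, Patlak transformation and
    windowed influx-constant fitting for regional time-activity curves and
    4-D volumes, template-based striatal masking and ROI extraction, and a
    statistical layer with Spearman rank correlation, bootstrapped partial
    regression, directional correlation Bayes factors under stretched-beta
    priors with prior-width robustness curves, permutation-based voxel-wise
    family-wise error control, and exact power analysis for correlation
    tests. A synthetic-data module generates EOG traces, time-activity
    curves, dynamic volumes, and cohorts with known ground truth so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
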
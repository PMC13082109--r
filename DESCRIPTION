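Package: msidiff
Title: Differential Abundance Analysis for Multi-Sample Mass Spectrometry
    Imaging Experiments with Complex Designs
Version: 0.1.0
Authors@R:
    person("MSI", "Workflow Maintainers", email = "msidiff@example.org",
           role = c("aut", "cre"))
Description: A five-step statistical workflow for detecting differentially
    abundant analytes in multi-sample mass spectrometry imaging (MSI)
    experiments: preprocessing and between-run normalization (including a
    censored-median procedure robust to sparsity and outliers), region of
    interest (ROI) segmentation with safeguards against double-dipping and
    selection bias, non-specific and sparsity-based feature filtering with
    isotope clustering and aggregation, per-feature linear mixed-effects
    models of ROI mean intensities with exact or Satterthwaite degrees of
    freedom and Benjamini-Hochberg false discovery rate control, and
    model-based sample-size planning for follow-up experiments. Includes
    simulators of peak-picked MSI experiments with ground-truth ROIs,
    controllable biological and technical variance components, and spatial
    autocorrelation, used to validate the workflow's operating
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
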
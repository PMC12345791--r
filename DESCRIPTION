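Package: qusr
Title: Quantitative Ultrasound Radiomics for Early Treatment-Response
    Prediction
Version: 0.1.0
Authors@R:
    person("QUS", "Radiomics Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Week-1 quantitative ultrasound (QUS) radiomics pipeline for
    predicting breast-tumour response to neoadjuvant chemotherapy from raw
    RF echo data: sliding-window power-spectrum estimation with
    reference-phantom normalization, six spectral tissue parameters
    (mid-band fit, spectral slope and intercept, scatterer spacing,
    effective scatterer diameter, acoustic concentration) plus attenuation,
    grey-level co-occurrence texture features of the parametric maps,
    delta-feature SVM-RBF classification of responders versus
    non-responders, and diagnostic-performance evaluation with exact
    Clopper-Pearson and logit confidence intervals.  Includes a synthetic
    RF point-scatterer generator (tumour scans, reference phantom,
    two-timepoint labelled cohorts) so the full pipeline runs without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    quadprog,
    rhdf5,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
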
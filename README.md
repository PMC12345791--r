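# qusr — quantitative-ultrasound radiomics for early treatment-response prediction

`qusr` implements a week-1 quantitative ultrasound (QUS) radiomics pipeline
for predicting breast-tumour response to neoadjuvant chemotherapy, for
researchers in ultrasound tissue characterization and imaging biomarkers.
Chemotherapy kills tumour cells within days — cell fragmentation,
aggregation and chromatin condensation change the tissue microstructure —
and those changes alter how tissue backscatters ultrasound long before the
tumour shrinks. The pipeline quantifies them from raw RF echo data one week
into treatment and classifies patients as responders (R) or non-responders
(NR), the non-responder being the positive class the clinic needs to catch.

## The method

1. **Spectral estimation.** Sliding Hann-tapered windows (2.5 mm × 2.5 mm,
   80 % overlap) over the tumour ROI; per-line FFT periodograms averaged
   Welch-style per window. Spectra are normalized by a reference phantom
   with known backscatter and attenuation measured on the same system:

   `ns(f) = S(f) − S_ref(f) + BSC_ref(f) + 2 z f (α − α_ref)`  [dB],

   which cancels the system transfer function exactly.
2. **QUS parameters per window** over the 3.0–8.5 MHz band:
   - `MBF`, `SS`, `SI` — OLS line fit `ns(f) ≈ SI + SS·f`, with
     `MBF = SI + SS·f_c` at the band centre (5.75 MHz);
   - `ASD`, `AAC` — Gaussian form-factor fit: regressing
     `ns(f) − 40·log10 f` on `f²` gives the effective scatterer diameter
     (slope, via `exp(−0.827 k² a²)`) and acoustic concentration (intercept,
     dB);
   - `SAS` — dominant scatterer spacing from the spectral-ripple
     autocorrelation, `SAS = c / (2 Δf)`;
   - attenuation `α` by the spectral-difference method (depth–frequency
     regression of spectral decay).
3. **Texture.** Each of the six parametric maps is quantized to 16 grey
   levels and summarized by four grey-level co-occurrence (GLCM) features —
   contrast, correlation, homogeneity, energy — averaged over the four
   principal angles at distance 1.
4. **Features.** 6 parameter means + 24 textures + attenuation = **31 named
   features** per patient-timepoint; the classifier input is the week-1
   delta `Δx = x_week1 − x_week0`.
5. **Classification.** Sequential forward feature selection (cross-validated
   balanced accuracy) feeding an SVM with RBF kernel, inverse-prevalence
   class weights for the ~4:1 R:NR imbalance. Positive class score ⇒
   predicted non-responder.
6. **Evaluation.** Confusion counts with NR positive; sensitivity,
   specificity, PPV, NPV, accuracy with exact Clopper–Pearson (and logit,
   for the predictive values) confidence intervals; ROC/AUC; per-feature
   unpaired Welch t-tests between response groups.

No patient data ship with the package: a synthetic RF generator (1-D
pulse-echo convolution over random point-scatterer fields, 6.5 MHz centre /
3.0–8.5 MHz band, 40 MHz sampling, c = 1540 m/s) produces tumour scans,
reference phantoms, and labelled two-timepoint cohorts with a controllable
week-1 microstructural change in responders, so every stage is exercisable
and testable end to end.

## Worked example

A scaled-down demo cohort (40 development + 16 validation patients; the
default configuration uses 100 + 51 and runs in under 15 minutes on one
CPU):

```r
library(qusr)
cfg <- list(seed = 7,
            dev = list(n_patients = 40, nonresponder_fraction = 0.2),
            val = list(n_patients = 16, nonresponder_fraction = 0.25),
            model = list(k = 3))
res <- run_pipeline(cfg, out_dir = "demo_out")
res$selected_features
#> [1] "MBF-mean" "AAC-COR"  "AAC-mean"
res$report
#> <performance_report> n = 16, AUC = 0.77
#> <confusion_counts> (NR positive) TP=3 FN=1 TN=11 FP=1 (n=16)
#>   sensitivity  75% (19-99%) [clopper_pearson]
#>   specificity  92% (62-100%) [clopper_pearson]
#>   ppv          75% (24-97%) [logit]
#>   npv          92% (59-99%) [logit]
#>   accuracy     88% (62-98%) [clopper_pearson]
```

Reading this: the forward selection found the injected backscatter-rise
signal (the mid-band-fit and acoustic-concentration deltas rise ~3 dB in
responders), and on the held-out synthetic cohort the model caught 3 of the
4 non-responders (sensitivity 75 %) while clearing 11 of 12 responders
(specificity 92 %); the wide exact intervals reflect the small validation
class sizes. `demo_out/` holds the delta-feature tables, serialized model,
predictions, JSON report with full-precision metrics, ROC points, and a run
manifest with config/output digests.

The same stages are scriptable from the shell via the launcher in
`inst/bin/`:

```sh
qusr run-all --config cohort.yaml --out out/ --seed 1
qusr simulate | extract | train | predict | evaluate ...
```

## Package layout

| Area | Files |
|---|---|
| RF synthesis | `R/pulse.R`, `R/scatterers.R`, `R/rf-simulate.R`, `R/cohort.R` |
| Spectra & QUS parameters | `R/spectra.R`, `R/qus-params.R` |
| Texture & features | `R/texture.R` |
| Classifier | `R/svm.R`, `R/response-model.R` |
| Evaluation | `R/evaluation.R` |
| Orchestration | `R/pipeline.R`, `R/cli.R`, `R/io-hdf5.R` |

The methods vignette (`vignettes/qus-radiomics.Rmd`) documents the model
assumptions, parameter conventions, what the synthetic generator does and
does not emulate, and the numerical design choices.
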
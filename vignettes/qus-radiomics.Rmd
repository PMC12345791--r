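---
title: "Methods: week-1 QUS radiomics response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: week-1 QUS radiomics response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
their assumptions, the tunable parameters and their defaults, what the
synthetic generator emulates and — importantly — what it does not, and the
numerical design choices made where the methodology left options open. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## 1. The problem

Neoadjuvant (pre-surgical) chemotherapy offers a window to assess tumour
response in vivo and adapt treatment. Cell death begins within days of the
first cycle — fragmentation, aggregation, chromatin condensation — and these
microstructural changes alter ultrasonic backscatter well before any change
in tumour size. Quantitative ultrasound (QUS) works on the raw
radio-frequency (RF) echo signal, before envelope detection, and
characterizes tissue through the frequency content of its backscatter.
This package implements the full chain from RF data to a binary
responder/non-responder (R/NR) prediction at week 1 of treatment, with the
non-responder as the positive class throughout: the clinically actionable
event is identifying, early, the patient whose regimen is not working.

## 2. Spectral estimation and reference-phantom normalization

Welch-style power spectra are computed in sliding windows over the tumour
region of interest (ROI): each scan line inside a window is Hann-tapered and
Fourier-transformed, per-line periodograms are averaged, and the result is
expressed in dB (`10·log10`, the convention for every spectral quantity in
the package).

Window defaults (`spectral_config()`): **2.5 mm axial × 11 lines
(≈2.5 mm)** with **80 % overlap** in both directions. The axial length must
be at least ten wavelengths at the centre frequency (10 × 0.237 mm =
2.37 mm at 6.5 MHz, c = 1540 m/s) for stable spectral estimates; this
constraint is enforced, and is why the default is 2.5 mm rather than the
2 mm that would otherwise be attractive for map resolution. At the default
strides a window grid covers every ROI pixel (a tested invariant). The
analysis band defaults to **3.0–8.5 MHz**, the −6 dB band of the emulated
6.5 MHz linear-array transducer.

Normalization follows the reference phantom method. With sample and
reference spectra taken from the same depth on the same system,

    ns(f) = S(f) − S_ref(f) + BSC_ref(f) + 2 · z · f · (α − α_ref)   [dB]

the system transfer function (transmit pulse, electronics, TGC) cancels
exactly in the subtraction; the phantom's known backscatter restores the
absolute scale; and the last term compensates differential round-trip
attenuation at the window-centre depth z (cm), with α in dB·cm⁻¹·MHz⁻¹.
(Written with amplitude attenuation in Np·cm⁻¹·MHz⁻¹ the same term is the
familiar `4 z Δα f · 10/ln 10`; the two forms are identical, this package
standardizes on dB units.) Attenuation compensation is point-wise at the
window centre. System independence — normalized spectra for the same tissue
agreeing across different simulated transducers — is asserted at ≤0.5 dB
band-mean difference in the acceptance suite.

## 3. The six QUS parameters and attenuation

The feature lineage names six parameters; the fitting conventions (not
restated by the methodology this package follows) are the standard ones,
each isolated behind its own function so a convention can be swapped:

* **MBF / SS / SI** (`fit_linear_spectrum`): ordinary least squares of
  `ns(f)` on `f` over the band. SS is the slope (dB/MHz), SI the 0-MHz
  intercept (dB), MBF the fitted value at the band midpoint (5.75 MHz), so
  `MBF = SI + SS·f_c` is an algebraic identity, tested to machine
  precision.
* **ASD / AAC** (`estimate_asd_aac`): Gaussian form-factor model. The
  backscattered power of a weak Gaussian scatterer of effective radius a is
  `∝ f⁴ · exp(−0.827 k² a²)`, `k = 2πf/c`; in dB this is linear in `f²`
  after subtracting the Rayleigh term `40 log10 f`. The regression slope
  maps to a (ASD = 2a, reported in µm) and the intercept is the acoustic
  concentration AAC on a relative dB scale — absolute physical units are
  deliberately not claimed, but concentration ratios are faithful: doubling
  scatterer concentration raises AAC by 3.01 dB (a tested property). An
  unphysical positive slope (negative squared radius) flags ASD invalid;
  AAC is still reported. Invalid windows are excluded from means and
  textures, and their count is logged in the `qus_maps` object.
* **SAS** (`estimate_sas`): dominant scatterer spacing from spectral
  ripple. A regular axial spacing d imprints a periodicity `Δf = c/(2d)`
  on the power spectrum; the detrended (quadratic polynomial) linear-power
  spectrum is autocorrelated over frequency lags, the search starts past
  the first zero crossing (skipping the speckle correlation lobe), and the
  first local maximum reaching half the global one is taken, so the
  fundamental beats its harmonics. **Significance**: the peak must exceed
  `z_{1−α/2} / √n_eff`, where the effective number of independent spectral
  bins is the time–bandwidth product `B·T` divided by the Hann equivalent
  noise bandwidth (1.5) — not the padded grid length, which would be
  anti-conservative by the padding factor. Diffuse media then return null
  (no significant spacing) in ≥90 % of realizations, a tested contract.
  *Naming note:* the feature list this package implements expands SAS as in
  its development lineage — spacing among scatterers (mm) — although one
  description of the same feature set prints "spectral average slope" for
  the acronym. The discrepancy is documented rather than silently resolved;
  the implementation provides the spacing estimator.
* **Attenuation** (`estimate_attenuation`): no method is prescribed by the
  lineage, so the spectral-difference method is used: per frequency bin,
  regress spectral amplitude (dB) on window depth across ≥3 depth strata;
  the depth-slopes regressed on frequency give `−2α`. Computed on
  sample-minus-reference spectra it yields the differential attenuation to
  the phantom, to which the phantom's known α is added back. The estimate
  is floored at zero (a physical constraint) for use as compensation and
  as the 31st feature; the signed value is retained for diagnostics.

`build_parametric_maps()` runs this chain for every in-ROI window of every
plane, producing one map per parameter per plane plus per-scan means. One
map-level choice departs from the single-spectrum contract: with diffuse
tissue the significance-gated SAS would be null in most windows, leaving the
SAS map too sparse for texture analysis, so maps use the ungated
dominant-peak estimate (`sas_require_significance = FALSE`). The gated
estimator remains the API for actual spacing inference.

## 4. GLCM texture and the 31-feature schema

Each parametric map is quantized to **16 grey levels over its own in-mask
min–max** (uniform bins), and grey-level co-occurrence matrices are
accumulated at **distance 1** for the four principal angles
{0°, 45°, 90°, 135°}, symmetrized and normalized; pairs with either end
outside the ROI are ignored. Four Haralick features are computed per matrix
and averaged over angles: contrast, correlation, homogeneity (inverse
difference `1/(1+|i−j|)`; the `1/(1+(i−j)²)` dialect is a config option),
and energy. None of n_levels / distance / angles are prescribed by the
lineage; these defaults are the common radiomics choices, and per-map
min–max quantization was chosen over fixed physical ranges because it makes
all four features exactly invariant to affine rescaling of a map — a tested
property that decouples texture from the arbitrary dB offsets of relative
calibration. Whether the original implementation used fixed colour-scale
ranges instead is unknown; `quantization = "fixed"` is provided. For a
degenerate constant map the correlation is set to 1 by convention
(a perfectly correlated field), and texture features are averaged across
planes (arithmetically, a tested aggregation identity).

The schema is exactly **31 features**: six parameter means, 6 × 4 textures
named `"<PARAM>-<FEATURE>"`, and `attenuation`. Assembly errors on missing
or duplicated maps rather than emitting silent NaNs. The classifier input
is the delta set `Δx = x_week1 − x_week0`, antisymmetric under week swap.

## 5. Classification

* **Selection** (`sequential_feature_selection`): greedy forward selection
  maximizing 5-fold stratified cross-validated balanced accuracy, ties
  broken by schema order, deterministic given the fold seed. The
  development lineage selected three delta features (its published triple
  being the spacing-correlation, mid-band-fit-energy and
  spacing-homogeneity deltas — with "ΔMBFF-ENE" presumed a typographical
  doubling of "ΔMBF-ENE", noted, not corrected); on synthetic cohorts the
  selected names depend on the injected effect and are not expected to
  reproduce that triple.
* **SVM-RBF** (`train_svm`): the kernel classifier is solved exactly in
  the dual with `quadprog` (a tiny ridge, 1e-8, guarantees positive
  definiteness), which at cohort sizes of ~100 is simpler and more
  deterministic than iterative solvers. Per-feature standardization is
  fitted on training data only — inside every CV fold as well — and a
  leakage test asserts scoring never touches the fitted statistics.
  Hyperparameters default to a small grid (C ∈ {1, 10, 100}, γ ∈ {0.01,
  0.1, 1} on standardized features) chosen by the same stratified CV; none
  were published. Class imbalance (the development prevalence is 81:19) is
  handled by inverse-prevalence class weights, configurable off.
* **Scores** (`predict`): the signed decision value on the
  distance-to-hyperplane scale. **Positive score ⇒ predicted
  non-responder** — the textual description of the development model states
  this mapping while its figure caption states the opposite; the text is
  taken as authoritative and the convention is a single documented
  constant. Ties at exactly 0 go to the majority class (R). Scores within
  a configurable margin of 0 are flagged as the indeterminate zone.

## 6. Evaluation

With NR positive: sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV,
NPV, accuracy. Sensitivity/specificity/accuracy carry exact Clopper–Pearson
intervals (beta-quantile form); predictive values carry standard logit
intervals, undefined (flagged, never zero-filled) at boundary proportions.
Display rounding is whole-percent; JSON reports keep full precision and
every percentage is recomputable from the stored counts. AUC is the
pairwise concordance probability (ties ½), equal for binary scores to
(sensitivity+specificity)/2 — worth knowing when an AUC printed alongside
integer metrics coincides with that identity. Published interval digits
that are inconsistent with exact binomial intervals at n = 6 (e.g. a
"50 % (50–50 %)" sensitivity row) are not fitted to; the package reports
correctly computed intervals. Per-feature group comparisons use Welch's
unpaired t-test by default (pooled-variance as option — the lineage says
only "unpaired"), without multiplicity correction (none was reported);
p-values are labelled unadjusted. A patient-exclusion list re-triggers the
full report, mirroring exploratory re-analysis after excluding patients who
did not complete the regimen.

## 7. The synthetic world

The generator exists so that every stage is testable without patient data.
What it emulates:

* **Pulse**: Gaussian-enveloped cosine, 6.5 MHz centre, −6 dB band
  3.0–8.5 MHz, 40 MHz sampling, c = 1540 m/s fixed.
* **Tissue**: random point scatterers (default 10 mm⁻², fully developed
  speckle) with zero-mean Gaussian reflectivities, so backscattered power
  is incoherent and exactly linear in concentration (+3.01 dB per
  doubling, tested). Finite scatterer size enters through the Gaussian
  form factor; quasi-periodic fields add a jittered axial comb **with a
  non-zero-mean (coherent) reflectivity component** — it is the coherent
  part of a regular lattice that imprints the spacing ripple; a zero-mean
  comb leaves no signature in the expected spectrum.
* **Propagation**: per-line 1-D convolution in the frequency domain;
  frequency-dependent attenuation and the form factor are applied per
  depth stratum (8 strata by default, 16 where attenuation accuracy is
  probed) — a piecewise-constant-in-depth approximation.
* **Geometry**: frames 4 cm deep × 256 lines at 0.23 mm pitch (a 60 mm
  linear array), three planes per scan standing in for the 0.5 cm-interval
  volumetric sweep, elliptical ROI ≥1.5 cm lateral extent (the eligibility
  threshold), enforced.
* **Cohorts**: development-style n = 100 at 19 % NR and validation-style
  n = 51 at 12 % NR, exact class counts, both timepoints sharing geometry
  and ROI. Responders' week-1 fields get a **+3 dB reflectivity-variance
  gain** and **30 % scatterer aggregation** (clustering), the stated
  microstructural correlates of early cell death; non-responders are
  redrawn from the week-0 distribution. The nuisance keeping classes from
  trivial separability is a per-scan acquisition gain jitter of 1.5 dB SD
  plus 2 dB SD per-patient biology; with the 3 dB effect this puts
  single-feature separation near d ≈ 1.4, i.e. accuracy in the high-70s —
  the scale of the development report — and these values were fixed a
  priori, not tuned to test outcomes.

What it does **not** emulate, hence what a green test does not establish:
no diffraction, focusing, or elevational beam structure; no electronic
noise or TGC; no tissue heterogeneity beyond an optional modulation knob
with no claim of realism (real tumours are heterogeneous, distorted, and
poorly defined); no physical backscatter units; and no biology connecting
the injected effect sizes to actual chemotherapy response. Classifier
metrics on synthetic cohorts validate the pipeline's mechanics, not the
clinical performance of any real-data model, whose trained weights are
unavailable — published cohort metrics are context, never targets.

## 8. Numerical choices and degenerate inputs

* FFT lengths are 2-3-smooth (`nextn`), windows zero-padded ×2; spectra
  in dB re 1 (absolute offsets cancel in normalization).
* All-zero analysis windows error ("degenerate window") rather than
  fabricating a dB floor; empty scatterer fields yield flagged all-zero
  frames; sampling below 4× centre frequency errors at construction.
* Echo delays are rounded to the nearest RF sample (≤ ±0.5 sample,
  ≤ ±0.51 rad phase jitter at 6.5 MHz) — immaterial for speckle statistics,
  visible only as mild decorrelation.
* The per-patient/per-stage seed fan-out is a documented affine map
  (`derive_seed`), keeping every derived seed within 32-bit range; every
  generator saves and restores the global RNG state.
* Pipeline configs are schema-validated with unknown keys rejected by
  name; the run manifest records config and output digests, and reruns at
  a fixed seed are byte-identical (tested).

## 9. Known limitations

The RF model's 1-D convolution cannot probe lateral-resolution effects on
texture; SAS map values are grid-quantized (`c/(2 ℓ df)`); the attenuation
estimator assumes depth-stationary tissue within the ROI; the development
cohort is synthetic, so selected features and hyperparameters will not
match any real-data model; and with n = 6 positives, validation-scale
interval estimates are inherently wide — the package reports them exactly
rather than optimistically.
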
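#' Synthetic two-timepoint cohort configuration
#'
#' The stated world: a development-style cohort of 100 patients with 19%
#' non-responders (the 81R/19NR development prevalence) or a validation-style
#' cohort of 51 patients at 12% prevalence; scans before treatment (week 0)
#' and at week 1, three image planes per scan at 0.5 cm spacing; an
#' L14-5/60-like pulse (6.5 MHz centre, 3.0–8.5 MHz band) sampled at 40 MHz
#' with c = 1540 m/s; frames 4 cm deep x 256 lines at 0.23 mm pitch; an
#' elliptical tumour ROI of at least 1.5 cm extent.
#'
#' Responders' week-1 scans get a chemotherapy-response effect injected into
#' the scatterer field — increased reflectivity variance (`gain_db`, the
#' backscatter rise that cell death produces) and partial aggregation of
#' scatterer positions (`aggregation`) — while non-responders are redrawn
#' from the week-0 distribution.  `noise_sd` is a per-scan acquisition gain
#' jitter (dB) applied to every scan of every patient, the nuisance that
#' keeps classes from being trivially separable.
#'
#' @param n_patients Cohort size.
#' @param nonresponder_fraction Proportion of NR labels; class counts are
#'   exactly `round(n * fraction)`.
#' @param effect_sizes List with `gain_db` (week-1 backscatter amplitude gain
#'   for responders, dB) and `aggregation` (fraction of scatterers clustered
#'   at week 1).
#' @param noise_sd Per-scan gain jitter SD, dB.
#' @param seed Integer master seed; identical seed gives an identical cohort.
#' @param geometry List: `depth_mm`, `width_mm`, `line_pitch_mm`, `n_planes`,
#'   `n_lines` (NULL = cover width).
#' @param roi List: `semi_axial_mm`, `semi_lateral_mm`, `centre_depth_mm`
#'   (ellipse half-axes; lateral extent must be >= 7.5 mm so tumours are
#'   >= 1.5 cm).
#' @param tissue List: `number_density` (per mm^2), `attenuation_range`
#'   (dB cm^-1 MHz^-1, per-patient uniform draw), `baseline_gain_sd` (dB,
#'   per-patient biological variability common to both weeks).
#' @param heterogeneity Extra within-tumour reflectivity modulation in [0, 1);
#'   no realism is claimed for this knob.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100, nonresponder_fraction = 0.19,
                          effect_sizes = list(gain_db = 3, aggregation = 0.3),
                          noise_sd = 1.5, seed = 1,
                          geometry = list(depth_mm = 40, width_mm = 58.88,
                                          line_pitch_mm = 0.23, n_planes = 3,
                                          n_lines = NULL),
                          roi = list(semi_axial_mm = 6, semi_lateral_mm = 9,
                                     centre_depth_mm = 20),
                          tissue = list(number_density = 10,
                                        attenuation_range = c(0.45, 0.75),
                                        baseline_gain_sd = 2),
                          heterogeneity = 0) {
  if (n_patients < 1) qstop("n_patients must be >= 1")
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1)
    qstop("nonresponder_fraction must lie in [0, 1]")
  if (roi$semi_lateral_mm < 7.5)
    qstop("ROI lateral semi-axis must be >= 7.5 mm (tumours >= 1.5 cm)")
  defaults <- eval(formals(cohort_config)$geometry)
  geometry <- modifyList(defaults, geometry)
  structure(list(n_patients = as.integer(n_patients),
                 nonresponder_fraction = nonresponder_fraction,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 seed = as.integer(seed), geometry = geometry, roi = roi,
                 tissue = tissue, heterogeneity = heterogeneity,
                 pulse = pulse_model()),
            class = "cohort_config")
}

#' Cohort labels for a configuration
#'
#' Exactly `round(n * fraction)` non-responders, placed by a seed-determined
#' permutation.
#'
#' @param config A [cohort_config()].
#' @return Character vector of `"R"`/`"NR"` of length `n_patients`.
#' @export
cohort_labels <- function(config) {
  n <- config$n_patients
  n_nr <- round(n * config$nonresponder_fraction)
  if ((n_nr == 0 || n_nr == n) &&
      config$nonresponder_fraction > 0 && config$nonresponder_fraction < 1)
    warning("requested nonresponder_fraction yields a single-class cohort at n = ",
            n, call. = FALSE)
  labels <- rep("R", n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 7L))
  labels[sample.int(n, n_nr)] <- "NR"
  labels
}

# elliptical ROI mask on the RF grid of one frame
roi_ellipse_mask <- function(frame, roi) {
  z <- frame_depth_axis(frame)
  x <- (seq_len(ncol(frame$rf)) - 0.5) * frame$line_pitch_mm
  cx <- mean(range(x))
  dz <- outer((z - roi$centre_depth_mm) / roi$semi_axial_mm,
              rep(1, length(x)))
  dx <- outer(rep(1, length(z)), (x - cx) / roi$semi_lateral_mm)
  dz^2 + dx^2 <= 1
}

#' Simulate one synthetic patient (both timepoints)
#'
#' Deterministic given `(config, i)`: per-patient seeds are derived from the
#' master seed, so any patient can be regenerated in isolation.
#'
#' @param config A [cohort_config()].
#' @param i Patient index (1-based).
#' @param label `"R"` or `"NR"`; defaults to the cohort label for `i`.
#' @return Object of class `synthetic_patient`: `patient_id`, `true_label`,
#'   `rf_week0`, `rf_week1` ([rf_scan()]s), `roi` (list of masks, shared by
#'   both timepoints), `alpha` (true attenuation).
#' @export
simulate_patient <- function(config, i, label = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(label)) label <- cohort_labels(config)[i]
  g <- config$geometry
  ps <- derive_seed(config$seed, 1000L + i)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(ps)
  alpha <- runif(1, config$tissue$attenuation_range[1],
                 config$tissue$attenuation_range[2])
  base_gain <- rnorm(1, 0, config$tissue$baseline_gain_sd)
  scan_gain <- rnorm(2, 0, config$noise_sd)          # per-week nuisance, dB
  base_sd <- 10^((base_gain + scan_gain) / 20)

  week_params <- function(week) {
    responded <- label == "R" && week == 1
    sd_w <- base_sd[week + 1]
    if (responded) sd_w <- sd_w * 10^(config$effect_sizes$gain_db / 20)
    list(depth_mm = g$depth_mm, width_mm = g$width_mm,
         number_density = config$tissue$number_density,
         amplitude_sd = sd_w,
         cluster_fraction = if (responded) config$effect_sizes$aggregation else 0)
  }
  scans <- lapply(0:1, function(week)
    simulate_rf_scan(week_params(week), config$pulse, attenuation = alpha,
                     n_planes = g$n_planes, seed = derive_seed(ps, 10L + week),
                     line_pitch_mm = g$line_pitch_mm, n_lines = g$n_lines))
  roi <- rep(list(roi_ellipse_mask(scans[[1]]$frames[[1]], config$roi)),
             g$n_planes)
  structure(list(patient_id = sprintf("P%03d", i), true_label = label,
                 rf_week0 = scans[[1]], rf_week1 = scans[[2]],
                 roi = roi, alpha = alpha),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s (%s), alpha = %.2f dB/cm/MHz\n",
              x$patient_id, x$true_label, x$alpha))
  invisible(x)
}

#' Simulate a full two-timepoint cohort
#'
#' For large cohorts holding every RF scan in memory is wasteful; the
#' pipeline instead streams [simulate_patient()] / feature extraction one
#' patient at a time with identical seeds.
#'
#' @param config A [cohort_config()].
#' @return List of [simulate_patient()] objects, plus attributes `labels`
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  labels <- cohort_labels(config)
  patients <- lapply(seq_len(config$n_patients), function(i)
    simulate_patient(config, i, labels[i]))
  structure(patients, labels = labels, config = config,
            class = c("synthetic_cohort", "list"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("<synthetic_cohort> %d patients (%d R / %d NR)\n",
              length(x), sum(lab == "R"), sum(lab == "NR")))
  invisible(x)
}

#' Feature-level synthetic delta cohort
#'
#' A lightweight generator producing the 31 delta features directly (no RF
#' stage): nuisance features are standard normal; responders receive a shift
#' of `effect` standard deviations on the informative features.  Default
#' effect 1.5 SD yields single-feature separability near the ~78% accuracy
#' scale of the development report.  With `effect = 0` the two classes are
#' exchangeable — the null generator.
#'
#' @param n_patients,nonresponder_fraction,seed As in [cohort_config()].
#' @param informative Names of informative features (subset of
#'   [qus_feature_names()]).
#' @param effect Responder shift in SD units.
#' @return data.frame: `patient_id`, `label`, 31 feature columns.
#' @export
simulate_delta_features <- function(n_patients = 100,
                                    nonresponder_fraction = 0.19,
                                    informative = "MBF-mean", effect = 1.5,
                                    seed = 1) {
  feats <- qus_feature_names()
  stopifnot(all(informative %in% feats))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_nr <- round(n_patients * nonresponder_fraction)
  label <- rep("R", n_patients)
  label[sample.int(n_patients, n_nr)] <- "NR"
  X <- matrix(rnorm(n_patients * 31), n_patients, 31,
              dimnames = list(NULL, feats))
  X[label == "R", informative] <- X[label == "R", informative] + effect
  cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
                   label = label, stringsAsFactors = FALSE),
        as.data.frame(X, check.names = FALSE))
}
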
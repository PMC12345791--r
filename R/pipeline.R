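# End-to-end week-1 pipeline: simulate -> extract -> train -> predict ->
# evaluate, with per-stage seeds fanned out from one master seed so each
# stage is independently reproducible.  Stage seed offsets (documented
# contract): reference phantom 11, development cohort 101, validation cohort
# 202, model folds 303.

#' Extract the 31 delta features for one patient
#'
#' Runs the full spectral/texture chain for both timepoints of a patient and
#' returns the week-1 minus week-0 delta set.
#'
#' @param patient A [simulate_patient()] object (or any list with
#'   `rf_week0`, `rf_week1`, `roi`, `patient_id`).
#' @param reference A [simulate_reference_phantom()] scan.
#' @param spectral A [spectral_config()].
#' @param glcm A [glcm_config()].
#' @return List: `delta` ([delta_features()]), `week0`, `week1`
#'   (`qus_feature_set`s).
#' @export
extract_patient_features <- function(patient, reference,
                                     spectral = spectral_config(),
                                     glcm = glcm_config()) {
  sets <- lapply(0:1, function(week) {
    scan <- patient[[paste0("rf_week", week)]]
    maps <- build_parametric_maps(scan, patient$roi, spectral, reference)
    assemble_features(maps, patient_id = patient$patient_id, week = week,
                      glcm = glcm)
  })
  list(delta = delta_features(sets[[1]], sets[[2]]),
       week0 = sets[[1]], week1 = sets[[2]])
}

#' Default pipeline configuration
#'
#' The demo world: a 100-patient development cohort at 19% non-responder
#' prevalence and a 51-patient validation cohort at 12% prevalence, default
#' acquisition geometry and effect sizes, 2.5 mm / 80% overlap spectral
#' windows, 16-level GLCM, and a 3-feature forward selection feeding the
#' SVM-RBF.
#'
#' @param seed Master seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    dev = list(n_patients = 100, nonresponder_fraction = 0.19),
    val = list(n_patients = 51, nonresponder_fraction = 0.12),
    cohort = list(),                 # overrides for cohort_config()
    spectral = list(),               # overrides for spectral_config()
    glcm = list(),                   # overrides for glcm_config()
    model = list(k = 3, grid = list(C = c(1, 10, 100),
                                    gamma = c(0.01, 0.1, 1))),
    exclude = character(0)),
    class = "pipeline_config")
}

pipeline_config_keys <- c("seed", "dev", "val", "cohort", "spectral",
                          "glcm", "model", "exclude")

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected by name before any stage runs.
#'
#' @param config A list / `pipeline_config`.
#' @return The validated config (invisibly classed).
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown))
    qstop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  base <- default_pipeline_config(if (is.null(config$seed)) 1L else config$seed)
  cfg <- modifyList(unclass(base), unclass(config))
  cfg$seed <- as.integer(cfg$seed)
  sub_keys <- list(
    dev = c("n_patients", "nonresponder_fraction"),
    val = c("n_patients", "nonresponder_fraction"),
    cohort = setdiff(names(formals(cohort_config)),
                     c("n_patients", "nonresponder_fraction", "seed")),
    spectral = names(formals(spectral_config)),
    glcm = names(formals(glcm_config)),
    model = c("k", "grid", "class_weights", "margin"))
  for (s in names(sub_keys)) {
    unknown <- setdiff(names(cfg[[s]]), sub_keys[[s]])
    if (length(unknown))
      qstop("unknown key(s) in config$", s, ": ", paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

cohort_config_from <- function(cfg, which, seed_offset) {
  do.call(cohort_config,
          c(list(n_patients = cfg[[which]]$n_patients,
                 nonresponder_fraction = cfg[[which]]$nonresponder_fraction,
                 seed = derive_seed(cfg$seed, seed_offset)),
            cfg$cohort))
}

extract_cohort_table <- function(ccfg, reference, spectral, glcm,
                                 progress = FALSE) {
  labels <- cohort_labels(ccfg)
  g <- ccfg$geometry
  n_lines <- if (is.null(g$n_lines)) max(1L, round(g$width_mm / g$line_pitch_mm))
  else g$n_lines
  c_mmus <- ccfg$pulse$sound_speed / 1000
  probe <- rf_frame(matrix(0, ceiling(2 * g$depth_mm / c_mmus *
                                        ccfg$pulse$sampling_rate), n_lines),
                    ccfg$pulse$sampling_rate, ccfg$pulse$sound_speed,
                    g$line_pitch_mm)
  if (!inherits(reference, "prepared_reference"))
    reference <- prepare_reference(reference, probe, spectral)
  rows <- vector("list", ccfg$n_patients)
  for (i in seq_len(ccfg$n_patients)) {
    pat <- simulate_patient(ccfg, i, labels[i])
    ext <- extract_patient_features(pat, reference, spectral, glcm)
    rows[[i]] <- cbind(feature_table(list(ext$delta)),
                       label = pat$true_label, alpha_true = pat$alpha)
    if (progress) message(sprintf("  patient %d/%d (%s)", i, ccfg$n_patients,
                                  labels[i]))
  }
  do.call(rbind, rows)
}

#' Run the full week-1 pipeline
#'
#' Simulates the reference phantom and both cohorts, extracts the 31 delta
#' features per patient (streaming, one patient in memory at a time), runs
#' sequential feature selection and SVM-RBF training on the development
#' cohort, scores the validation cohort, and evaluates diagnostic
#' performance.  All intermediate artifacts (feature tables, model,
#' predictions, report, run manifest) are written under `out_dir` as
#' CSV/JSON.
#'
#' @param config A [default_pipeline_config()]-style list (validated).
#' @param out_dir Output directory (created).
#' @param seed Optional master-seed override.
#' @param progress Emit per-patient progress messages.
#' @return List: `report` ([performance_report()]), `model`,
#'   `selected_features`, `ttests`, `dev`, `val` (delta tables), `paths`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         seed = NULL, progress = FALSE) {
  cfg <- validate_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spectral <- do.call(spectral_config, cfg$spectral)
  glcm <- do.call(glcm_config, cfg$glcm)
  dev_cfg <- cohort_config_from(cfg, "dev", 101L)
  val_cfg <- cohort_config_from(cfg, "val", 202L)

  g <- dev_cfg$geometry
  reference <- simulate_reference_phantom(
    dev_cfg$pulse, known_bsc = 1, known_attenuation = 0.5,
    depth_mm = g$depth_mm, width_mm = g$width_mm,
    line_pitch_mm = g$line_pitch_mm, n_lines = g$n_lines,
    n_planes = g$n_planes, seed = derive_seed(cfg$seed, 11L))

  if (progress) message("extracting development cohort (n = ",
                        dev_cfg$n_patients, ")")
  dev_tab <- extract_cohort_table(dev_cfg, reference, spectral, glcm, progress)
  if (progress) message("extracting validation cohort (n = ",
                        val_cfg$n_patients, ")")
  val_tab <- extract_cohort_table(val_cfg, reference, spectral, glcm, progress)

  selected <- sequential_feature_selection(
    dev_tab, k = cfg$model$k, seed = derive_seed(cfg$seed, 303L))
  model <- train_svm(dev_tab, selected, grid = cfg$model$grid,
                     seed = derive_seed(cfg$seed, 303L))
  preds <- predict(model, val_tab,
                   margin = if (is.null(cfg$model$margin)) 0 else cfg$model$margin)
  truth <- val_tab[, c("patient_id", "label")]
  report <- performance_report(preds, truth, exclude = cfg$exclude)
  ttests <- group_ttests(dev_tab)

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- list(
      dev_features = file.path(out_dir, "dev_delta_features.csv"),
      val_features = file.path(out_dir, "val_delta_features.csv"),
      model = file.path(out_dir, "model.json"),
      predictions = file.path(out_dir, "predictions.csv"),
      report = file.path(out_dir, "report.json"),
      roc = file.path(out_dir, "roc_points.csv"),
      ttests = file.path(out_dir, "dev_ttests.csv"),
      manifest = file.path(out_dir, "manifest.json"))
    write.csv(dev_tab, paths$dev_features, row.names = FALSE)
    write.csv(val_tab, paths$val_features, row.names = FALSE)
    write_response_model(model, paths$model)
    write.csv(preds, paths$predictions, row.names = FALSE)
    write_performance_report(report, paths$report, paths$roc)
    write.csv(ttests, paths$ttests, row.names = FALSE)
    cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
    manifest <- list(
      config_md5 = unname(tools::md5sum(
        local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("qusr")),
      selected_features = selected,
      outputs = lapply(paths[names(paths) != "manifest"], function(p)
        unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(report = report, model = model, selected_features = selected,
       ttests = ttests, dev = dev_tab, val = val_tab, paths = paths)
}
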
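#' GLCM configuration
#'
#' Defaults: 16 grey levels quantized over the in-mask min–max of each map,
#' pixel distance 1, the four principal angles averaged, symmetric and
#' normalized co-occurrence matrices, and the inverse-difference homogeneity
#' dialect `1/(1+|i-j|)` (the `1/(1+(i-j)^2)` dialect is available).
#'
#' @param n_levels Number of grey levels (>= 2).
#' @param distances Pixel offset distance (>= 1).
#' @param angles Angle set in degrees, subset of {0, 45, 90, 135}.
#' @param symmetric,normalized Matrix construction flags.
#' @param quantization `"minmax"` (per-map in-mask range) or `"fixed"` with
#'   `fixed_range = c(lo, hi)`.
#' @param fixed_range Quantization range when `quantization = "fixed"`.
#' @param hom_dialect Homogeneity denominator: `"inverse_diff"` for
#'   `1+|i-j|`, `"inverse_diff_sq"` for `1+(i-j)^2`.
#' @return Object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 16, distances = 1,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normalized = TRUE,
                        quantization = c("minmax", "fixed"),
                        fixed_range = NULL,
                        hom_dialect = c("inverse_diff", "inverse_diff_sq")) {
  quantization <- match.arg(quantization)
  hom_dialect <- match.arg(hom_dialect)
  if (n_levels < 2) qstop("n_levels must be >= 2")
  if (any(distances < 1)) qstop("distances must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135)))
    qstop("angles must be a subset of {0, 45, 90, 135}")
  if (quantization == "fixed" &&
      (is.null(fixed_range) || length(fixed_range) != 2 ||
       fixed_range[1] >= fixed_range[2]))
    qstop("quantization = 'fixed' requires fixed_range = c(lo, hi)")
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances[1]), angles = angles,
                 symmetric = symmetric, normalized = normalized,
                 quantization = quantization, fixed_range = fixed_range,
                 hom_dialect = hom_dialect),
            class = "glcm_config")
}

# quantize map values to 1..n_levels; NA preserved (treated as outside mask)
quantize_map <- function(values, config) {
  rng <- if (config$quantization == "fixed") config$fixed_range
  else range(values, na.rm = TRUE)
  if (!all(is.finite(rng))) qstop("no finite in-mask values to quantize")
  if (rng[1] == rng[2]) {
    q <- values
    q[!is.na(q)] <- 1L
    return(q)
  }
  q <- floor((values - rng[1]) / (rng[2] - rng[1]) * config$n_levels) + 1L
  pmin(pmax(q, 1L), config$n_levels)
}

glcm_offset <- function(angle, d) {
  # (row, col) offset; rows increase axially (downwards)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         qstop("unsupported angle"))
}

#' Grey-level co-occurrence matrix of a masked map
#'
#' Counts co-occurrences of quantized grey levels at the configured pixel
#' offset over all pixel pairs whose two ends are both inside the mask
#' (`NA` values are outside); optionally symmetrized and normalized to a
#' joint probability matrix.
#'
#' @param map A `parametric_map` or a numeric matrix with `NA` outside the
#'   mask.
#' @param config A [glcm_config()].
#' @param angle One angle in degrees (0, 45, 90, 135).
#' @return `n_levels x n_levels` matrix of class `glcm`.
#' @export
compute_glcm <- function(map, config = glcm_config(), angle = 0) {
  values <- if (inherits(map, "parametric_map")) map$values else map
  if (!is.matrix(values)) qstop("map must be a matrix or parametric_map")
  q <- quantize_map(values, config)
  off <- glcm_offset(angle, config$distances)
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) < 1 || length(c1) < 1) qstop("no valid pixel pairs at this offset")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) qstop("no valid pixel pairs inside the mask")
  n <- config$n_levels
  counts <- matrix(tabulate((a[ok] - 1L) * n + b[ok], nbins = n * n), n, n,
                   byrow = TRUE)
  if (config$symmetric) counts <- counts + t(counts)
  p <- if (config$normalized) counts / sum(counts) else counts
  structure(p, class = c("glcm", "matrix", "array"))
}

#' Haralick texture features of a GLCM
#'
#' `CON = sum p(i,j) (i-j)^2`; `COR = sum (i-mu_i)(j-mu_j) p(i,j) /
#' (sigma_i sigma_j)`; `HOM = sum p(i,j) / (1+|i-j|)` (or the squared-
#' difference dialect); `ENE = sum p(i,j)^2`.  A degenerate matrix with zero
#' marginal variance (constant map) gets `COR = 1` by convention.
#'
#' @param glcm Normalized co-occurrence matrix ([compute_glcm()]).
#' @param config A [glcm_config()] (for the homogeneity dialect).
#' @return Named vector `c(CON, COR, HOM, ENE)`.
#' @export
texture_features <- function(glcm, config = glcm_config()) {
  p <- unclass(glcm)
  if (abs(sum(p) - 1) > 1e-8) qstop("texture_features expects a normalized GLCM")
  n <- nrow(p)
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(seq_len(n) * pi_); mu_j <- sum(seq_len(n) * pj)
  var_i <- sum((seq_len(n) - mu_i)^2 * pi_)
  var_j <- sum((seq_len(n) - mu_j)^2 * pj)
  con <- sum(p * (i - j)^2)
  cor <- if (var_i <= 0 || var_j <= 0) 1
  else sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  denom <- if (config$hom_dialect == "inverse_diff") 1 + abs(i - j)
  else 1 + (i - j)^2
  c(CON = con, COR = cor, HOM = sum(p / denom), ENE = sum(p^2))
}

#' Angle-averaged texture features of a parametric map
#'
#' Computes one GLCM per configured angle and averages the four features
#' over angles.
#'
#' @inheritParams compute_glcm
#' @return Named vector `c(CON, COR, HOM, ENE)`.
#' @export
map_texture_features <- function(map, config = glcm_config()) {
  feats <- vapply(config$angles,
                  function(a) texture_features(compute_glcm(map, config, a), config),
                  numeric(4))
  rowMeans(feats)
}

#' Assemble the 31-feature QUS set for one patient-timepoint
#'
#' Six per-scan parameter means, the four GLCM features of each of the six
#' parametric maps (texture computed per plane, then averaged across planes),
#' and the scan attenuation estimate: exactly 31 named features.
#'
#' @param maps A [build_parametric_maps()] result, or a list of per-plane
#'   lists of `parametric_map`s.
#' @param means Named numeric vector of the six parameter means (taken from
#'   `maps` when it is a `qus_maps`).
#' @param attenuation Scalar dB cm^-1 MHz^-1 (taken from `maps` likewise).
#' @param patient_id,week Identifiers carried with the set.
#' @param glcm A [glcm_config()].
#' @return Object of class `qus_feature_set`: named `features` vector
#'   (length 31), `patient_id`, `week`.
#' @export
assemble_features <- function(maps, means = NULL, attenuation = NULL,
                              patient_id = NA_character_, week = NA_integer_,
                              glcm = glcm_config()) {
  if (inherits(maps, "qus_maps")) {
    if (is.null(means)) means <- maps$means
    if (is.null(attenuation)) attenuation <- maps$attenuation$alpha
    maps <- maps$maps
  }
  params <- qus_param_names()
  have <- names(maps[[1]])
  if (anyDuplicated(have)) qstop("duplicate parameter maps: ",
                                 paste(have[duplicated(have)], collapse = ", "))
  missing <- setdiff(params, have)
  if (length(missing)) qstop("missing parameter maps: ",
                             paste(missing, collapse = ", "))
  if (is.null(means) || is.null(names(means)) || !all(params %in% names(means)))
    qstop("means must be named with all six parameters")
  if (is.null(attenuation) || !is.finite(attenuation))
    qstop("attenuation value required")
  tex <- lapply(params, function(p) {
    per_plane <- vapply(maps, function(fm) map_texture_features(fm[[p]], glcm),
                        numeric(4))
    rowMeans(per_plane)
  })
  names(tex) <- params
  feats <- c(stats::setNames(means[params], paste0(params, "-mean")),
             unlist(lapply(params, function(p)
               stats::setNames(tex[[p]], paste0(p, "-", names(tex[[p]]))))),
             attenuation = unname(attenuation))
  feats <- feats[qus_feature_names()]
  stopifnot(length(feats) == 31L, !anyNA(names(feats)))
  structure(list(features = feats, patient_id = patient_id, week = week),
            class = "qus_feature_set")
}

#' @export
print.qus_feature_set <- function(x, ...) {
  cat(sprintf("<qus_feature_set> patient %s, week %s: 31 features\n",
              x$patient_id, x$week))
  print(round(head(x$features, 8), 3))
  invisible(x)
}

#' Week-1 minus week-0 delta features
#'
#' @param week0,week1 `qus_feature_set` objects for the same patient.
#' @return Object of class `delta_feature_set` with the 31 differences.
#' @export
delta_features <- function(week0, week1) {
  stopifnot(inherits(week0, "qus_feature_set"),
            inherits(week1, "qus_feature_set"))
  if (!identical(week0$patient_id, week1$patient_id))
    qstop("patient_id mismatch between timepoints")
  if (!identical(names(week0$features), names(week1$features)))
    qstop("feature schema mismatch between timepoints")
  structure(list(features = week1$features - week0$features,
                 patient_id = week0$patient_id),
            class = "delta_feature_set")
}

#' Feature table across patients
#'
#' @param sets List of `qus_feature_set` or `delta_feature_set` objects.
#' @return data.frame with `patient_id` (and `week` where present) plus the
#'   31 feature columns.
#' @export
feature_table <- function(sets) {
  rows <- lapply(sets, function(s) {
    d <- as.data.frame(as.list(s$features), check.names = FALSE)
    d <- cbind(data.frame(patient_id = s$patient_id), d)
    if (!is.null(s$week) && !is.na(s$week)) d <- cbind(d[1], week = s$week, d[-1])
    d
  })
  do.call(rbind, rows)
}
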
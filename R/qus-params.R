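#' Linear fit of a normalized spectrum (MBF, SS, SI)
#'
#' Ordinary least squares of the normalized spectrum (dB) on frequency (MHz)
#' over the analysis band.  The spectral slope SS is the fitted slope
#' (dB/MHz), the spectral intercept SI the 0-MHz intercept (dB), and the
#' mid-band fit MBF the fitted value at the band midpoint, so
#' `MBF = SI + SS * f_c` holds by construction.
#'
#' @param ns A [normalize_spectrum()] result.
#' @param band Optional sub-band `c(f_lo, f_hi)` MHz; defaults to the
#'   spectrum's own band.
#' @return Object of class `linear_fit_result` with `SS`, `SI`, `MBF`,
#'   `f_centre`.
#' @export
fit_linear_spectrum <- function(ns, band = NULL) {
  stopifnot(inherits(ns, "normalized_spectrum"))
  if (is.null(band)) band <- ns$band
  sel <- ns$frequencies >= band[1] & ns$frequencies <= band[2]
  f <- ns$frequencies[sel]; y <- ns$ns[sel]
  if (length(f) < 3) qstop("need at least 3 frequency points in the band")
  fit <- fit_linear_matrix(f, matrix(y, ncol = 1), mean(band))
  structure(list(SS = fit$SS[1], SI = fit$SI[1], MBF = fit$MBF[1],
                 f_centre = mean(band)),
            class = "linear_fit_result")
}

# vectorized OLS on a common frequency grid; Y is nfreq x nwin (dB)
fit_linear_matrix <- function(f, Y, f_centre) {
  X <- cbind(1, f)
  B <- unname(solve(crossprod(X), crossprod(X, Y)))
  SI <- B[1, ]; SS <- B[2, ]
  list(SI = SI, SS = SS, MBF = SI + SS * f_centre)
}

#' Effective scatterer diameter and acoustic concentration (ASD, AAC)
#'
#' Gaussian form-factor fit to the normalized backscatter spectrum: the model
#' `ns_dB(f) = AAC_dB + 40 log10(f) - (10/ln 10) * 0.827 * k^2 * a_eff^2`
#' (with `k = 2 pi f / c`) is linear in `f^2` after subtracting the Rayleigh
#' term `40 log10(f)`, so an OLS regression on `f^2` yields the effective
#' radius from the slope and the acoustic concentration (dB, relative scale)
#' from the intercept.  A positive slope is unphysical (negative squared
#' radius): ASD is then flagged invalid while AAC is still reported.
#'
#' @param ns A [normalize_spectrum()] result.
#' @param sound_speed m/s.
#' @param band Optional sub-band, MHz.
#' @return Object of class `scatterer_estimate`: `ASD` (um, or `NA` when
#'   invalid), `AAC` (dB), `valid` flag.
#' @export
estimate_asd_aac <- function(ns, sound_speed = 1540, band = NULL) {
  stopifnot(inherits(ns, "normalized_spectrum"))
  if (is.null(band)) band <- ns$band
  sel <- ns$frequencies >= band[1] & ns$frequencies <= band[2]
  f <- ns$frequencies[sel]; y <- ns$ns[sel]
  if (length(f) < 3) qstop("need at least 3 frequency points in the band")
  est <- fit_asd_matrix(f, matrix(y, ncol = 1), sound_speed)
  structure(list(ASD = est$ASD[1], AAC = est$AAC[1], valid = est$valid[1]),
            class = "scatterer_estimate")
}

fit_asd_matrix <- function(f, Y, sound_speed) {
  c_mmus <- sound_speed / 1000
  X <- cbind(1, f^2)
  B <- unname(solve(crossprod(X), crossprod(X, Y - 40 * log10(f))))
  m <- B[2, ]                                     # dB / MHz^2
  a_mm <- c_mmus / (2 * pi) * sqrt(pmax(-m, 0) * log(10) / (10 * 0.827))
  valid <- m <= 0
  ASD <- ifelse(valid, 2000 * a_mm, NA_real_)
  list(AAC = B[1, ], ASD = ASD, valid = valid)
}

#' Scatterer spacing estimate (SAS)
#'
#' Dominant spacing among scatterers from the periodicity ("ripple") of the
#' backscatter spectrum: the detrended linear-power spectrum is
#' autocorrelated over frequency lags; a regular axial spacing `d` produces a
#' ripple of period `delta_f = c / (2 d)`, so the first autocorrelation peak
#' at lag `delta_f` maps to `SAS = c / (2 delta_f)` (mm).  Peak search starts
#' after the first zero crossing (skipping the speckle correlation lobe) and
#' takes the first local maximum reaching at least half the global one, so
#' the fundamental wins over its harmonics.  The peak must exceed a
#' significance bound calibrated on the effective number of independent
#' spectral bins — the time-bandwidth product `B * T` over the Hann
#' equivalent noise bandwidth 1.5, not the (padded) grid size — otherwise
#' the estimate is null: diffuse random media carry no significant spacing.
#'
#' Naming note: this pipeline's feature list expands "SAS" as in its
#' development lineage, spacing-among-scatterers; some descriptions of the
#' same feature set print "spectral average slope" for the acronym.
#'
#' @param ns A [normalize_spectrum()] result.
#' @param sound_speed m/s.
#' @param band Optional sub-band, MHz.
#' @param require_significance If `FALSE`, always return the dominant-peak
#'   spacing (used for map construction, where a value per window is needed).
#' @param significance_level Two-sided white-noise level for the peak test.
#' @param detrend_order Polynomial order removed from the linear-power
#'   spectrum before autocorrelation.
#' @return Object of class `sas_estimate`: `SAS` (mm or `NA`), `delta_f`
#'   (MHz), `peak_r`, `significant`.
#' @export
estimate_sas <- function(ns, sound_speed = 1540, band = NULL,
                         require_significance = TRUE,
                         significance_level = 0.01, detrend_order = 2) {
  stopifnot(inherits(ns, "normalized_spectrum"))
  if (is.null(band)) band <- ns$band
  sel <- ns$frequencies >= band[1] & ns$frequencies <= band[2]
  f <- ns$frequencies[sel]; y <- ns$ns[sel]
  if (length(f) < 12) qstop("unresolvable spacing: analysis band too narrow")
  df <- f[2] - f[1]
  est <- sas_matrix(matrix(y, ncol = 1), df, sound_speed,
                    significance_level, detrend_order,
                    t_support_us = ns$t_support_us,
                    bandwidth_mhz = diff(range(f)))
  sig <- est$significant[1]
  sas <- if (!sig && require_significance) NA_real_ else est$SAS[1]
  structure(list(SAS = sas, delta_f = est$delta_f[1], peak_r = est$peak_r[1],
                 significant = sig),
            class = "sas_estimate")
}

# vectorized spacing estimator; Y dB matrix nfreq x nwin on a uniform grid
sas_matrix <- function(Y, df, sound_speed, significance_level = 0.01,
                       detrend_order = 2, t_support_us = NULL,
                       bandwidth_mhz = NULL) {
  c_mmus <- sound_speed / 1000
  n <- nrow(Y); nwin <- ncol(Y)
  p <- from_db(Y)
  x <- seq_len(n)
  X <- cbind(1, stats::poly(x, degree = detrend_order))
  R <- p - X %*% solve(crossprod(X), crossprod(X, p))
  denom <- colSums(R^2)
  lmax <- n - 3L
  r <- matrix(NA_real_, lmax, nwin)
  for (l in seq_len(lmax))
    r[l, ] <- colSums(R[seq_len(n - l), , drop = FALSE] *
                        R[(l + 1):n, , drop = FALSE]) / denom
  # effective independent bins: time-bandwidth product over Hann ENBW
  if (is.null(bandwidth_mhz)) bandwidth_mhz <- n * df
  n_eff <- if (is.null(t_support_us)) n
  else max(8, bandwidth_mhz * t_support_us / 1.5)
  thr <- qnorm(1 - significance_level / 2) / sqrt(n_eff)
  # search after the first zero crossing (skip the speckle correlation lobe);
  # first local maximum reaching half the global one beats its harmonics
  first_np <- apply(r <= 0, 2, function(z) {
    i <- which(z); if (length(i)) i[1] else lmax
  })
  peak_lag <- peak_r <- numeric(nwin)
  for (j in seq_len(nwin)) {
    lo <- min(first_np[j] + 1L, lmax - 1L)
    seg <- r[lo:lmax, j]
    gm <- max(seg)
    loc <- which(diff(sign(diff(c(-Inf, seg, -Inf)))) < 0)   # local maxima
    k <- loc[seg[loc] >= 0.5 * gm][1]
    peak_lag[j] <- lo + k - 1L
    peak_r[j] <- seg[k]
  }
  delta_f <- peak_lag * df
  list(SAS = c_mmus / (2 * delta_f), delta_f = delta_f, peak_r = peak_r,
       significant = peak_r > thr)
}

#' Attenuation estimate by the spectral-difference method
#'
#' Pools window power spectra (dB) from at least three depth strata and
#' regresses, per frequency bin, spectral amplitude on window depth; the
#' per-frequency depth slopes (dB/cm) are then regressed on frequency, whose
#' slope equals `-2 alpha` (round trip), giving the one-way attenuation
#' coefficient `alpha` in dB cm^-1 MHz^-1 (floored at 0).
#'
#' When the spectra are sample-minus-reference differences the method returns
#' the differential attenuation `alpha_sample - alpha_ref`.
#'
#' @param spectra Either a list of `window_spectrum` objects or a numeric
#'   matrix (nfreq x nwindows, dB).
#' @param depths_cm Window-centre depths (cm); taken from the objects when
#'   `spectra` is a list.
#' @param frequencies MHz grid; required for the matrix form.
#' @param band Analysis band, MHz.
#' @return Object of class `attenuation_estimate`: `alpha` (dB cm^-1
#'   MHz^-1), `alpha_signed` (before flooring), `n_windows`.
#' @export
estimate_attenuation <- function(spectra, depths_cm = NULL,
                                 frequencies = NULL, band = c(3, 8.5)) {
  if (is.list(spectra) && !is.matrix(spectra)) {
    stopifnot(all(vapply(spectra, inherits, TRUE, "window_spectrum")))
    frequencies <- spectra[[1]]$frequencies
    depths_cm <- vapply(spectra, function(s) s$window_centre$axial_mm / 10, 0)
    spectra <- vapply(spectra, function(s) s$power, numeric(length(frequencies)))
  }
  if (is.null(frequencies) || is.null(depths_cm))
    qstop("matrix input requires frequencies and depths_cm")
  if (length(unique(round(depths_cm, 6))) < 3)
    qstop("need spectra from at least 3 depth strata")
  sel <- frequencies >= band[1] & frequencies <= band[2]
  S <- spectra[sel, , drop = FALSE]
  f <- frequencies[sel]
  d <- depths_cm - mean(depths_cm)
  slope_per_f <- as.vector(S %*% d) / sum(d^2)        # dB/cm at each f
  gfit <- coef(lm(slope_per_f ~ f))
  alpha_signed <- -gfit[[2]] / 2
  structure(list(alpha = max(0, alpha_signed), alpha_signed = alpha_signed,
                 n_windows = ncol(S)),
            class = "attenuation_estimate")
}

#' @export
print.attenuation_estimate <- function(x, ...) {
  cat(sprintf("<attenuation_estimate> alpha = %.3f dB/cm/MHz (%d windows)\n",
              x$alpha, x$n_windows))
  invisible(x)
}

#' Precompute depth-resolved reference spectra
#'
#' The reference phantom's Welch spectra (averaged over all planes and
#' lateral positions at every axial window start) depend only on the scan
#' geometry and spectral configuration, so they can be computed once per
#' cohort and reused for every patient scan.
#'
#' @param reference A [simulate_reference_phantom()] scan.
#' @param frame An [rf_frame()] with the sample-scan geometry (any tissue
#'   frame of matching size).
#' @param config A [spectral_config()].
#' @return Object of class `prepared_reference`.
#' @export
prepare_reference <- function(reference, frame, config = spectral_config()) {
  w <- window_samples(frame, config)
  ax_stride <- max(1L, round(w * (1 - config$axial_overlap)))
  ax_starts <- seq(1L, nrow(frame$rf) - w + 1L, by = ax_stride)
  sp <- reference_spectra(reference, ax_starts, config)
  alpha <- reference$metadata$attenuation
  bsc_db <- reference$metadata$known_bsc_db
  structure(list(frequencies = sp$frequencies, power_db = sp$power_db,
                 axial_starts = ax_starts,
                 attenuation = if (is.null(alpha)) 0 else alpha,
                 bsc_db = if (is.null(bsc_db)) function(f) rep(0, length(f))
                 else bsc_db,
                 n_samples = nrow(frame$rf), window_samples = w),
            class = "prepared_reference")
}

new_parametric_map <- function(parameter_id, values, pixel_spacing_mm,
                               roi_mask, origin_mm) {
  structure(list(parameter_id = parameter_id, values = values,
                 pixel_spacing_mm = pixel_spacing_mm, roi_mask = roi_mask,
                 origin_mm = origin_mm),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s: %d x %d windows (%.2f x %.2f mm), %d in ROI\n",
              x$parameter_id, nrow(x$values), ncol(x$values),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], sum(x$roi_mask)))
  invisible(x)
}

#' Build the six QUS parametric maps over a tumour ROI
#'
#' Runs the whole spectral chain for every in-ROI sliding window of every
#' plane of a scan: Welch power spectra, reference-phantom normalization with
#' point attenuation compensation at the window-centre depth, then the
#' MBF/SS/SI linear fit, the ASD/AAC form-factor fit, and the SAS spacing
#' estimate per window.  The scan attenuation is estimated first by the
#' spectral-difference method on sample-minus-reference spectra (differential
#' to the phantom's known attenuation) unless supplied.
#'
#' @param scan An [rf_scan()] of the tissue.
#' @param roi Logical mask (RF samples x lines), or a list of one mask per
#'   plane.
#' @param config A [spectral_config()].
#' @param reference A [simulate_reference_phantom()] scan (or any `rf_scan`
#'   with `metadata$known_bsc_db` and `metadata$attenuation`).
#' @param alpha_sample Optional known tissue attenuation (dB cm^-1 MHz^-1);
#'   estimated when `NULL`.
#' @param sas_require_significance Passed to the spacing estimator; maps
#'   default to the ungated dominant-peak estimate so that SAS textures are
#'   defined for diffuse media.
#' @return Object of class `qus_maps`: `maps` (per plane, per parameter
#'   [new_parametric_map]s), `means` (the six per-scan mean features),
#'   `attenuation` (`attenuation_estimate`), `n_windows`, `n_invalid`.
#' @export
build_parametric_maps <- function(scan, roi, config = spectral_config(),
                                  reference, alpha_sample = NULL,
                                  sas_require_significance = FALSE) {
  stopifnot(inherits(scan, "rf_scan"))
  frames <- scan$frames
  if (is.matrix(roi)) roi <- rep(list(roi), length(frames))
  if (length(roi) != length(frames)) qstop("need one ROI mask per plane")
  if (!any(vapply(roi, any, TRUE))) qstop("ROI mask is empty")

  fr1 <- frames[[1]]
  w <- window_samples(fr1, config)
  nl <- config$window_lines
  ax_stride <- max(1L, round(w * (1 - config$axial_overlap)))
  lat_stride <- max(1L, round(nl * (1 - config$lateral_overlap)))
  ax_starts <- seq(1L, nrow(fr1$rf) - w + 1L, by = ax_stride)
  lat_starts <- seq(1L, ncol(fr1$rf) - nl + 1L, by = lat_stride)

  # which grid nodes have their centre pixel inside the ROI, per frame
  centre_r <- pmin(ax_starts + w %/% 2L, nrow(fr1$rf))
  centre_c <- pmin(lat_starts + nl %/% 2L, ncol(fr1$rf))
  grids <- lapply(roi, function(m) {
    g <- m[centre_r, centre_c, drop = FALSE]
    g
  })
  if (!any(vapply(grids, any, TRUE)))
    qstop("ROI smaller than one analysis window")

  if (inherits(reference, "prepared_reference")) {
    if (reference$n_samples != nrow(fr1$rf) ||
        reference$window_samples != w ||
        length(reference$axial_starts) != length(ax_starts))
      qstop("prepared reference does not match the scan geometry")
    ref_sp <- list(frequencies = reference$frequencies,
                   power_db = reference$power_db)
    alpha_ref <- reference$attenuation
    bsc_db <- reference$bsc_db
  } else {
    ref_sp <- reference_spectra(reference, ax_starts, config)
    alpha_ref <- reference$metadata$attenuation
    if (is.null(alpha_ref)) alpha_ref <- 0
    bsc_db <- reference$metadata$known_bsc_db
    if (is.null(bsc_db)) bsc_db <- function(f) rep(0, length(f))
  }

  per_frame <- vector("list", length(frames))
  diff_all <- NULL; depth_all <- NULL
  for (i in seq_along(frames)) {
    g <- grids[[i]]
    nodes <- which(g, arr.ind = TRUE)
    if (nrow(nodes) == 0L) { per_frame[[i]] <- NULL; next }
    ws <- window_spectra(frames[[i]], ax_starts[nodes[, 1]],
                         lat_starts[nodes[, 2]], config)
    diffs <- ws$power_db - ref_sp$power_db[, nodes[, 1], drop = FALSE]
    per_frame[[i]] <- list(nodes = nodes, ws = ws, diffs = diffs)
    diff_all <- cbind(diff_all, diffs)
    depth_all <- c(depth_all, ws$centres$axial_mm / 10)
  }

  att <- tryCatch(
    estimate_attenuation(diff_all, depth_all, ref_sp$frequencies, config$band),
    error = function(e) NULL)
  if (is.null(alpha_sample)) {
    alpha_sample <- if (is.null(att)) alpha_ref else max(0, alpha_ref + att$alpha_signed)
  }
  att_report <- if (is.null(att)) {
    structure(list(alpha = alpha_sample, alpha_signed = alpha_sample,
                   n_windows = 0L), class = "attenuation_estimate")
  } else {
    att$alpha <- max(0, alpha_ref + att$alpha_signed)
    att$alpha_signed <- alpha_ref + att$alpha_signed
    att
  }

  f <- ref_sp$frequencies
  in_band <- f >= config$band[1] & f <= config$band[2]
  fb <- f[in_band]
  f_centre <- mean(config$band)
  c_mps <- fr1$sound_speed
  params <- qus_param_names()
  pixel_spacing <- c(ax_stride / fr1$sampling_rate * (c_mps / 1000) / 2,
                     lat_stride * fr1$line_pitch_mm)

  maps <- vector("list", length(frames))
  vals_all <- stats::setNames(vector("list", 6), params)
  n_windows <- 0L; n_invalid <- 0L
  for (i in seq_along(frames)) {
    pf <- per_frame[[i]]
    empty <- matrix(NA_real_, length(ax_starts), length(lat_starts))
    frame_maps <- stats::setNames(lapply(params, function(p)
      new_parametric_map(p, empty, pixel_spacing, grids[[i]],
                         c((ax_starts[1] - 1 + w / 2) / fr1$sampling_rate * (c_mps / 1000) / 2,
                           (lat_starts[1] - 1 + nl / 2) * fr1$line_pitch_mm))),
      params)
    if (!is.null(pf)) {
      depth_cm <- pf$ws$centres$axial_mm / 10
      comp <- outer(fb, depth_cm, function(ff, dd)
        attenuation_compensation_db(ff, dd, alpha_sample, alpha_ref))
      NS <- pf$diffs[in_band, , drop = FALSE] + bsc_db(fb) + comp
      lin <- fit_linear_matrix(fb, NS, f_centre)
      sca <- fit_asd_matrix(fb, NS, c_mps)
      sas <- sas_matrix(NS, fb[2] - fb[1], c_mps,
                        t_support_us = w / fr1$sampling_rate,
                        bandwidth_mhz = diff(range(fb)))
      sas_vals <- sas$SAS
      if (sas_require_significance) sas_vals[!sas$significant] <- NA_real_
      est <- list(MBF = lin$MBF, SS = lin$SS, SI = lin$SI,
                  SAS = sas_vals, ASD = sca$ASD, AAC = sca$AAC)
      idx <- pf$nodes
      for (p in params) {
        m <- frame_maps[[p]]$values
        m[idx] <- est[[p]]
        frame_maps[[p]]$values <- m
        vals_all[[p]] <- c(vals_all[[p]], est[[p]])
      }
      n_windows <- n_windows + nrow(idx)
      n_invalid <- n_invalid + sum(!sca$valid)
    }
    maps[[i]] <- frame_maps
  }
  means <- vapply(vals_all, function(v) mean(v, na.rm = TRUE), 0)
  structure(list(maps = maps, means = means, attenuation = att_report,
                 n_windows = n_windows, n_invalid = n_invalid,
                 pixel_spacing_mm = pixel_spacing, config = config),
            class = "qus_maps")
}

#' @export
print.qus_maps <- function(x, ...) {
  cat(sprintf("<qus_maps> %d planes, %d ROI windows (%d invalid ASD fits)\n",
              length(x$maps), x$n_windows, x$n_invalid))
  cat("  means: ", paste(sprintf("%s=%.2f", names(x$means), x$means),
                         collapse = ", "), "\n")
  cat(sprintf("  attenuation: %.3f dB/cm/MHz\n", x$attenuation$alpha))
  invisible(x)
}

#' Export a parametric map as PNG with a fixed colour scale
#'
#' Fixed display ranges follow the usual parametric-image conventions
#' (MBF -10..30 dB, SS -6..2 dB/MHz); other parameters default to their
#' in-map range.
#'
#' @param map A `parametric_map`.
#' @param path Output PNG path.
#' @param zlim Colour scale limits; chosen by parameter when `NULL`.
#' @export
write_map_png <- function(map, path, zlim = NULL) {
  if (is.null(zlim))
    zlim <- switch(map$parameter_id, MBF = c(-10, 30), SS = c(-6, 2), NULL)
  v <- map$values
  if (is.null(zlim)) zlim <- range(v, na.rm = TRUE)
  v <- pmin(pmax(v, zlim[1]), zlim[2])
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(t(v)[, rev(seq_len(nrow(v))), drop = FALSE], zlim = zlim,
                  col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                  main = map$parameter_id)
  invisible(path)
}
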
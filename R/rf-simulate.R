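#' RF frame container
#'
#' A single B-scan plane of raw RF echo data: a samples x lines matrix plus
#' acquisition geometry.  All spectral estimation starts here.
#'
#' @param rf Numeric matrix, axial samples x scan lines.
#' @param sampling_rate RF sampling rate, MHz.
#' @param sound_speed m/s.
#' @param line_pitch_mm Lateral spacing between scan lines, mm.
#' @return Object of class `rf_frame`.
#' @export
rf_frame <- function(rf, sampling_rate = 40, sound_speed = 1540,
                     line_pitch_mm = 0.23) {
  if (!is.matrix(rf) || !is.numeric(rf)) qstop("rf must be a numeric matrix")
  if (any(!is.finite(rf))) qstop("rf contains non-finite values")
  if (sampling_rate <= 0) qstop("sampling_rate must be positive")
  structure(list(rf = rf, sampling_rate = sampling_rate,
                 sound_speed = sound_speed, line_pitch_mm = line_pitch_mm,
                 depth_mm = nrow(rf) / sampling_rate * (sound_speed / 1000) / 2),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, fs = %g MHz, depth = %.1f mm%s\n",
              nrow(x$rf), ncol(x$rf), x$sampling_rate, x$depth_mm,
              if (isTRUE(attr(x, "empty_field"))) " [empty field]" else ""))
  invisible(x)
}

# axial depth (mm) of each RF sample row
frame_depth_axis <- function(frame) {
  (seq_len(nrow(frame$rf)) - 0.5) / frame$sampling_rate *
    (frame$sound_speed / 1000) / 2
}

#' Simulate one RF frame from a scatterer field
#'
#' Pulse-echo model: each line is the superposition of transmit-pulse echoes
#' at the scatterers' round-trip delays, scaled by reflectivity.  The pulse is
#' applied in the frequency domain; frequency-dependent attenuation (and the
#' Gaussian form factor for finite scatterer size, and any phantom backscatter
#' spectrum) is applied per depth stratum, a piecewise-constant-in-depth
#' approximation controlled by `n_strata`.  No diffraction or elevational beam
#' model: pure 1-D convolution per line.  Deterministic given the field.
#'
#' @param field A [scatterer_field()].
#' @param pulse A [pulse_model()].
#' @param attenuation One-way attenuation coefficient, dB cm^-1 MHz^-1.
#' @param line_pitch_mm Lateral line spacing, mm.
#' @param n_lines Number of scan lines; default covers the field width.
#' @param n_strata Depth strata for the attenuation/form-factor filter.
#' @param bsc_linear Optional relative backscatter power spectrum (function of
#'   frequency in MHz returning positive linear power, or a positive scalar);
#'   used by the reference-phantom generator.
#' @return An [rf_frame()]; a zero frame flagged with attribute `empty_field`
#'   when the field holds no scatterers.
#' @export
simulate_rf_frame <- function(field, pulse, attenuation = 0,
                              line_pitch_mm = 0.23, n_lines = NULL,
                              n_strata = 8, bsc_linear = NULL) {
  stopifnot(inherits(field, "scatterer_field"), inherits(pulse, "pulse_model"))
  if (pulse$sampling_rate <= 4 * pulse$centre_frequency)
    qstop("sampling below the Nyquist margin")
  if (attenuation < 0) qstop("attenuation must be >= 0")
  c_mmus <- pulse$sound_speed / 1000
  fs <- pulse$sampling_rate
  if (is.null(n_lines)) n_lines <- max(1L, round(field$width_mm / line_pitch_mm))
  n_t <- ceiling(2 * field$depth_mm / c_mmus * fs)

  if (length(field$z_mm) == 0L) {
    fr <- rf_frame(matrix(0, n_t, n_lines), fs, pulse$sound_speed, line_pitch_mm)
    attr(fr, "empty_field") <- TRUE
    return(fr)
  }

  pw_len <- length(pulse_waveform(pulse)$waveform)
  nfft <- stats::nextn(n_t + pw_len + 8L, c(2L, 3L))
  P <- pulse_transfer(pulse, nfft)
  f_abs <- abs(((seq_len(nfft) - 1 + nfft %/% 2) %% nfft - nfft %/% 2)) * fs / nfft

  line <- floor(field$x_mm / line_pitch_mm) + 1L
  samp <- round(2 * field$z_mm / c_mmus * fs) + 1L
  keep <- line >= 1L & line <= n_lines & samp >= 1L & samp <= n_t
  z <- field$z_mm[keep]; line <- line[keep]; samp <- samp[keep]
  amp <- field$amplitude[keep]

  # depth-independent filters
  H0 <- P
  if (!is.null(bsc_linear)) {
    b <- if (is.function(bsc_linear)) bsc_linear(f_abs) else rep(bsc_linear, nfft)
    if (any(!is.finite(b)) || any(b <= 0))
      qstop("backscatter spectrum must be positive over the simulated band")
    H0 <- H0 * sqrt(b)
  }

  flat <- attenuation == 0 && field$effective_radius_um == 0
  n_str <- if (flat) 1L else as.integer(n_strata)
  breaks <- seq(0, field$depth_mm, length.out = n_str + 1L)
  stratum <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L), n_str)
  a_mm <- field$effective_radius_um / 1000
  k_grid <- 2 * pi * f_abs / c_mmus

  S <- matrix(0 + 0i, nfft, n_lines)
  for (k in seq_len(n_str)) {
    in_k <- stratum == k
    if (!any(in_k)) next
    imp <- matrix(0, nfft, n_lines)
    idx <- samp[in_k] + (line[in_k] - 1L) * nfft
    agg <- rowsum(amp[in_k], idx)
    imp[as.integer(rownames(agg))] <- agg
    Hk <- H0
    if (attenuation > 0) {
      z_bar_cm <- (breaks[k] + breaks[k + 1L]) / 2 / 10
      Hk <- Hk * 10^(-attenuation * f_abs * 2 * z_bar_cm / 20)
    }
    if (a_mm > 0) Hk <- Hk * exp(-0.827 * k_grid^2 * a_mm^2 / 2)
    S <- S + mvfft(imp) * Hk
  }
  rf <- Re(mvfft(S, inverse = TRUE)) / nfft
  rf_frame(rf[seq_len(n_t), , drop = FALSE], fs, pulse$sound_speed, line_pitch_mm)
}

#' RF scan container (multiple image planes)
#'
#' Planes are parallel frames acquired at fixed elevational intervals
#' (default 0.5 cm), each an independent speckle realization of the same
#' tissue statistics.
#'
#' @param frames List of [rf_frame()] objects with identical geometry.
#' @param plane_spacing_cm Elevational spacing, cm.
#' @param metadata Optional list (e.g. phantom ground truth).
#' @export
rf_scan <- function(frames, plane_spacing_cm = 0.5, metadata = list()) {
  stopifnot(length(frames) >= 1, all(vapply(frames, inherits, TRUE, "rf_frame")))
  dims <- vapply(frames, function(f) dim(f$rf), integer(2))
  if (any(dims != dims[, 1])) qstop("all frames must share geometry")
  structure(list(frames = frames, plane_spacing_cm = plane_spacing_cm,
                 metadata = metadata),
            class = "rf_scan")
}

#' @export
print.rf_scan <- function(x, ...) {
  cat(sprintf("<rf_scan> %d planes at %.1f cm spacing; ", length(x$frames),
              x$plane_spacing_cm))
  print(x$frames[[1]])
  invisible(x)
}

#' Simulate a multi-plane scan of one tissue state
#'
#' Each plane gets an independent scatterer realization drawn from the same
#' field parameters (seeds `seed + plane - 1`).
#'
#' @param field_params List of arguments for [scatterer_field()] (minus
#'   `seed`).
#' @param pulse A [pulse_model()].
#' @param attenuation dB cm^-1 MHz^-1.
#' @param n_planes Number of image planes.
#' @param seed Base seed.
#' @inheritParams simulate_rf_frame
#' @export
simulate_rf_scan <- function(field_params, pulse, attenuation = 0,
                             n_planes = 3, seed = 1,
                             line_pitch_mm = 0.23, n_lines = NULL,
                             n_strata = 8, bsc_linear = NULL) {
  frames <- lapply(seq_len(n_planes), function(p) {
    fld <- do.call(scatterer_field,
                   c(field_params, list(seed = derive_seed(seed, p))))
    simulate_rf_frame(fld, pulse, attenuation, line_pitch_mm, n_lines,
                      n_strata, bsc_linear)
  })
  rf_scan(frames, metadata = list(attenuation = attenuation, seed = seed))
}

#' Simulate a reference phantom acquisition
#'
#' A homogeneous random medium with known backscatter spectrum and known
#' attenuation, scanned with the same system model as the tissue — the
#' normalizer used by the reference phantom method.  Ground truth is recorded
#' in the scan metadata.
#'
#' @param pulse A [pulse_model()].
#' @param known_bsc Relative backscatter power: positive scalar or a function
#'   of frequency (MHz) returning positive linear power.
#' @param known_attenuation One-way attenuation, dB cm^-1 MHz^-1.
#' @param depth_mm,width_mm,line_pitch_mm,n_lines Geometry.
#' @param number_density Scatterers per mm^2 (dense: fully developed speckle).
#' @param n_planes Number of independent planes.
#' @param seed Integer seed.
#' @return An [rf_scan()] whose metadata holds `known_bsc_db` (function of
#'   MHz), `attenuation`, and the generator settings.
#' @export
simulate_reference_phantom <- function(pulse, known_bsc = 1,
                                       known_attenuation = 0,
                                       depth_mm = 40, width_mm = 58.88,
                                       line_pitch_mm = 0.23, n_lines = NULL,
                                       number_density = 12, n_planes = 3,
                                       seed = 99) {
  test_f <- seq(0.5, pulse$sampling_rate / 2, by = 0.5)
  bvals <- if (is.function(known_bsc)) known_bsc(test_f) else rep(known_bsc, length(test_f))
  if (any(!is.finite(bvals)) || any(bvals <= 0))
    qstop("known_bsc must be positive over the analysis band")
  scan <- simulate_rf_scan(
    list(depth_mm = depth_mm, width_mm = width_mm,
         number_density = number_density),
    pulse, attenuation = known_attenuation, n_planes = n_planes, seed = seed,
    line_pitch_mm = line_pitch_mm, n_lines = n_lines, bsc_linear = known_bsc)
  bsc_db <- if (is.function(known_bsc)) {
    force(known_bsc); function(f) to_db(known_bsc(f))
  } else {
    b <- to_db(known_bsc); function(f) rep(b, length(f))
  }
  scan$metadata <- list(known_bsc = known_bsc, known_bsc_db = bsc_db,
                        attenuation = known_attenuation,
                        number_density = number_density, seed = seed,
                        pulse = pulse)
  class(scan) <- c("reference_phantom", class(scan))
  scan
}
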
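#' Sliding-window spectral analysis configuration
#'
#' Defaults follow the usual QUS lineage: 2.5 mm x 2.5 mm Hann-tapered
#' windows (>= 10 wavelengths at 6.5 MHz) with 80% overlap in both
#' directions, Welch-style averaging of per-line periodograms within each
#' window, and a 3.0–8.5 MHz analysis band matching the transducer.
#'
#' @param window_length_mm Axial window length, mm; must be at least ten
#'   wavelengths at `centre_frequency`.
#' @param window_lines Lateral window width in scan lines.
#' @param axial_overlap,lateral_overlap Window overlap fractions in [0, 1).
#' @param band Analysis band `c(f_lo, f_hi)`, MHz.
#' @param taper Only `"hann"` is provided.
#' @param pad_factor Zero-padding factor for the per-line FFT.
#' @param centre_frequency MHz; used for the wavelength validity check.
#' @param sound_speed m/s; used for the wavelength validity check.
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(window_length_mm = 2.5, window_lines = 11,
                            axial_overlap = 0.8, lateral_overlap = 0.8,
                            band = c(3, 8.5), taper = "hann", pad_factor = 2,
                            centre_frequency = 6.5, sound_speed = 1540) {
  taper <- match.arg(taper, "hann")
  if (axial_overlap < 0 || axial_overlap >= 1 ||
      lateral_overlap < 0 || lateral_overlap >= 1)
    qstop("overlaps must lie in [0, 1)")
  if (length(band) != 2 || band[1] >= band[2]) qstop("band must be c(f_lo, f_hi) with f_lo < f_hi")
  lambda_mm <- sound_speed / 1000 / centre_frequency
  if (window_length_mm < 10 * lambda_mm)
    qstop(sprintf("window_length_mm must be >= 10 wavelengths at %.2f MHz (%.2f mm)",
                  centre_frequency, 10 * lambda_mm))
  if (window_lines < 1) qstop("window_lines must be >= 1")
  structure(list(window_length_mm = window_length_mm,
                 window_lines = as.integer(window_lines),
                 axial_overlap = axial_overlap,
                 lateral_overlap = lateral_overlap,
                 band = band, taper = taper, pad_factor = pad_factor,
                 centre_frequency = centre_frequency,
                 sound_speed = sound_speed),
            class = "spectral_config")
}

# window length in RF samples for a given frame
window_samples <- function(frame, config) {
  c_mmus <- frame$sound_speed / 1000
  max(8L, round(2 * config$window_length_mm / c_mmus * frame$sampling_rate))
}

hann_taper <- function(w) 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))

# Vectorized engine: Welch-averaged power spectra (dB) for many windows of one
# frame.  axial_starts are first-sample indices, line_starts first-line
# indices; both vectors have one entry per window.
window_spectra <- function(frame, axial_starts, line_starts, config) {
  rf <- frame$rf
  w <- window_samples(frame, config)
  nl <- config$window_lines
  n_t <- nrow(rf); n_l <- ncol(rf)
  if (length(axial_starts) != length(line_starts))
    qstop("axial_starts and line_starts must have equal length")
  if (any(axial_starts < 1L | axial_starts + w - 1L > n_t |
          line_starts < 1L | line_starts + nl - 1L > n_l))
    qstop("window extends outside the frame")
  nwin <- length(axial_starts)
  # column-major gather: for each window its lines are contiguous
  col_starts <- rep(axial_starts, each = nl) +
    (rep(line_starts, each = nl) + rep(seq_len(nl) - 1L, nwin) - 1L) * n_t
  idx <- outer(seq_len(w) - 1L, col_starts, `+`)
  seg <- matrix(rf[idx], nrow = w)
  if (any(colSums(seg != 0) == 0))
    qstop("degenerate window: all-zero RF segment")
  h <- hann_taper(w)
  seg <- seg * h
  nfft <- stats::nextn(config$pad_factor * w, c(2L, 3L))
  padded <- matrix(0, nfft, ncol(seg))
  padded[seq_len(w), ] <- seg
  pw <- Mod(mvfft(padded))^2 / sum(h^2)
  # average the nl per-line periodograms of each window
  acc <- pw[, seq(1L, ncol(pw), by = nl), drop = FALSE]
  if (nl > 1L) for (m in 2:nl)
    acc <- acc + pw[, seq(m, ncol(pw), by = nl), drop = FALSE]
  acc <- acc / nl
  half <- seq_len(nfft %/% 2 + 1L)
  freqs <- (half - 1L) * frame$sampling_rate / nfft
  c_mmus <- frame$sound_speed / 1000
  centres <- data.frame(
    axial_mm = (axial_starts - 1 + w / 2) / frame$sampling_rate * c_mmus / 2,
    lateral_mm = (line_starts - 1 + nl / 2) * frame$line_pitch_mm)
  list(frequencies = freqs, power_db = to_db(acc[half, , drop = FALSE]),
       centres = centres, band = config$band, window_samples = w,
       nfft = nfft, t_support_us = w / frame$sampling_rate)
}

#' Power spectrum of a single analysis window
#'
#' Hann-tapered per-line FFT periodograms averaged across the window's lines
#' (Welch-style), in dB re 1.
#'
#' @param frame An [rf_frame()].
#' @param axial_start First RF sample of the window (index).
#' @param line_start First scan line of the window (index).
#' @param config A [spectral_config()].
#' @return Object of class `window_spectrum`: `frequencies` (MHz),
#'   `power` (dB), `window_centre` (axial/lateral mm), `band`.
#' @export
compute_power_spectrum <- function(frame, axial_start, line_start,
                                   config = spectral_config()) {
  ws <- window_spectra(frame, as.integer(axial_start), as.integer(line_start),
                       config)
  structure(list(frequencies = ws$frequencies, power = ws$power_db[, 1],
                 window_centre = as.list(ws$centres[1, ]),
                 band = ws$band, t_support_us = ws$t_support_us),
            class = "window_spectrum")
}

#' @export
print.window_spectrum <- function(x, ...) {
  cat(sprintf("<window_spectrum> %d bins, %.2f-%.2f MHz grid, centre (%.1f, %.1f) mm\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$window_centre$axial_mm, x$window_centre$lateral_mm))
  invisible(x)
}

# attenuation compensation term (dB): round-trip path 2*z at depth z_cm,
# alpha in dB/cm/MHz
attenuation_compensation_db <- function(freq_mhz, depth_cm, alpha_sample, alpha_ref) {
  2 * depth_cm * freq_mhz * (alpha_sample - alpha_ref)
}

bsc_db_values <- function(phantom_bsc, freqs) {
  if (is.function(phantom_bsc)) phantom_bsc(freqs)
  else if (length(phantom_bsc) == 1L) rep(phantom_bsc, length(freqs))
  else if (length(phantom_bsc) == length(freqs)) phantom_bsc
  else qstop("phantom_bsc must be a scalar, a function of frequency, or match the grid")
}

#' Reference-phantom normalization of a window spectrum
#'
#' Computes the normalized spectrum `ns(f) = S_dB(f) - R_dB(f) + BSC_dB(f) +
#' 2 z f (alpha_s - alpha_r)` on the analysis band: subtracting the reference
#' spectrum measured at the same depth on the same system cancels the system
#' transfer function exactly; the phantom's known backscatter restores the
#' absolute scale and the last term compensates the differential round-trip
#' attenuation at the window-centre depth `z` (cm).
#'
#' @param sample,reference `window_spectrum` objects on identical frequency
#'   grids at the same depth.
#' @param phantom_bsc Phantom backscatter in dB: scalar, vector on the grid,
#'   or function of frequency (MHz).
#' @param alpha_sample,alpha_ref One-way attenuation, dB cm^-1 MHz^-1.
#' @param depth_cm Window-centre depth, cm (>= 0).
#' @return Object of class `normalized_spectrum` restricted to the analysis
#'   band: `frequencies`, `ns` (dB), `window_centre`.
#' @export
normalize_spectrum <- function(sample, reference, phantom_bsc = 0,
                               alpha_sample = 0, alpha_ref = 0,
                               depth_cm = NULL) {
  stopifnot(inherits(sample, "window_spectrum"),
            inherits(reference, "window_spectrum"))
  if (length(sample$frequencies) != length(reference$frequencies) ||
      any(abs(sample$frequencies - reference$frequencies) > 1e-9))
    qstop("frequency grid mismatch between sample and reference")
  if (is.null(depth_cm)) depth_cm <- sample$window_centre$axial_mm / 10
  if (depth_cm < 0) qstop("depth_cm must be >= 0")
  f <- sample$frequencies
  ns <- sample$power - reference$power + bsc_db_values(phantom_bsc, f) +
    attenuation_compensation_db(f, depth_cm, alpha_sample, alpha_ref)
  in_band <- f >= sample$band[1] & f <= sample$band[2]
  structure(list(frequencies = f[in_band], ns = ns[in_band],
                 window_centre = sample$window_centre, band = sample$band,
                 t_support_us = sample$t_support_us),
            class = "normalized_spectrum")
}

#' @export
print.normalized_spectrum <- function(x, ...) {
  cat(sprintf("<normalized_spectrum> %d bins on [%.2f, %.2f] MHz, band mean %.2f dB\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              mean(x$ns)))
  invisible(x)
}

#' Export a spectrum to CSV
#'
#' @param x A `window_spectrum` or `normalized_spectrum`.
#' @param path Output CSV path.
#' @export
write_spectrum_csv <- function(x, path) {
  val <- if (inherits(x, "normalized_spectrum")) x$ns else x$power
  write.csv(data.frame(frequency_mhz = x$frequencies, power_db = val),
            path, row.names = FALSE)
  invisible(path)
}

# Depth-resolved reference spectra: mean linear power over all planes and all
# lateral positions at each axial start, in dB.  Returns nfreq x n_axial.
reference_spectra <- function(ref_scan, axial_starts, config) {
  stopifnot(inherits(ref_scan, "rf_scan"))
  fr1 <- ref_scan$frames[[1]]
  nl <- config$window_lines
  lat <- seq(1L, ncol(fr1$rf) - nl + 1L,
             by = max(1L, floor(nl / 2)))
  acc <- NULL
  for (fr in ref_scan$frames) {
    ws <- window_spectra(fr,
                         rep(axial_starts, each = length(lat)),
                         rep(lat, length(axial_starts)), config)
    lin <- from_db(ws$power_db)
    m <- vapply(seq_along(axial_starts), function(j) {
      cols <- (j - 1L) * length(lat) + seq_along(lat)
      rowMeans(lin[, cols, drop = FALSE])
    }, numeric(nrow(lin)))
    acc <- if (is.null(acc)) m else acc + m
    freqs <- ws$frequencies
  }
  list(frequencies = freqs, power_db = to_db(acc / length(ref_scan$frames)),
       axial_starts = axial_starts)
}
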
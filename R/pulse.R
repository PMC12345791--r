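#' Transmit pulse model
#'
#' Gaussian-enveloped cosine pulse emulating a linear-array transducer
#' (default: 6.5 MHz centre frequency with a 3.0–8.5 MHz band, i.e. a -6 dB
#' fractional bandwidth of 5.5/6.5).  The -6 dB convention is the usual one
#' for medical transducer bandwidth specs.
#'
#' @param centre_frequency Centre frequency, MHz.
#' @param fractional_bandwidth Two-sided -6 dB bandwidth divided by the centre
#'   frequency; must lie in (0, 2).
#' @param sampling_rate RF sampling rate, MHz; must exceed 4 x centre
#'   frequency (Nyquist margin).
#' @param sound_speed Speed of sound, m/s.
#' @return An object of class `pulse_model`.
#' @examples
#' p <- pulse_model()
#' w <- pulse_waveform(p)
#' @export
pulse_model <- function(centre_frequency = 6.5,
                        fractional_bandwidth = 5.5 / 6.5,
                        sampling_rate = 40,
                        sound_speed = 1540) {
  if (!is.numeric(centre_frequency) || centre_frequency <= 0)
    qstop("centre_frequency must be > 0 MHz")
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    qstop("fractional_bandwidth must lie in (0, 2)")
  if (sampling_rate <= 4 * centre_frequency)
    qstop("sampling_rate must exceed 4 x centre_frequency (Nyquist margin); ",
          "got ", sampling_rate, " MHz for fc = ", centre_frequency, " MHz")
  if (sound_speed <= 0) qstop("sound_speed must be positive")
  structure(list(centre_frequency = centre_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate = sampling_rate,
                 sound_speed = sound_speed),
            class = "pulse_model")
}

#' @export
print.pulse_model <- function(x, ...) {
  bw <- x$fractional_bandwidth * x$centre_frequency
  cat(sprintf("<pulse_model> fc = %.2f MHz, -6 dB band = %.2f-%.2f MHz, fs = %g MHz, c = %g m/s\n",
              x$centre_frequency, x$centre_frequency - bw / 2,
              x$centre_frequency + bw / 2, x$sampling_rate, x$sound_speed))
  invisible(x)
}

# Gaussian envelope time constant (us) from the -6 dB spectral half-width.
pulse_sigma_t <- function(pulse) {
  half_bw <- pulse$fractional_bandwidth * pulse$centre_frequency / 2   # MHz
  sigma_f <- half_bw / sqrt(2 * log(10^(6 / 20)))
  1 / (2 * pi * sigma_f)
}

#' Sampled pulse waveform
#'
#' @param pulse A [pulse_model()].
#' @param n_sigma Envelope support half-width in units of the Gaussian time
#'   constant.
#' @return List with `waveform` (amplitude samples), `t_us` (time axis,
#'   microseconds) and `centre_index` (sample of the envelope peak).
#' @export
pulse_waveform <- function(pulse, n_sigma = 4) {
  sigma_t <- pulse_sigma_t(pulse)
  dt <- 1 / pulse$sampling_rate
  half <- ceiling(n_sigma * sigma_t / dt)
  t_us <- (-half:half) * dt
  w <- cos(2 * pi * pulse$centre_frequency * t_us) * exp(-t_us^2 / (2 * sigma_t^2))
  list(waveform = w, t_us = t_us, centre_index = half + 1L)
}

# Conjugate-symmetric pulse transfer function on an n-point FFT grid, with the
# envelope peak mapped to zero delay (so an echo lands at its geometric sample).
pulse_transfer <- function(pulse, nfft) {
  pw <- pulse_waveform(pulse)
  if (length(pw$waveform) >= nfft)
    qstop("FFT length too short for the pulse support")
  p <- numeric(nfft)
  idx <- seq_along(pw$waveform) - pw$centre_index           # ...-1, 0, 1...
  p[(idx %% nfft) + 1L] <- pw$waveform
  fft(p)
}
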
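#' Random point-scatterer field
#'
#' Generates the tissue model consumed by [simulate_rf_frame()]: point
#' scatterers at random (or quasi-periodic, or partially clustered) positions
#' in an axial x lateral field of view, with zero-mean Gaussian reflectivity
#' amplitudes so that backscattered power adds incoherently (power scales
#' linearly with concentration).
#'
#' `spacing_mode = "quasi_periodic"` snaps axial positions to a comb of period
#' `period_mm` with Gaussian jitter — the ground truth for scatterer-spacing
#' (SAS) recovery.  `cluster_fraction > 0` reassigns that fraction of
#' scatterers to Gaussian clumps (mimicking cell aggregation after treatment).
#'
#' @param depth_mm,width_mm Field of view (axial depth from the transducer
#'   face, lateral width), mm.
#' @param number_density Scatterers per mm^2; the realized count is
#'   `round(number_density * area)` so density contrasts are exact.
#' @param amplitude_sd Standard deviation of the Gaussian reflectivity
#'   amplitudes (dimensionless).
#' @param effective_radius_um Effective Gaussian scatterer radius, um; 0 means
#'   ideal point scatterers (form factor = 1).
#' @param spacing_mode `"random"` or `"quasi_periodic"`.
#' @param period_mm Axial comb period for quasi-periodic spacing, mm.
#' @param jitter_frac Axial jitter SD as a fraction of `period_mm`.
#' @param coherent_amplitude Mean reflectivity (in units of `amplitude_sd`)
#'   added to quasi-periodic scatterers: a regular lattice scatters
#'   coherently, and it is this non-zero-mean component that imprints the
#'   spacing ripple on the power spectrum.  Ignored for random fields, which
#'   stay zero-mean (diffuse).
#' @param cluster_fraction Fraction of scatterers drawn into clusters.
#' @param cluster_sd_mm Gaussian cluster radius, mm.
#' @param mean_cluster_size Expected scatterers per cluster.
#' @param seed Integer seed; the field is a pure function of its arguments.
#' @return An object of class `scatterer_field` with `z_mm`, `x_mm`,
#'   `amplitude` vectors and the generating parameters.
#' @export
scatterer_field <- function(depth_mm = 40, width_mm = 58.88,
                            number_density = 10, amplitude_sd = 1,
                            effective_radius_um = 0,
                            spacing_mode = c("random", "quasi_periodic"),
                            period_mm = 1, jitter_frac = 0.03,
                            coherent_amplitude = 2,
                            cluster_fraction = 0, cluster_sd_mm = 0.15,
                            mean_cluster_size = 6,
                            seed = 1) {
  spacing_mode <- match.arg(spacing_mode)
  if (depth_mm <= 0 || width_mm <= 0) qstop("field of view must be positive")
  if (number_density < 0) qstop("number_density must be >= 0")
  if (cluster_fraction < 0 || cluster_fraction > 1)
    qstop("cluster_fraction must lie in [0, 1]")
  n <- round(number_density * depth_mm * width_mm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n == 0L) {
    z <- x <- a <- numeric(0)
  } else {
    x <- runif(n, 0, width_mm)
    if (spacing_mode == "random") {
      z <- runif(n, 0, depth_mm)
    } else {
      comb <- seq(period_mm / 2, depth_mm, by = period_mm)
      z <- sample(comb, n, replace = TRUE) + rnorm(n, 0, jitter_frac * period_mm)
    }
    if (cluster_fraction > 0) {
      n_cl <- max(1L, round(n * cluster_fraction / mean_cluster_size))
      cz <- runif(n_cl, 0, depth_mm)
      cx <- runif(n_cl, 0, width_mm)
      move <- which(runif(n) < cluster_fraction)
      pick <- sample.int(n_cl, length(move), replace = TRUE)
      z[move] <- cz[pick] + rnorm(length(move), 0, cluster_sd_mm)
      x[move] <- cx[pick] + rnorm(length(move), 0, cluster_sd_mm)
    }
    a <- rnorm(n, 0, amplitude_sd)
    if (spacing_mode == "quasi_periodic")
      a <- a + coherent_amplitude * amplitude_sd
    keep <- z > 0 & z < depth_mm & x > 0 & x < width_mm
    z <- z[keep]; x <- x[keep]; a <- a[keep]
  }
  structure(list(z_mm = z, x_mm = x, amplitude = a,
                 depth_mm = depth_mm, width_mm = width_mm,
                 number_density = number_density,
                 effective_radius_um = effective_radius_um,
                 spacing_mode = spacing_mode, period_mm = period_mm,
                 seed = seed),
            class = "scatterer_field")
}

#' @export
print.scatterer_field <- function(x, ...) {
  cat(sprintf("<scatterer_field> %d scatterers in %.1f x %.1f mm (%s), a_eff = %g um\n",
              length(x$z_mm), x$depth_mm, x$width_mm, x$spacing_mode,
              x$effective_radius_um))
  invisible(x)
}

# Save/restore the global RNG state so generators are pure functions of their
# seed without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
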
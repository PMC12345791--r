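# QUS parameter estimators: linear spectral fit, Gaussian form-factor
# ASD/AAC, spacing (SAS), spectral-difference attenuation, map assembly.

test_that("linear fit is exact on noiseless lines", {
  f <- seq(3, 8.5, by = 0.1)
  fit <- fit_linear_spectrum(make_ns(f, 2 * f + 3))
  expect_equal(fit$SS, 2, tolerance = 1e-10)
  expect_equal(fit$SI, 3, tolerance = 1e-10)
  expect_equal(fit$MBF, 3 + 2 * 5.75, tolerance = 1e-10)

  flat <- fit_linear_spectrum(make_ns(f, rep(7, length(f))))
  expect_equal(unlist(flat[c("SS", "SI", "MBF")]),
               c(SS = 0, SI = 7, MBF = 7), tolerance = 1e-10)
  expect_error(fit_linear_spectrum(make_ns(f[1:2], c(1, 2))), "3 frequency")
})

test_that("MBF = SI + SS * f_c holds to machine precision on random spectra", {
  set.seed(21)
  f <- seq(3, 8.5, by = 0.14)
  for (i in 1:50) {
    fit <- fit_linear_spectrum(make_ns(f, rnorm(length(f), 0, 5)))
    expect_equal(fit$MBF, fit$SI + fit$SS * fit$f_centre, tolerance = 1e-12)
  }
})

test_that("noisy-line slope lands in its 95% least-squares CI >= 93% of runs", {
  f <- seq(3, 8.5, length.out = 50)
  X <- cbind(1, f)
  covered <- vapply(1:1000, function(s) {
    set.seed(s)
    y <- 1.8 * f - 4 + rnorm(50, 0, 1)
    fit <- fit_linear_spectrum(make_ns(f, y))
    res <- y - (fit$SI + fit$SS * f)
    se <- sqrt(sum(res^2) / 48 * solve(crossprod(X))[2, 2])
    abs(fit$SS - 1.8) <= qt(0.975, 48) * se
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("ASD/AAC invert the Gaussian form-factor model (inverse crime)", {
  f <- seq(3, 8.5, by = 0.1)
  c_mmus <- 1.54
  for (asd_um in c(60, 100, 150)) {
    a_mm <- asd_um / 2000
    ns <- make_ns(f, 12 + 40 * log10(f) -
                    (10 / log(10)) * 0.827 * (2 * pi * f / c_mmus)^2 * a_mm^2)
    est <- estimate_asd_aac(ns)
    expect_lt(abs(est$ASD - asd_um) / asd_um, 0.05)
    expect_equal(est$AAC, 12, tolerance = 1e-6)
  }
  # point scatterers: form factor -> 1, slope ~ 0, ASD ~ 0
  est0 <- estimate_asd_aac(make_ns(f, 5 + 40 * log10(f)))
  expect_lt(abs(est0$ASD), 1e-3)
  # unphysical positive slope: ASD invalid, AAC still reported
  estp <- estimate_asd_aac(make_ns(f, 5 + 40 * log10(f) + 0.5 * f^2))
  expect_true(is.na(estp$ASD))
  expect_false(estp$valid)
  expect_true(is.finite(estp$AAC))
})

test_that("SAS recovers quasi-periodic spacings and nulls diffuse media", {
  p <- pulse_model()
  cfgL <- spectral_config(window_length_mm = 12, window_lines = 11)
  probe <- function(mode, d, seed) {
    fld <- scatterer_field(depth_mm = 30, width_mm = 8, number_density = 6,
                           spacing_mode = mode, period_mm = d, seed = seed)
    estimate_sas(probe_ns(fld, p, ref_seed = seed + 500, config = cfgL,
                          axial_start = round(2 * 8 / 1.54 * 40), n_lines = 34))
  }
  for (d in c(0.5, 1.0)) {
    est <- lapply(1:5, function(s) probe("quasi_periodic", d, s))
    sas <- vapply(est, function(e) e$SAS, 0)
    det <- !is.na(sas)
    expect_gte(sum(det), 3)
    # tolerance: one frequency-grid lag around the true ripple period
    tol <- d - 1.54 / (2 * (1.54 / (2 * d) + 0.0309))
    for (v in sas[det]) expect_lt(abs(v - d), max(tol, 0.05))
  }
  nulls <- vapply(1:20, function(s) is.na(probe("random", 1, s + 40)$SAS), TRUE)
  expect_gte(mean(nulls), 0.9)
  expect_error(estimate_sas(make_ns(seq(3, 4, by = 0.2), rnorm(6))),
               "unresolvable")
})

test_that("attenuation estimator: zero, recovery, monotonicity, guards", {
  p <- pulse_model()
  est_alpha <- function(alpha, seed) {
    scan <- simulate_rf_scan(list(depth_mm = 40, width_mm = 9,
                                  number_density = 10), p,
                             attenuation = alpha, n_planes = 1, seed = seed,
                             n_lines = 39, n_strata = 16)
    ref <- simulate_reference_phantom(p, 1, 0, depth_mm = 40, width_mm = 9,
                                      n_lines = 39, n_planes = 1,
                                      seed = seed + 70)
    roi <- matrix(TRUE, nrow(scan$frames[[1]]$rf), 39)
    roi[c(1:220, 1850:2078), ] <- FALSE
    m <- build_parametric_maps(scan, roi, spectral_config(), ref)
    m$attenuation$alpha_signed
  }
  a0 <- mean(vapply(1:3, function(s) est_alpha(0, s), 0))
  expect_lt(abs(a0), 0.1)
  a1 <- mean(vapply(1:4, function(s) est_alpha(0.35, s + 10), 0))
  a2 <- mean(vapply(1:4, function(s) est_alpha(0.7, s + 10), 0))
  expect_lt(abs(a2 - 0.7) / 0.7, 0.15)
  expect_lt(abs(a2 / a1 - 2), 0.4)
  expect_error(estimate_attenuation(matrix(0, 10, 2), c(1, 2),
                                    seq(3, 8, length.out = 10)),
               "3 depth strata")
})

test_that("map assembly: homogeneity, contrast recovery, mask guards", {
  p <- pulse_model()
  cfg <- spectral_config()
  ref <- simulate_reference_phantom(p, 1, 0, depth_mm = 24, width_mm = 20,
                                    n_lines = 87, n_planes = 2, seed = 31)
  # homogeneous medium: map spread bounded by speckle
  fld <- scatterer_field(depth_mm = 24, width_mm = 20, number_density = 10,
                         seed = 8)
  scan <- rf_scan(list(simulate_rf_frame(fld, p, n_lines = 87)))
  roi <- matrix(FALSE, nrow(scan$frames[[1]]$rf), 87)
  roi[300:1000, 10:78] <- TRUE
  maps <- build_parametric_maps(scan, roi, cfg, ref)
  mbf <- maps$maps[[1]]$MBF$values
  expect_lt(sd(mbf[!is.na(mbf)]), 2)
  expect_identical(names(maps$means), qus_param_names())

  # two-region medium: doubled concentration raises MBF by ~3 dB
  fld2 <- scatterer_field(depth_mm = 24, width_mm = 20, number_density = 10,
                          seed = 9)
  right <- fld2$x_mm > 10
  fld_lo <- fld2; fld_lo$z_mm <- fld2$z_mm[!right]
  fld_lo$x_mm <- fld2$x_mm[!right]; fld_lo$amplitude <- fld2$amplitude[!right]
  extra <- scatterer_field(depth_mm = 24, width_mm = 20, number_density = 10,
                           seed = 10)
  keep <- extra$x_mm > 10
  fld2$z_mm <- c(fld2$z_mm, extra$z_mm[keep])
  fld2$x_mm <- c(fld2$x_mm, extra$x_mm[keep])
  fld2$amplitude <- c(fld2$amplitude, extra$amplitude[keep])
  scan2 <- rf_scan(list(simulate_rf_frame(fld2, p, n_lines = 87)))
  maps2 <- build_parametric_maps(scan2, roi, cfg, ref)
  m2 <- maps2$maps[[1]]$MBF
  lat_mm <- (seq_len(ncol(m2$values)) - 1) * m2$pixel_spacing_mm[2] +
    m2$origin_mm[2]
  left_mean <- mean(m2$values[, lat_mm < 9], na.rm = TRUE)
  right_mean <- mean(m2$values[, lat_mm > 11], na.rm = TRUE)
  expect_lt(abs((right_mean - left_mean) - 3.01), 1)

  expect_error(build_parametric_maps(scan, matrix(FALSE, nrow(scan$frames[[1]]$rf), 87),
                                     cfg, ref), "empty")
  tiny <- matrix(FALSE, nrow(scan$frames[[1]]$rf), 87)
  tiny[2, 2] <- TRUE
  expect_error(build_parametric_maps(scan, tiny, cfg, ref), "smaller than one")
})
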
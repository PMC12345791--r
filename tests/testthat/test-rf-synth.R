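# Synthetic RF generator: geometry, determinism, incoherent power scaling,
# cohort label contracts.

test_that("empty field gives a flagged all-zero frame; Nyquist guard trips", {
  p <- pulse_model()
  fld <- scatterer_field(depth_mm = 10, width_mm = 4, number_density = 0)
  fr <- simulate_rf_frame(fld, p, n_lines = 17)
  expect_true(all(fr$rf == 0))
  expect_true(isTRUE(attr(fr, "empty_field")))
  expect_error(pulse_model(centre_frequency = 6.5, sampling_rate = 20),
               "Nyquist")
})

test_that("single scatterer echoes at the round-trip sample index", {
  p <- pulse_model()
  fld <- scatterer_field(depth_mm = 20, width_mm = 5, number_density = 0)
  for (z in c(5, 10, 14.3)) {
    fld$z_mm <- z; fld$x_mm <- 2.5; fld$amplitude <- 1
    fr <- simulate_rf_frame(fld, p, n_lines = 21)
    peak <- which.max(apply(abs(fr$rf), 1, max))
    expect_equal(peak, round(2 * z / 1.54 * 40) + 1, tolerance = 0,
                 info = paste("z =", z))
  }
})

test_that("frames are a pure function of the field (determinism)", {
  p <- pulse_model()
  f1 <- scatterer_field(depth_mm = 10, width_mm = 4, number_density = 8,
                        seed = 3)
  f2 <- scatterer_field(depth_mm = 10, width_mm = 4, number_density = 8,
                        seed = 3)
  expect_identical(f1$z_mm, f2$z_mm)
  expect_identical(simulate_rf_frame(f1, p, n_lines = 17)$rf,
                   simulate_rf_frame(f2, p, n_lines = 17)$rf)
})

test_that("doubling scatterer concentration doubles backscattered power", {
  # incoherent scattering: mean power linear in concentration, so the shift
  # is +3.01 dB over many independent realizations
  p <- pulse_model()
  pow <- function(dens, seed) {
    fld <- scatterer_field(depth_mm = 10, width_mm = 4,
                           number_density = dens, seed = seed)
    mean(simulate_rf_frame(fld, p, n_lines = 17)$rf^2)
  }
  p1 <- vapply(1:100, function(s) pow(5, s), 0)
  p2 <- vapply(1:100, function(s) pow(10, s + 1000), 0)
  shift <- 10 * log10(mean(p2) / mean(p1))
  expect_lt(abs(shift - 3.01), 0.5)
})

test_that("reference phantom validates backscatter and reproduces by seed", {
  p <- pulse_model()
  expect_error(simulate_reference_phantom(p, known_bsc = -1), "positive")
  r1 <- simulate_reference_phantom(p, 1, 0, depth_mm = 10, width_mm = 4,
                                   n_lines = 17, n_planes = 1, seed = 5)
  r2 <- simulate_reference_phantom(p, 1, 0, depth_mm = 10, width_mm = 4,
                                   n_lines = 17, n_planes = 1, seed = 5)
  expect_identical(r1$frames[[1]]$rf, r2$frames[[1]]$rf)
  # two phantoms differing only by seed: band-averaged spectra agree within
  # speckle tolerance once averaged over many windows
  r3 <- simulate_reference_phantom(p, 1, 0, depth_mm = 30, width_mm = 14,
                                   n_lines = 60, n_planes = 1, seed = 6)
  r4 <- simulate_reference_phantom(p, 1, 0, depth_mm = 30, width_mm = 14,
                                   n_lines = 60, n_planes = 1, seed = 7)
  cfg <- spectral_config()
  band_mean <- function(scan) {
    g <- expand.grid(ax = seq(200, 1300, by = 130), lat = seq(1, 49, by = 6))
    mean(vapply(seq_len(nrow(g)), function(i) {
      s <- compute_power_spectrum(scan$frames[[1]], g$ax[i], g$lat[i], cfg)
      mean(s$power[s$frequencies >= 3 & s$frequencies <= 8.5])
    }, 0))
  }
  expect_lt(abs(band_mean(r3) - band_mean(r4)), 0.5)
})

test_that("cohort label counts are exact and seeds reproduce cohorts", {
  cc <- cohort_config(n_patients = 100, nonresponder_fraction = 0.19)
  expect_identical(sum(cohort_labels(cc) == "NR"), 19L)   # 81 R / 19 NR
  cc2 <- cohort_config(n_patients = 51, nonresponder_fraction = 0.12)
  expect_identical(sum(cohort_labels(cc2) == "NR"), 6L)  # round(51 * 0.12)
  expect_warning(cohort_labels(cohort_config(n_patients = 3,
                                             nonresponder_fraction = 0.1)),
                 "single-class")

  small_geom <- list(depth_mm = 12, width_mm = 16, n_planes = 1)
  cc3 <- cohort_config(n_patients = 2, nonresponder_fraction = 0.5,
                       geometry = small_geom,
                       roi = list(semi_axial_mm = 3, semi_lateral_mm = 7.5,
                                  centre_depth_mm = 6), seed = 4)
  coh_a <- simulate_cohort(cc3)
  coh_b <- simulate_cohort(cc3)
  expect_identical(coh_a[[1]]$rf_week0$frames[[1]]$rf,
                   coh_b[[1]]$rf_week0$frames[[1]]$rf)
  expect_identical(coh_a[[2]]$rf_week1$frames[[1]]$rf,
                   coh_b[[2]]$rf_week1$frames[[1]]$rf)
  expect_identical(attr(coh_a, "labels"), attr(coh_b, "labels"))
  # timepoints share ROI topology
  expect_identical(coh_a[[1]]$roi, coh_b[[1]]$roi)
})

test_that("null feature generator yields uniform p-values across seeds", {
  pvals <- vapply(1:200, function(s) {
    d <- simulate_delta_features(n_patients = 40, nonresponder_fraction = 0.3,
                                 effect = 0, seed = s)
    t.test(d[d$label == "R", "MBF-mean"], d[d$label == "NR", "MBF-mean"])$p.value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
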
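# Independent oracles used across the suite.  These deliberately use naive
# enumeration / direct formulas, not the package's vectorized code paths.

# brute-force GLCM by explicit pair enumeration
glcm_oracle <- function(q, n_levels, offset, symmetric = TRUE) {
  counts <- matrix(0, n_levels, n_levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    a <- q[i, j]; b <- q[i2, j2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# direct-formula texture features
texture_oracle <- function(p, hom_sq = FALSE) {
  n <- nrow(p)
  con <- 0; hom <- 0; ene <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  s_i <- 0; s_j <- 0; cross <- 0
  for (i in 1:n) for (j in 1:n) {
    con <- con + p[i, j] * (i - j)^2
    hom <- hom + p[i, j] / (1 + if (hom_sq) (i - j)^2 else abs(i - j))
    ene <- ene + p[i, j]^2
    s_i <- s_i + (i - mu_i)^2 * p[i, j]
    s_j <- s_j + (j - mu_j)^2 * p[i, j]
    cross <- cross + (i - mu_i) * (j - mu_j) * p[i, j]
  }
  cor <- if (s_i <= 0 || s_j <= 0) 1 else cross / sqrt(s_i * s_j)
  c(CON = con, COR = cor, HOM = hom, ENE = ene)
}

# O(n^2) pairwise concordance AUC (ties count 1/2)
auc_oracle <- function(scores, truths) {
  pos <- which(truths == "NR"); neg <- which(truths == "R")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# construct a normalized_spectrum by hand (for estimator unit tests)
make_ns <- function(f, vals, band = range(f), t_support_us = NULL) {
  structure(list(frequencies = f, ns = vals,
                 window_centre = list(axial_mm = 20, lateral_mm = 10),
                 band = band, t_support_us = t_support_us),
            class = "normalized_spectrum")
}

# construct a window_spectrum by hand
make_ws <- function(f, power_db, band = range(f), depth_mm = 20) {
  structure(list(frequencies = f, power = power_db,
                 window_centre = list(axial_mm = depth_mm, lateral_mm = 10),
                 band = band, t_support_us = NULL),
            class = "window_spectrum")
}

# random masked map for texture property tests
random_masked_map <- function(seed, max_dim = 16) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1); nc <- sample(4:max_dim, 1)
  m <- matrix(rnorm(nr * nc), nr, nc)
  m[matrix(runif(nr * nc) < 0.2, nr, nc)] <- NA
  if (all(is.na(m))) m[1:2, 1:2] <- rnorm(4)
  m
}

# small standard probe: one tissue frame + phantom reference spectrum pair
probe_ns <- function(field, pulse = pulse_model(), ref_seed = 901,
                     config = spectral_config(), axial_start = NULL,
                     line_start = 6, attenuation = 0, n_lines = NULL) {
  if (is.null(n_lines)) n_lines <- max(1L, round(field$width_mm / 0.23))
  fr <- simulate_rf_frame(field, pulse, attenuation = attenuation,
                          n_lines = n_lines)
  ref <- simulate_reference_phantom(pulse, 1, 0, depth_mm = field$depth_mm,
                                    width_mm = field$width_mm,
                                    n_lines = n_lines, n_planes = 1,
                                    seed = ref_seed)
  if (is.null(axial_start))
    axial_start <- round(nrow(fr$rf) / 3)
  s <- compute_power_spectrum(fr, axial_start, line_start, config)
  r <- compute_power_spectrum(ref$frames[[1]], axial_start, line_start, config)
  normalize_spectrum(s, r, alpha_sample = attenuation, alpha_ref = 0)
}
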
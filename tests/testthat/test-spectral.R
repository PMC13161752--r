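# Welch estimation and the periodic/distribution features

test_that("Welch grid, sinusoid power and Parseval behave as specified", {
  fs <- 250
  ps <- welch_psd(rnorm(30 * fs), fs)
  expect_equal(ps$resolution, 0.25)
  expect_equal(ps$freqs[1:3], c(0, 0.25, 0.5))
  # pure sinusoid: band power around the tone is A^2/2
  A <- 3
  t <- seq(0, 30, length.out = 30 * fs + 1)[-1]
  ps2 <- welch_psd(A * sin(2 * pi * 10 * t), fs)
  expect_equal(band_power(ps2, 9.5, 10.5), A^2 / 2,
               tolerance = 0.02 * A^2 / 2)
  # white noise: integrated density recovers the variance
  x <- with_seed_local(2, rnorm(60 * fs, sd = 2))
  ps3 <- welch_psd(x, fs)
  expect_equal(band_power(ps3, 0, 125), var(x), tolerance = 0.05 * var(x))
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("band power integrates exactly on analytic spectra", {
  flat <- power_spectrum(seq(0.25, 45, 0.25), rep(1, 180))
  expect_equal(band_power(flat, 4, 8), 4)
  # f^-2 on a fine grid: closed form 1/4 - 1/8
  f <- seq(0.5, 45, by = 0.005)
  ps <- power_spectrum(f, f^-2)
  expect_equal(band_power(ps, 4, 8), 0.125, tolerance = 0.001 * 0.125)
  # five canonical bands tile the total range exactly
  bands <- canonical_bands()
  parts <- vapply(seq_len(nrow(bands)), function(b) {
    band_power(ps, bands$lo[b], bands$hi[b])
  }, numeric(1))
  expect_equal(sum(parts), band_power(ps, 0.5, 30), tolerance = 1e-12)
  expect_error(band_power(flat, 8, 4), "lo < hi")
})

test_that("relative powers and ratios on a flat spectrum match geometry", {
  flat <- power_spectrum(seq(0.25, 45, 0.25), rep(1, 180))
  rp <- relative_powers_and_ratios(flat)
  expect_equal(unname(rp["Delta_Rel"]), 3.5 / 29.5, tolerance = 1e-9)
  expect_equal(unname(rp["Theta_Rel"]), 4 / 29.5, tolerance = 1e-9)
  expect_equal(sum(rp[1:5]), 1, tolerance = 1e-9)
  expect_equal(unname(rp["Theta_Alpha_Ratio"]), 4 / 5, tolerance = 1e-9)
  expect_equal(unname(rp["Beta_Delta_Ratio"]), 12 / 3.5, tolerance = 1e-9)
})

test_that("stored ratios equal quotients of stored fractions on real epochs", {
  sp <- draw_subject(default_presets()$sevoflurane, "s1", seed = 2)
  for (i in 1:5) {
    rp <- relative_powers_and_ratios(
      welch_psd(synth_epoch_signal(sp, seed = 700 + i), 250))
    expect_equal(sum(rp[1:5]), 1, tolerance = 1e-9)
    expect_equal(unname(rp["Theta_Alpha_Ratio"] * rp["Alpha_Delta_Ratio"]),
                 unname(rp["Theta_Delta_Ratio"]), tolerance = 1e-9)
    expect_equal(unname(rp["Beta_Alpha_Ratio"]),
                 unname(rp["Beta_Rel"] / rp["Alpha_Rel"]), tolerance = 1e-9)
  }
})

test_that("spectral edges interpolate the cumulative power", {
  flat <- power_spectrum(seq(0.25, 45, 0.25), rep(1, 180))
  expect_equal(spectral_edge(flat, 0.5), 15.25)
  expect_equal(spectral_edge(flat, 0.95), 28.525)
  expect_equal(spectral_edge(flat, 1), 30)
  # f^-2: closed-form median frequency 1/(2 - 0.5*(2 - 1/30))
  f <- seq(0.5, 45, by = 0.005)
  ps <- power_spectrum(f, f^-2)
  expect_equal(spectral_edge(ps, 0.5), 0.98361, tolerance = 1e-3)
  expect_lte(spectral_edge(ps, 0.5), spectral_edge(ps, 0.95))
})

test_that("alpha peak refinement follows the three-point parabola", {
  f <- seq(0.25, 45, 0.25)
  d <- rep(0.5, length(f))
  d[f == 10.25] <- 1.2
  d[f == 10.0] <- 1.0
  d[f == 10.5] <- 1.1
  ps <- power_spectrum(f, d)
  # vertex: delta = 0.5 (y- - y+) / (y- - 2 y0 + y+) = 1/6 bin
  expect_equal(alpha_peak(ps), 10.25 + 0.25 / 6, tolerance = 1e-9)
  # symmetric neighbors: no shift
  d2 <- rep(0.5, length(f)); d2[f == 10.25] <- 1.2
  d2[f == 10.0] <- d2[f == 10.5] <- 1.0
  expect_equal(alpha_peak(power_spectrum(f, d2)), 10.25)
  # ties break toward the lower frequency
  d3 <- rep(0.5, length(f)); d3[f == 9] <- d3[f == 11] <- 2
  expect_lte(alpha_peak(power_spectrum(f, d3)), 9)
})

test_that("alpha bandwidth uses the fitted FWHM with a 5-Hz clip", {
  mk_model <- function(peaks) {
    structure(list(peaks = peaks,
                   freqs = seq(1, 30, 0.25),
                   log_psd = -2 * log10(seq(1, 30, 0.25)),
                   aperiodic_line = -2 * log10(seq(1, 30, 0.25))),
              class = "spectral_model")
  }
  m1 <- mk_model(list(list(center = 10, height = 0.5, sd = 1.0)))
  expect_equal(alpha_bandwidth(m1), 2 * sqrt(2 * log(2)), tolerance = 1e-9)
  m2 <- mk_model(list(list(center = 10, height = 0.5, sd = 3.0)))
  expect_equal(alpha_bandwidth(m2), 5)
  # pure power law, no alpha peak: fallback is finite and within the band
  f <- seq(0.25, 45, 0.25)
  m3 <- parameterize_spectrum(power_spectrum(f, 10 * f^-2))
  bw <- alpha_bandwidth(m3)
  expect_true(is.finite(bw) && bw > 0 && bw <= 5)
})

test_that("spectral entropy matches closed forms", {
  f <- seq(0.25, 45, 0.25)
  nbins <- sum(f >= 0.5 & f <= 30)
  expect_equal(spectral_entropy(power_spectrum(f, rep(2, length(f)))),
               log(nbins), tolerance = 1e-12)
  one <- rep(0, length(f)); one[f == 10] <- 5
  expect_equal(spectral_entropy(power_spectrum(f, one)), 0)
  two <- rep(0, length(f)); two[f == 10] <- 0.75; two[f == 12] <- 0.25
  expect_equal(spectral_entropy(power_spectrum(f, two)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
})

test_that("feature vectors have 17 finite values in fixed order", {
  sp <- draw_subject(default_presets()$propofol, "s1", seed = 1, fixed = TRUE)
  e <- synth_epoch_signal(sp, seed = 12)
  fv <- extract_feature_vector(e, 250)
  expect_named(fv, feature_names())
  expect_length(fv, 17)
  expect_true(all(is.finite(fv)))
  expect_equal(extract_feature_vector(e, 250), fv) # idempotent
  expect_true(fv["Peak_Freq"] >= 8 && fv["Peak_Freq"] <= 13)
  expect_true(fv["SEF50"] <= fv["SEF95"])
})

test_that("adding theta power raises Theta_Rel and lowers every other band", {
  f <- seq(0.25, 45, 0.25)
  base <- 10 * f^-1.5
  bump <- ifelse(f > 4 & f < 8, 5 * dnorm(f, 6, 0.5), 0)
  r0 <- relative_powers_and_ratios(power_spectrum(f, base))
  r1 <- relative_powers_and_ratios(power_spectrum(f, base + bump))
  expect_gt(r1["Theta_Rel"], r0["Theta_Rel"])
  for (nm in c("Delta_Rel", "Alpha_Rel", "Beta_Rel", "Gamma_Rel")) {
    expect_lt(r1[nm], r0[nm])
  }
})
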
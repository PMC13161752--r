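# Synthetic cohort generator: subject draws, spectral shaping, artifacts

test_that("fixed-mode subject draws sit exactly at preset means", {
  pr <- default_presets()$sevoflurane
  sp <- draw_subject(pr, "s1", seed = 3, fixed = TRUE)
  expect_equal(sp$aperiodic$exponent, pr$exponent_mean)
  expect_equal(sp$aperiodic$offset, pr$offset_mean)
  expect_equal(sp$peaks$alpha$center_hz, pr$alpha_center_mean)
})

test_that("subject draws are deterministic given the seed", {
  pr <- default_presets()$propofol
  a <- draw_subject(pr, "s1", seed = 11)
  b <- draw_subject(pr, "s1", seed = 11)
  expect_identical(a, b)
  c <- draw_subject(pr, "s1", seed = 12)
  expect_false(identical(a$aperiodic, c$aperiodic))
})

test_that("drawn exponents match truncated-normal moments", {
  pr <- default_presets()$propofol
  draws <- vapply(1:3000, function(i) {
    draw_subject(pr, "s", seed = i)$aperiodic$exponent
  }, numeric(1))
  # truncated-normal mean (lower truncation at 0.5), closed form
  a <- (0.5 - pr$exponent_mean) / pr$exponent_sd
  mu_tr <- pr$exponent_mean + pr$exponent_sd * dnorm(a) / (1 - pnorm(a))
  se <- pr$exponent_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_tr), 3 * se)
  expect_true(all(draws >= 0.5))
})

test_that("a flat band-limited spectrum obeys Parseval", {
  # near-white background, no peaks: variance ~ c * (45 - 0.5)
  sp <- list(aperiodic = aperiodic_params(0, 0.01), peaks = list())
  x <- synth_epoch_signal(sp, n_samples = 250 * 300, fs = 250, seed = 5)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_equal(var(x), 44.5, tolerance = 0.05 * 44.5)
})

test_that("a long realization's Welch PSD tracks the analytic model", {
  sp <- draw_subject(default_presets()$propofol, "s1", seed = 1, fixed = TRUE)
  x <- synth_epoch_signal(sp, n_samples = 250 * 300, fs = 250, seed = 2)
  ps <- welch_psd(x, 250)
  sel <- ps$freqs >= 1 & ps$freqs <= 30
  S <- model_psd(ps$freqs[sel], sp$aperiodic, sp$peaks)
  expect_lt(max(abs(log10(ps$density[sel] / S))), 0.05)
})

test_that("epoch synthesis is bit-identical under the same seed", {
  sp <- draw_subject(default_presets()$propofol, "s1", seed = 1, fixed = TRUE)
  expect_identical(synth_epoch_signal(sp, seed = 9),
                   synth_epoch_signal(sp, seed = 9))
})

test_that("mean epoch PSD matches analytic band powers within 3%", {
  sp <- draw_subject(default_presets()$sevoflurane, "s1", seed = 1,
                     fixed = TRUE)
  dens <- NULL
  for (i in 1:200) {
    w <- welch_psd(synth_epoch_signal(sp, seed = 5000 + i), 250)
    dens <- if (is.null(dens)) w$density else dens + w$density
  }
  ps <- power_spectrum(w$freqs, dens / 200)
  bands <- canonical_bands()
  for (b in seq_len(nrow(bands))) {
    est <- band_power(ps, bands$lo[b], bands$hi[b])
    truth <- oracle_band_power(function(f) model_psd(f, sp$aperiodic, sp$peaks),
                               bands$lo[b], bands$hi[b])
    expect_lt(abs(est - truth) / truth, 0.03)
  }
})

test_that("artifact injection scales, labels and counts behave", {
  sp <- draw_subject(default_presets()$propofol, "s1", seed = 1, fixed = TRUE)
  epochs <- t(vapply(1:20, function(i) synth_epoch_signal(sp, seed = i),
                     numeric(7500)))
  # rate 0: untouched
  out0 <- inject_artifacts(epochs, 0, seed = 1)
  expect_identical(out0$epochs, epochs)
  expect_true(all(out0$labels == "clean"))
  # dropout power scaling is exactly 0.02^2
  out <- inject_artifacts(epochs, 0.45, seed = 2)
  drop <- which(out$labels == "dropout")
  expect_gt(length(drop), 0)
  for (i in drop) {
    expect_equal(sum(out$epochs[i, ]^2), 4e-4 * sum(epochs[i, ]^2),
                 tolerance = 1e-12)
  }
  # corrupted count within 3-sigma binomial bounds at the default rate
  big <- matrix(rnorm(1000 * 100), 1000)
  outb <- inject_artifacts(big, 0.034, seed = 3)
  n_bad <- sum(outb$labels != "clean")
  expect_gte(n_bad, 17)
  expect_lte(n_bad, 51)
})

test_that("cohort generation is reproducible and correctly shaped", {
  coh <- variable_cohort()
  expect_s3_class(coh, "eeg_cohort")
  expect_length(coh$recordings, 40)
  expect_equal(nrow(coh$ground_truth$artifact_labels), 1200)
  groups <- vapply(coh$recordings, `[[`, character(1), "group")
  expect_equal(unname(table(groups)[c("propofol", "sevoflurane")]),
               c(20L, 20L), ignore_attr = TRUE)
  # ground-truth group labels match the recordings
  for (sid in names(coh$recordings)) {
    expect_equal(coh$ground_truth$subjects[[sid]]$group,
                 coh$recordings[[sid]]$group)
  }
  coh2 <- generate_cohort(seed = coh$seed)
  expect_identical(coh$ground_truth, coh2$ground_truth)
})

test_that("cohorts round-trip to plain-text files", {
  coh <- generate_cohort(seed = 3, n_subjects = 2, epochs_per_subject = 2)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  sid <- names(coh$recordings)[1]
  sig <- as.matrix(read.csv(file.path(d, paste0(sid, "_signal.csv")),
                            header = FALSE))
  expect_equal(dim(sig), dim(coh$recordings[[sid]]$signal))
  expect_equal(unname(sig[1, 1:5]), coh$recordings[[sid]]$signal[1, 1:5],
               tolerance = 1e-5)
})
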
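#' Synthetic maintenance-phase EEG cohorts
#'
#' The generator realizes per-subject spectral parameters from a
#' [group_preset()], synthesizes 30-s epochs whose expected one-sided PSD
#' equals the analytic model spectrum exactly (inverse-FFT spectral shaping
#' with uniform random phases, band-limited to 0.5--45 Hz), injects dropout
#' and electrocautery artifact epochs, and records complete ground truth for
#' parameter-recovery tests.
#'
#' @name synth
NULL

# Truncated-normal draw by rejection; sd = 0 returns the mean (clamped).
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lower && v <= upper) return(v)
  }
}

#' Realize one subject's generator parameters from a preset
#'
#' Draws the subject's aperiodic background (exponent truncated below at 0.5,
#' offset normal) and alpha peak center (truncated to 8--13 Hz), then
#' recalibrates the four peak powers against the drawn background so the
#' subject's analytic band fractions still hit the preset targets. With
#' `fixed = TRUE` every parameter sits at the preset mean (all SDs treated
#' as zero).
#'
#' @param preset a [group_preset()].
#' @param subject_id subject identifier (string or integer).
#' @param seed integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @param fixed logical; if `TRUE`, no between-subject variation.
#' @param n_epochs number of 30-s epochs for this subject (default from
#'   preset).
#' @return A `subject_gen_params` object.
#' @export
draw_subject <- function(preset, subject_id, seed = NULL, fixed = FALSE,
                         n_epochs = preset$epochs_per_subject) {
  with_seed(seed, {
    esd <- if (fixed) 0 else preset$exponent_sd
    osd <- if (fixed) 0 else preset$offset_sd
    asd <- if (fixed) 0 else preset$alpha_center_sd
    exponent <- rtruncnorm1(preset$exponent_mean, esd, lower = 0.5)
    offset <- if (osd == 0) preset$offset_mean else
      stats::rnorm(1, preset$offset_mean, osd)
    alpha_c <- rtruncnorm1(preset$alpha_center_mean, asd,
                           lower = 8, upper = 13)
    bg <- aperiodic_params(offset, exponent)
    peaks <- list(
      slow  = peak_spec(preset$slow_center_hz, preset$slow_sd_hz),
      theta = peak_spec(preset$theta_center_hz, preset$theta_sd_hz),
      alpha = peak_spec(alpha_c, preset$alpha_sd_hz),
      beta  = peak_spec(preset$beta_center_hz, preset$beta_sd_hz)
    )
    # Best-effort calibration (tol = Inf): extreme aperiodic draws can make
    # the exact group-mean band fractions geometrically unattainable with
    # nonnegative peak powers; such subjects keep the closest achievable
    # fractions, which is itself realistic between-subject variation.
    # Fixed-mode draws sit at the preset means, where calibration is exact.
    peaks <- calibrate_peak_powers(bg, peaks, preset$target_rel_powers,
                                   tol = Inf)
    structure(list(
      subject_id = subject_id,
      group = preset$name,
      aperiodic = bg,
      peaks = peaks,
      n_epochs = n_epochs,
      seed = seed
    ), class = "subject_gen_params")
  })
}

#' Synthesize one epoch of EEG by spectral shaping
#'
#' Builds a complex half-spectrum with deterministic amplitudes
#' \eqn{\sqrt{S(f_k)\, f_s\, n / 2}} and i.i.d. uniform random phases on the
#' bins falling in 0.5--45 Hz (zero outside), Hermitian-symmetrizes and
#' inverse-transforms. Every realization's full-length periodogram equals the
#' model PSD exactly on the synthesis grid, so the expected Welch PSD equals
#' \eqn{S(f)} up to window smoothing.
#'
#' @param params a `subject_gen_params` (or any list with `aperiodic` and
#'   `peaks`).
#' @param n_samples samples per epoch (default 7500 = 30 s at 250 Hz); even.
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric signal vector, uV, zero-mean.
#' @export
synth_epoch_signal <- function(params, n_samples = 7500, fs = 250,
                               seed = NULL) {
  stopifnot(n_samples %% 2 == 0, fs > 90)
  with_seed(seed, {
    nf <- n_samples / 2
    freqs <- (1:nf) * fs / n_samples
    S <- model_psd(freqs, params$aperiodic, params$peaks)
    S[freqs < 0.5 | freqs > 45] <- 0
    # continuous roll-off below the band edge (half-cosine down to 0.25 Hz):
    # a hard spectral cliff at 0.5 Hz would smear into the delta band under
    # the Welch window and bias its measured power
    tap <- freqs >= 0.25 & freqs < 0.5
    S[tap] <- model_psd(0.5, params$aperiodic, params$peaks) *
      0.5 * (1 - cos(pi * (freqs[tap] - 0.25) / 0.25))
    amp <- sqrt(S * fs * n_samples / 2)
    phases <- stats::runif(nf, 0, 2 * pi)
    Xpos <- amp * exp(1i * phases)
    Xpos[nf] <- Re(Xpos[nf]) # Nyquist bin must be real
    X <- c(0 + 0i, Xpos, Conj(rev(Xpos[-nf])))
    Re(stats::fft(X, inverse = TRUE)) / n_samples
  })
}

#' Inject dropout and electrocautery artifacts into an epoch set
#'
#' Each epoch is independently corrupted with probability `rate`; a corrupted
#' epoch becomes, with equal probability, a signal dropout (amplitude scaled
#' by 0.02, emulating a lead-off) or an electrocautery burst (added white
#' noise with SD equal to 30 times the session's median epoch RMS).
#'
#' @param epochs numeric matrix, epochs x samples.
#' @param rate corruption probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @return List with `epochs` (modified matrix) and `labels` (character
#'   vector: `"clean"`, `"dropout"`, `"cautery"`).
#' @export
inject_artifacts <- function(epochs, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 0.5)
  with_seed(seed, {
    n <- nrow(epochs)
    labels <- rep("clean", n)
    if (rate > 0 && n > 0) {
      rms <- apply(epochs, 1, function(x) sqrt(mean(x^2)))
      med_rms <- stats::median(rms)
      hit <- stats::runif(n) < rate
      kind <- stats::runif(n) < 0.5
      for (i in which(hit)) {
        if (kind[i]) {
          epochs[i, ] <- epochs[i, ] * 0.02
          labels[i] <- "dropout"
        } else {
          epochs[i, ] <- epochs[i, ] +
            stats::rnorm(ncol(epochs), 0, 30 * med_rms)
          labels[i] <- "cautery"
        }
      }
    }
    list(epochs = epochs, labels = labels)
  })
}

#' Generate a two-group synthetic EEG cohort with ground truth
#'
#' For each preset, realizes `n_subjects` subjects (via [draw_subject()]),
#' synthesizes their epochs, injects artifacts at the preset rate, and
#' concatenates epochs into one continuous recording per subject. Fully
#' reproducible from `seed`.
#'
#' @param presets list of [group_preset()]s (default [default_presets()]).
#' @param seed integer master seed.
#' @param fixed logical; `TRUE` pins all subject parameters at preset means.
#' @param n_subjects optional override, recycled over presets.
#' @param epochs_per_subject optional override.
#' @param artifact_rate optional override (e.g. 0 for clean cohorts).
#' @param n_channels number of frontal channels; channels beyond the first
#'   replicate the signal plus independent noise at 10% of its power.
#' @param fs sampling rate, Hz.
#' @return An `eeg_cohort`: list with `recordings` (list of `eeg_recording`)
#'   and `ground_truth` (`subjects` = per-subject `subject_gen_params`,
#'   `artifact_labels` = data.frame subject_id/epoch_index/label).
#' @export
generate_cohort <- function(presets = default_presets(), seed = 1,
                            fixed = FALSE, n_subjects = NULL,
                            epochs_per_subject = NULL, artifact_rate = NULL,
                            n_channels = 1, fs = 250) {
  recordings <- list()
  subjects <- list()
  lab_rows <- list()
  sidx <- 0L
  for (preset in presets) {
    ns <- if (is.null(n_subjects)) preset$n_subjects else n_subjects
    ne <- if (is.null(epochs_per_subject)) preset$epochs_per_subject else
      epochs_per_subject
    rate <- if (is.null(artifact_rate)) preset$artifact_rate else artifact_rate
    stopifnot(ns >= 2)
    for (s in seq_len(ns)) {
      sidx <- sidx + 1L
      sid <- sprintf("%s_%02d", preset$name, s)
      sp <- draw_subject(preset, sid, seed = child_seed(seed, sidx),
                         fixed = fixed, n_epochs = ne)
      epo_seed <- child_seed(seed, 100000L + sidx)
      epochs <- with_seed(epo_seed, {
        t(vapply(seq_len(ne), function(e) {
          synth_epoch_signal(sp, n_samples = round(30 * fs), fs = fs)
        }, numeric(round(30 * fs))))
      })
      inj <- inject_artifacts(epochs, rate,
                              seed = child_seed(seed, 200000L + sidx))
      signal <- as.vector(t(inj$epochs))
      if (n_channels > 1) {
        base_sd <- stats::sd(signal)
        signal <- with_seed(child_seed(seed, 300000L + sidx), {
          rbind(signal, t(vapply(seq_len(n_channels - 1), function(ch) {
            signal + stats::rnorm(length(signal), 0, sqrt(0.1) * base_sd)
          }, numeric(length(signal)))))
        })
      } else {
        signal <- matrix(signal, nrow = 1)
      }
      recordings[[sid]] <- structure(list(
        subject_id = sid, group = preset$name, fs = fs,
        channels = paste0("Fp", seq_len(n_channels)),
        signal = signal, loc_time = NULL, end_time = NULL
      ), class = "eeg_recording")
      subjects[[sid]] <- sp
      lab_rows[[sid]] <- data.frame(
        subject_id = sid, epoch_index = seq_len(ne), label = inj$labels,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    recordings = recordings,
    ground_truth = list(
      subjects = subjects,
      artifact_labels = do.call(rbind, c(lab_rows, make.row.names = FALSE))
    ),
    fs = fs, epoch_len_s = 30, seed = seed
  ), class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$group, character(1))
  cat("Synthetic EEG cohort:", length(x$recordings), "subjects (",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "),
      "), fs =", x$fs, "Hz, 30-s epochs\n")
  invisible(x)
}

#' Write a cohort to disk as plain-text matrices plus JSON sidecars
#'
#' One CSV signal matrix per subject (channels x samples), a JSON sidecar per
#' subject (id, group, sampling rate, epoch boundaries), and the full ground
#' truth as JSON.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    utils::write.table(
      format(rec$signal, digits = 7, scientific = TRUE, trim = TRUE),
      file.path(dir, paste0(rec$subject_id, "_signal.csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    ns <- round(30 * rec$fs)
    jsonlite::write_json(list(
      subject_id = rec$subject_id, group = rec$group, fs = rec$fs,
      channels = rec$channels,
      epoch_starts = seq(0, ncol(rec$signal) - ns, by = ns)
    ), file.path(dir, paste0(rec$subject_id, "_meta.json")),
    auto_unbox = TRUE, digits = NA)
  }
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    subjects = lapply(gt$subjects, function(sp) list(
      subject_id = sp$subject_id, group = sp$group,
      offset = sp$aperiodic$offset, exponent = sp$aperiodic$exponent,
      peaks = lapply(sp$peaks, function(pk) unclass(pk)),
      n_epochs = sp$n_epochs)),
    artifact_labels = gt$artifact_labels
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
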
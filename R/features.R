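#' Per-epoch spectral features
#'
#' All periodic/distribution features are computed from the epoch's Welch
#' PSD over the analysis range 0.5--30 Hz: five relative band powers, five
#' band-power ratios, the alpha peak frequency (raw-PSD argmax in 8--13 Hz
#' with parabolic refinement), alpha bandwidth (from the fitted spectral
#' model), spectral edge frequencies SEF50/SEF95, and spectral entropy.
#' Together with the aperiodic exponent and offset they form the fixed-order
#' 17-value feature vector.
#'
#' @name features
NULL

#' Band power by trapezoidal integration
#'
#' Integrates the one-sided density over `[lo, hi]` with linear interpolation
#' at band edges that fall between grid points. Adjacent bands sharing an
#' edge are exactly additive.
#'
#' @param ps a `power_spectrum`.
#' @param lo,hi band edges, Hz (`lo < hi`, inside the grid).
#' @return Band power, uV^2.
#' @export
band_power <- function(ps, lo, hi) {
  if (lo >= hi) stop("band edges must satisfy lo < hi")
  f <- ps$freqs; d <- ps$density
  if (lo < f[1] || hi > f[length(f)]) stop("band outside the spectrum grid")
  inner <- which(f > lo & f < hi)
  fg <- c(lo, f[inner], hi)
  dg <- c(stats::approx(f, d, lo)$y, d[inner], stats::approx(f, d, hi)$y)
  sum(diff(fg) * (dg[-1] + dg[-length(dg)]) / 2)
}

#' Relative band powers and band-power ratios
#'
#' Five fractions (delta, theta, alpha, beta, gamma) of total 0.5--30 Hz
#' power, plus the five ratios Theta/Alpha, Theta/Delta, Beta/Delta,
#' Beta/Alpha and Alpha/Delta as quotients of the fractions. A zero
#' denominator yields `NA` (never infinity) and the result is flagged.
#'
#' @param ps a `power_spectrum`.
#' @return Named numeric vector of 10 values, with attribute `flagged`
#'   (logical) when any ratio denominator was zero.
#' @export
relative_powers_and_ratios <- function(ps) {
  bands <- canonical_bands()
  bp <- vapply(seq_len(nrow(bands)),
               function(b) band_power(ps, bands$lo[b], bands$hi[b]),
               numeric(1))
  total <- sum(bp)
  if (total <= 0) stop("total power over 0.5-30 Hz is not positive")
  rel <- bp / total
  names(rel) <- paste0(c("Delta", "Theta", "Alpha", "Beta", "Gamma"), "_Rel")
  safe_div <- function(a, b) if (b == 0) NA_real_ else unname(a / b)
  ratios <- c(
    Theta_Alpha_Ratio = safe_div(rel[2], rel[3]),
    Theta_Delta_Ratio = safe_div(rel[2], rel[1]),
    Beta_Delta_Ratio  = safe_div(rel[4], rel[1]),
    Beta_Alpha_Ratio  = safe_div(rel[4], rel[3]),
    Alpha_Delta_Ratio = safe_div(rel[3], rel[1])
  )
  out <- c(rel, ratios)
  attr(out, "flagged") <- anyNA(ratios)
  out
}

#' Spectral edge frequency
#'
#' Smallest frequency below which a fraction `q` of the total 0.5--30 Hz
#' power lies, with linear interpolation of the cumulative trapezoid power
#' inside the crossing bin.
#'
#' @param ps a `power_spectrum`.
#' @param q quantile, e.g. 0.50 (median frequency) or 0.95 (SEF95).
#' @return Frequency, Hz.
#' @export
spectral_edge <- function(ps, q) {
  stopifnot(q > 0, q <= 1)
  f <- ps$freqs; d <- ps$density
  lo <- TOTAL_RANGE[1]; hi <- TOTAL_RANGE[2]
  inner <- which(f > lo & f < hi)
  fg <- c(lo, f[inner], hi)
  dg <- c(stats::approx(f, d, lo)$y, d[inner], stats::approx(f, d, hi)$y)
  cum <- c(0, cumsum(diff(fg) * (dg[-1] + dg[-length(dg)]) / 2))
  total <- cum[length(cum)]
  if (total <= 0) stop("total power over 0.5-30 Hz is not positive")
  target <- q * total
  i <- which(cum >= target - 1e-15 * total)[1]
  if (i == 1) return(fg[1])
  fg[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) *
    (fg[i] - fg[i - 1])
}

#' Alpha peak frequency
#'
#' Argmax of the raw density over grid bins within 8--13 Hz, refined by
#' three-point parabolic interpolation and clamped to the band; ties break
#' toward the lower frequency.
#'
#' @param ps a `power_spectrum`.
#' @return Peak frequency, Hz, in `[8, 13]`.
#' @export
alpha_peak <- function(ps) {
  f <- ps$freqs; d <- ps$density
  band <- which(f >= 8 & f <= 13)
  if (length(band) == 0) stop("spectrum grid does not cover 8-13 Hz")
  gi <- band[which.max(d[band])]
  f0 <- f[gi]
  if (gi > 1 && gi < length(f)) {
    ym <- d[gi - 1]; y0 <- d[gi]; yp <- d[gi + 1]
    den <- ym - 2 * y0 + yp
    delta <- if (den == 0) 0 else 0.5 * (ym - yp) / den
    delta <- min(max(delta, -0.5), 0.5)
    f0 <- f0 + delta * ps$resolution
  }
  min(max(f0, 8), 13)
}

#' Alpha bandwidth
#'
#' Full width at half maximum of the fitted alpha-band Gaussian peak
#' (\eqn{2\sqrt{2\ln 2}\,\sigma}), clipped to the 5-Hz band width. When the
#' spectral model contains no peak centered in 8--13 Hz, falls back to the
#' half-maximum width of the background-subtracted (flattened) spectrum
#' around its alpha-band argmax, intersected with 8--13 Hz.
#'
#' @param model a `spectral_model` from [parameterize_spectrum()].
#' @return Bandwidth, Hz, in `(0, 5]`.
#' @export
alpha_bandwidth <- function(model) {
  alpha_pks <- Filter(function(p) p$center >= 8 && p$center <= 13,
                      model$peaks)
  if (length(alpha_pks) > 0) {
    sd <- alpha_pks[[1]]$sd # peaks are sorted by height, take the dominant
    return(min(2 * sqrt(2 * log(2)) * sd, 5))
  }
  # fallback: half-max width of the background-subtracted log spectrum
  f <- model$freqs
  detr <- model$log_psd - model$aperiodic_line
  band <- which(f >= 8 & f <= 13)
  db <- detr[band]; fb <- f[band]
  i0 <- which.max(db)
  hm <- db[i0] / 2
  if (db[i0] <= 0) return(f[2] - f[1])
  li <- i0
  while (li > 1 && db[li - 1] >= hm) li <- li - 1
  ri <- i0
  while (ri < length(db) && db[ri + 1] >= hm) ri <- ri + 1
  max(fb[ri] - fb[li], f[2] - f[1])
}

#' Spectral entropy
#'
#' Shannon entropy (natural log, nats) of the density over grid bins in
#' 0.5--30 Hz normalized to a probability distribution; zero bins
#' contribute 0.
#'
#' @param ps a `power_spectrum`.
#' @return Entropy, nats.
#' @export
spectral_entropy <- function(ps) {
  sel <- ps$freqs >= TOTAL_RANGE[1] & ps$freqs <= TOTAL_RANGE[2]
  d <- ps$density[sel]
  total <- sum(d)
  if (total <= 0) stop("total power over 0.5-30 Hz is not positive")
  p <- d / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Extract the 17-value feature vector for one epoch
#'
#' Computes the Welch PSD, the aperiodic/periodic decomposition and all
#' spectral features, returning them in the fixed table order.
#'
#' @param epoch numeric signal vector (one 30-s epoch), uV.
#' @param fs sampling rate, Hz.
#' @param model optional precomputed `spectral_model` for the epoch.
#' @return Named numeric vector of length 17 (see [feature_names()]), with
#'   attribute `flagged` when a ratio denominator was zero.
#' @export
extract_feature_vector <- function(epoch, fs, model = NULL) {
  ps <- welch_psd(epoch, fs)
  if (is.null(model)) model <- parameterize_spectrum(ps)
  rp <- relative_powers_and_ratios(ps)
  out <- c(
    rp,
    Peak_Freq = alpha_peak(ps),
    Alpha_Bandwidth = alpha_bandwidth(model),
    SEF95 = spectral_edge(ps, 0.95),
    SEF50 = spectral_edge(ps, 0.50),
    Exponent = model$aperiodic$exponent,
    Offset = model$aperiodic$offset,
    SpecEn = spectral_entropy(ps)
  )
  out <- stats::setNames(as.numeric(out), feature_names())
  attr(out, "flagged") <- isTRUE(attr(rp, "flagged"))
  out
}

#' Extract the per-epoch feature table for a whole cohort
#'
#' Segments every recording into 30-s epochs, applies the two-stage artifact
#' screen, and extracts the 17 features for each retained epoch.
#'
#' @param cohort an `eeg_cohort` (or list of `eeg_recording`s).
#' @param qc logical; apply the power-threshold screen (default `TRUE`).
#' @return A data.frame (`cohort_features`) with columns `subject_id`,
#'   `group`, `epoch_index` and the 17 features; attribute `qc` holds the
#'   per-subject rejection summary (kept/total/rate and per-epoch reasons).
#' @export
extract_cohort_features <- function(cohort, qc = TRUE) {
  recordings <- if (inherits(cohort, "eeg_cohort")) cohort$recordings else
    cohort
  rows <- list()
  qc_sum <- list()
  for (rec in recordings) {
    es <- segment_epochs(rec)
    ne <- nrow(es$epochs)
    if (ne == 0) next
    if (qc && ne >= 2) {
      st <- session_power_stats(es)
      mask <- apply_qc(es, st)
    } else {
      mask <- list(keep = rep(TRUE, ne), reason = rep("clean", ne),
                   rejection_rate = 0)
    }
    kept <- which(mask$keep)
    fv <- t(vapply(kept, function(e) {
      extract_feature_vector(es$epochs[e, ], rec$fs)
    }, numeric(17)))
    rows[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id, group = rec$group, epoch_index = kept,
      fv, stringsAsFactors = FALSE)
    qc_sum[[rec$subject_id]] <- data.frame(
      subject_id = rec$subject_id, epoch_index = seq_len(ne),
      keep = mask$keep, reason = mask$reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "qc") <- do.call(rbind, c(qc_sum, make.row.names = FALSE))
  class(out) <- c("cohort_features", "data.frame")
  out
}
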
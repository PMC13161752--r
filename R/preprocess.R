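#' Preprocessing: maintenance window, epoching, two-stage artifact rejection
#'
#' Recordings are trimmed to the steady-state maintenance window, segmented
#' into non-overlapping 30-s epochs (channels averaged in the time domain),
#' and screened by the two-stage power-threshold rule: per-epoch total power
#' over 0.5--45 Hz is log10-transformed, and epochs falling below
#' \eqn{\mu - 2.5\sigma} (dropouts / lead-off) or above \eqn{\mu + 2.5\sigma}
#' (broadband interference such as electrocautery) of the session mean are
#' rejected in a single pass.
#'
#' @name preprocess
NULL

#' Trim a recording to the steady-state maintenance window
#'
#' Retains samples in `[LOC + 20 min, end_of_surgery - 10 min)`. Returns an
#' empty-signal recording (with a warning) when that window is non-positive.
#'
#' @param recording an `eeg_recording`.
#' @param loc_time_s loss-of-consciousness time, seconds from recording start;
#'   defaults to the recording's own event time.
#' @param end_surgery_time_s end-of-surgery time, seconds.
#' @return The trimmed `eeg_recording`.
#' @export
select_maintenance_window <- function(recording,
                                      loc_time_s = recording$loc_time,
                                      end_surgery_time_s = recording$end_time) {
  if (is.null(loc_time_s) || is.null(end_surgery_time_s)) {
    stop("maintenance-window selection requires LOC and end-of-surgery times")
  }
  fs <- recording$fs
  lo_s <- loc_time_s + 1200
  hi_s <- end_surgery_time_s - 600
  n <- ncol(recording$signal)
  if (hi_s <= lo_s) {
    warning("maintenance window is empty (",
            round(hi_s - lo_s), " s); returning empty recording")
    recording$signal <- recording$signal[, 0, drop = FALSE]
    return(recording)
  }
  i0 <- floor(lo_s * fs) + 1
  i1 <- min(floor(hi_s * fs), n)
  recording$signal <- recording$signal[, i0:i1, drop = FALSE]
  recording
}

#' Segment a recording into non-overlapping 30-s epochs
#'
#' Channels are averaged in the time domain first; the trailing remainder
#' shorter than 30 s is discarded.
#'
#' @param recording an `eeg_recording`.
#' @return An `epoch_set`: list with `epochs` (n_epochs x n_samples matrix),
#'   `start_times` (s), `epoch_len_s`, `fs`.
#' @export
segment_epochs <- function(recording) {
  fs <- recording$fs
  ns <- round(30 * fs)
  trace <- if (nrow(recording$signal) > 1) {
    colMeans(recording$signal)
  } else {
    as.vector(recording$signal)
  }
  ne <- length(trace) %/% ns
  epochs <- if (ne > 0) {
    matrix(trace[seq_len(ne * ns)], nrow = ne, byrow = TRUE)
  } else {
    matrix(numeric(0), nrow = 0, ncol = ns)
  }
  structure(list(
    epochs = epochs,
    start_times = (seq_len(ne) - 1) * 30,
    epoch_len_s = 30, fs = fs
  ), class = "epoch_set")
}

#' Session-level log-power statistics for the artifact screen
#'
#' Integrates each epoch's Welch PSD over 0.5--45 Hz, log10-transforms, and
#' records the session mean, sample SD and the symmetric
#' \eqn{\mu \pm 2.5\sigma} thresholds.
#'
#' @param epoch_set an `epoch_set` (or a plain epochs x samples matrix, with
#'   `fs` supplied).
#' @param fs sampling rate, Hz (taken from `epoch_set` when present).
#' @param n_sigma threshold width in SDs (default 2.5).
#' @return A `session_power_stats`: `log_power` per epoch, `mu`, `sigma`,
#'   `low`, `high`.
#' @export
session_power_stats <- function(epoch_set, fs = NULL, n_sigma = 2.5) {
  epochs <- if (is.matrix(epoch_set)) epoch_set else epoch_set$epochs
  if (is.null(fs)) fs <- epoch_set$fs
  if (nrow(epochs) < 2) stop("need at least 2 epochs for session statistics")
  lp <- unname(apply(epochs, 1, function(x) {
    ps <- welch_psd(x, fs)
    log10(band_power(ps, QC_RANGE[1], QC_RANGE[2]))
  }))
  mu <- mean(lp)
  sigma <- stats::sd(lp)
  structure(list(log_power = lp, mu = mu, sigma = sigma,
                 low = mu - n_sigma * sigma, high = mu + n_sigma * sigma,
                 n_sigma = n_sigma),
            class = "session_power_stats")
}

#' Apply the two-stage power-threshold artifact screen
#'
#' Single pass: an epoch is rejected as `dropout` if its log10 total power
#' falls below the low threshold, as `high_power` if above the high one.
#' A zero-SD session rejects nothing.
#'
#' @param epoch_set an `epoch_set` (or matrix; only its row count is used).
#' @param stats a [session_power_stats()] computed on the same epochs.
#' @return A `qc_mask`: `keep` logical, `reason` in
#'   `{clean, dropout, high_power}`, `rejection_rate`.
#' @export
apply_qc <- function(epoch_set, stats) {
  epochs <- if (is.matrix(epoch_set)) epoch_set else epoch_set$epochs
  stopifnot(length(stats$log_power) == nrow(epochs))
  lp <- stats$log_power
  reason <- rep("clean", length(lp))
  if (stats$sigma > 0) {
    reason[lp < stats$low] <- "dropout"
    reason[lp > stats$high] <- "high_power"
  }
  keep <- reason == "clean"
  structure(list(keep = keep, reason = reason,
                 rejection_rate = mean(!keep)),
            class = "qc_mask")
}

#' @export
print.qc_mask <- function(x, ...) {
  cat(sprintf("QC mask: %d/%d epochs kept (rejection rate %.2f%%)\n",
              sum(x$keep), length(x$keep), 100 * x$rejection_rate))
  invisible(x)
}
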
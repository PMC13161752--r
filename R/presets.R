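#' Drug-specific generator presets
#'
#' A `group_preset` bundles everything the cohort generator needs for one
#' maintenance regime: the between-subject distribution of the aperiodic
#' background (offset, exponent), the alpha peak location distribution, fixed
#' centers/widths for the slow, theta and beta peaks, the target relative band
#' powers the peak calibration must hit, the artifact rate, and cohort shape.
#'
#' @param name group label, e.g. `"propofol"`.
#' @param exponent_mean,exponent_sd between-subject aperiodic exponent.
#' @param offset_mean,offset_sd between-subject offset, log10(uV^2/Hz).
#' @param alpha_center_mean,alpha_center_sd alpha peak center, Hz.
#' @param alpha_sd_hz,theta_center_hz,theta_sd_hz,beta_center_hz,beta_sd_hz,slow_center_hz,slow_sd_hz
#'   fixed peak geometry, Hz.
#' @param target_rel_powers 5-vector (delta, theta, alpha, beta, gamma)
#'   summing to 1.
#' @param artifact_rate fraction of epochs corrupted by injected artifacts.
#' @param epochs_per_subject,n_subjects cohort shape.
#' @return A `group_preset` object.
#' @export
group_preset <- function(name,
                         exponent_mean, exponent_sd,
                         offset_mean, offset_sd,
                         alpha_center_mean, alpha_center_sd,
                         alpha_sd_hz = 1.2,
                         theta_center_hz = 6.0, theta_sd_hz = 1.0,
                         beta_center_hz = 18.0, beta_sd_hz = 3.0,
                         slow_center_hz = 1.2, slow_sd_hz = 0.6,
                         target_rel_powers,
                         artifact_rate = 0.034,
                         epochs_per_subject = 30,
                         n_subjects = 20) {
  stopifnot(length(target_rel_powers) == 5, all(target_rel_powers >= 0),
            abs(sum(target_rel_powers) - 1) < 1e-9,
            exponent_sd >= 0, offset_sd >= 0, alpha_center_sd >= 0,
            artifact_rate >= 0, artifact_rate < 0.5)
  structure(list(
    name = name,
    exponent_mean = exponent_mean, exponent_sd = exponent_sd,
    offset_mean = offset_mean, offset_sd = offset_sd,
    alpha_center_mean = alpha_center_mean, alpha_center_sd = alpha_center_sd,
    alpha_sd_hz = alpha_sd_hz,
    theta_center_hz = theta_center_hz, theta_sd_hz = theta_sd_hz,
    beta_center_hz = beta_center_hz, beta_sd_hz = beta_sd_hz,
    slow_center_hz = slow_center_hz, slow_sd_hz = slow_sd_hz,
    target_rel_powers = stats::setNames(as.numeric(target_rel_powers),
                                        canonical_bands()$name),
    artifact_rate = artifact_rate,
    epochs_per_subject = epochs_per_subject,
    n_subjects = n_subjects
  ), class = "group_preset")
}

#' Default presets for propofol- and sevoflurane-maintained anesthesia
#'
#' Centers taken from the published group means for maintenance-phase frontal
#' EEG: alpha peak 10.88 vs 8.78 Hz, aperiodic exponent 2.07 vs 2.37, and the
#' group-mean relative band powers renormalized to sum to one
#' (propofol \eqn{\propto} (0.60, 0.10, 0.17, 0.13, 0.01); sevoflurane
#' \eqn{\propto} (0.63, 0.20, 0.15, 0.06, 0.005)). Between-subject SDs follow
#' the same source where reported. The shared offset mean is 1.0
#' log10(uV^2/Hz) — relative-power features are scale-free, so the absolute
#' level is a free choice — with a 0.3 between-subject SD.
#'
#' @return Named list with elements `propofol` and `sevoflurane`.
#' @export
default_presets <- function() {
  list(
    propofol = group_preset(
      name = "propofol",
      exponent_mean = 2.07, exponent_sd = 0.40,
      offset_mean = 1.0, offset_sd = 0.3,
      alpha_center_mean = 10.88, alpha_center_sd = 0.74,
      target_rel_powers = c(0.60, 0.10, 0.17, 0.13, 0.01) / 1.01
    ),
    sevoflurane = group_preset(
      name = "sevoflurane",
      exponent_mean = 2.37, exponent_sd = 0.21,
      offset_mean = 1.0, offset_sd = 0.3,
      alpha_center_mean = 8.78, alpha_center_sd = 0.87,
      target_rel_powers = c(0.63, 0.20, 0.15, 0.06, 0.005) / 1.045
    )
  )
}
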
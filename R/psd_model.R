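#' Parametric PSD model: aperiodic 1/f background plus Gaussian peaks
#'
#' The generator's ground-truth spectrum is
#' \deqn{S(f) = 10^{L} f^{-x} + \sum_k p_k \, N(f; c_k, \sigma_k)}
#' where `L` is the offset (log10 \eqn{\mu V^2}/Hz at 1 Hz), `x` the aperiodic
#' exponent, and each oscillatory peak contributes total band-integrated power
#' `p_k` (\eqn{\mu V^2}) spread as a unit-area Gaussian density truncated and
#' renormalized to 0.5--45 Hz. Peaks are additive in linear power, which makes
#' band-power calibration a nonnegative linear solve.
#'
#' @name psd-model
NULL

#' Construct aperiodic background parameters
#'
#' @param offset log10 power density at 1 Hz, log10(uV^2/Hz).
#' @param exponent dimensionless 1/f decay rate; must be positive.
#' @return An `aperiodic_params` object.
#' @export
aperiodic_params <- function(offset, exponent) {
  stopifnot(is.finite(offset), is.finite(exponent), exponent > 0)
  structure(list(offset = offset, exponent = exponent),
            class = "aperiodic_params")
}

#' Construct an oscillatory peak specification
#'
#' @param center_hz peak center frequency, Hz (> 0).
#' @param sd_hz Gaussian spectral width parameter, Hz (> 0).
#' @param power_uv2 total band-integrated power of the bump, uV^2 (>= 0).
#' @return A `peak_spec` object.
#' @export
peak_spec <- function(center_hz, sd_hz, power_uv2 = 0) {
  stopifnot(center_hz > 0, sd_hz > 0, power_uv2 >= 0)
  structure(list(center_hz = center_hz, sd_hz = sd_hz, power_uv2 = power_uv2),
            class = "peak_spec")
}

# Truncated unit-area Gaussian density on [lo, hi]; zero outside.
trunc_gauss_density <- function(f, center, sd, lo = 0.5, hi = 45) {
  mass <- stats::pnorm(hi, center, sd) - stats::pnorm(lo, center, sd)
  d <- stats::dnorm(f, center, sd) / mass
  d[f < lo | f > hi] <- 0
  d
}

# Fraction of a truncated Gaussian's mass falling in [lo, hi].
trunc_gauss_mass <- function(center, sd, lo, hi, tlo = 0.5, thi = 45) {
  lo <- max(lo, tlo); hi <- min(hi, thi)
  if (hi <= lo) return(0)
  (stats::pnorm(hi, center, sd) - stats::pnorm(lo, center, sd)) /
    (stats::pnorm(thi, center, sd) - stats::pnorm(tlo, center, sd))
}

# Analytic integral of the background 10^L f^-x over [lo, hi].
aperiodic_band_power <- function(bg, lo, hi) {
  L <- bg$offset; x <- bg$exponent
  if (abs(x - 1) < 1e-12) {
    10^L * log(hi / lo)
  } else {
    10^L * (hi^(1 - x) - lo^(1 - x)) / (1 - x)
  }
}

#' Evaluate the model power spectral density
#'
#' @param f frequencies, Hz.
#' @param bg [aperiodic_params()] background.
#' @param peaks list of [peak_spec()].
#' @return Density values, uV^2/Hz.
#' @export
model_psd <- function(f, bg, peaks = list()) {
  d <- 10^bg$offset * f^(-bg$exponent)
  d[f <= 0] <- 0
  for (pk in peaks) {
    d <- d + pk$power_uv2 * trunc_gauss_density(f, pk$center_hz, pk$sd_hz)
  }
  d
}

#' Analytic relative band powers of a model spectrum
#'
#' Band powers of \eqn{S(f)} over the five canonical bands, normalized by the
#' total over 0.5--30 Hz, computed in closed form.
#'
#' @inheritParams model_psd
#' @return Named 5-vector of band fractions summing to 1.
#' @export
analytic_band_fractions <- function(bg, peaks = list()) {
  bands <- canonical_bands()
  bp <- vapply(seq_len(nrow(bands)), function(b) {
    v <- aperiodic_band_power(bg, bands$lo[b], bands$hi[b])
    for (pk in peaks) {
      v <- v + pk$power_uv2 *
        trunc_gauss_mass(pk$center_hz, pk$sd_hz, bands$lo[b], bands$hi[b])
    }
    v
  }, numeric(1))
  stats::setNames(bp / sum(bp), bands$name)
}

#' Calibrate peak powers to hit target relative band powers
#'
#' Given the aperiodic background and the centers/widths of the four
#' oscillatory peaks (slow, theta, alpha, beta), solves for nonnegative peak
#' powers such that the analytic relative powers of the full model over the
#' five canonical bands match `target_rel`. Because peaks are additive in
#' linear power the constraints are linear in the powers and are solved by
#' nonnegative least squares; no gamma peak exists, so the gamma fraction is
#' carried by the aperiodic tail and the beta peak's upper tail.
#'
#' @param bg [aperiodic_params()] background.
#' @param peaks list of 4 [peak_spec()] (slow, theta, alpha, beta); their
#'   `power_uv2` entries are ignored and replaced.
#' @param target_rel numeric 5-vector (delta, theta, alpha, beta, gamma)
#'   summing to 1.
#' @param tol maximum tolerated absolute deviation of any achieved band
#'   fraction from its target (default 0.01).
#' @return The `peaks` list with calibrated `power_uv2`, with attribute
#'   `achieved_fractions`.
#' @export
calibrate_peak_powers <- function(bg, peaks, target_rel, tol = 0.01) {
  stopifnot(length(peaks) == 4, length(target_rel) == 5,
            all(target_rel >= 0), abs(sum(target_rel) - 1) < 1e-9)
  bands <- canonical_bands()
  nb <- nrow(bands); np <- length(peaks)
  # A[b, k]: fraction of peak k's unit power landing in band b
  A <- matrix(0, nb, np)
  for (k in seq_len(np)) {
    A[, k] <- vapply(seq_len(nb), function(b) {
      trunc_gauss_mass(peaks[[k]]$center_hz, peaks[[k]]$sd_hz,
                       bands$lo[b], bands$hi[b])
    }, numeric(1))
  }
  tvec <- vapply(seq_len(nb), function(b) {
    aperiodic_band_power(bg, bands$lo[b], bands$hi[b])
  }, numeric(1))
  T0 <- sum(tvec)
  Cx <- colSums(A) # peak mass within [0.5, 30]
  # band_b(S) = r_b * total(S)  <=>  (A - r %*% t(C)) p = r*T0 - t
  M <- A - outer(target_rel, Cx)
  b <- target_rel * T0 - tvec
  sol <- pracma::lsqnonneg(M, b)
  p <- pmax(sol$x, 0)
  for (k in seq_len(np)) peaks[[k]]$power_uv2 <- p[k]
  achieved <- analytic_band_fractions(bg, peaks)
  dev <- abs(achieved - target_rel)
  if (max(dev) > tol) {
    worst <- bands$name[which.max(dev)]
    stop(sprintf(
      "peak-power calibration infeasible: %s band off target by %.4f (tol %.3g)",
      worst, max(dev), tol))
  }
  attr(peaks, "achieved_fractions") <- achieved
  peaks
}
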
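#' Aperiodic/periodic decomposition of a power spectrum
#'
#' Simplified spectral parameterization in the specparam (FOOOF) tradition:
#' the log10 PSD over the fit range (default 1--30 Hz) is modeled as a
#' straight line in log10 frequency, \eqn{\log_{10} P(f) = L - x \log_{10} f}
#' (no knee), plus Gaussian oscillatory peaks in log-power space. `L` is the
#' broadband offset (intercept at 1 Hz) and `x` the aperiodic exponent. The
#' background fit is made robust to peaks by a peak-masked refit; peaks are
#' then extracted iteratively from the flattened residual.
#'
#' @name aperiodic
NULL

# Iteratively detect Gaussian peaks in a residual log-power spectrum.
# threshold: max(thresh_sd * SD(current residual), abs_floor) log10 units.
# The residual SD is estimated from the negative half of the residual
# (oscillatory peaks only push it positive, so a raw SD would be inflated
# by the very peaks being hunted).
detect_gaussian_peaks <- function(f, resid, max_peaks = 6,
                                  sd_bounds = c(0.5, 6),
                                  thresh_sd = 2.0, abs_floor = 0.05) {
  peaks <- list()
  r <- resid
  for (it in seq_len(max_peaks)) {
    neg <- r[r < 0]
    noise_sd <- if (length(neg) >= 5) sqrt(mean(neg^2)) else stats::sd(r)
    thr <- max(thresh_sd * noise_sd, abs_floor)
    imax <- which.max(r)
    h0 <- r[imax]
    if (h0 < thr) break
    c0 <- f[imax]
    # seed the width from the local half-maximum extent, then least-squares
    # fit within a window around the maximum (keeps neighbouring peaks from
    # blending into one broad Gaussian)
    li <- imax; while (li > 1 && r[li - 1] >= h0 / 2) li <- li - 1
    ri <- imax; while (ri < length(r) && r[ri + 1] >= h0 / 2) ri <- ri + 1
    s0 <- min(max((f[ri] - f[li]) / (2 * sqrt(2 * log(2))), sd_bounds[1]),
              sd_bounds[2])
    win <- abs(f - c0) <= 3 * s0
    fit <- tryCatch(suppressWarnings({
      m <- minpack.lm::nlsLM(
        rw ~ h * exp(-(fw - cc)^2 / (2 * s^2)),
        data = data.frame(fw = f[win], rw = r[win]),
        start = list(h = h0, cc = c0, s = s0),
        lower = c(h = 1e-6, cc = max(c0 - s0, min(f)), s = sd_bounds[1]),
        upper = c(h = Inf, cc = min(c0 + s0, max(f)), s = sd_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 60))
      as.list(stats::coef(m))
    }), error = function(e) NULL)
    if (is.null(fit)) fit <- list(h = h0, cc = c0, s = s0)
    if (fit$h <= 0) break
    peaks[[length(peaks) + 1]] <- list(center = fit$cc, height = fit$h,
                                       sd = fit$s)
    r <- r - fit$h * exp(-(f - fit$cc)^2 / (2 * fit$s^2))
  }
  peaks
}

# Mask bins within +/- 2 sd of any peak center; returns logical keep vector.
peak_mask <- function(f, peaks) {
  keep <- rep(TRUE, length(f))
  for (pk in peaks) {
    keep[abs(f - pk$center) <= 2 * pk$sd] <- FALSE
  }
  keep
}

ols_line <- function(lf, lp) {
  co <- stats::lm.fit(cbind(1, lf), lp)$coefficients
  c(intercept = co[[1]], slope = co[[2]])
}

# A peak-masked refit is only trustworthy when enough bins remain AND they
# still span a substantial part of the log-frequency axis; a refit on a
# narrow sliver extrapolates wildly.
mask_usable <- function(lf, keep) {
  sum(keep) >= 5 &&
    diff(range(lf[keep])) >= 0.5 * diff(range(lf))
}

#' Robust aperiodic (1/f) background fit
#'
#' Two-stage fit in log10--log10 space: (1) an ordinary least-squares line;
#' (2) peaks are detected on the stage-1 residual and all bins within
#' \eqn{\pm 2\sigma} of a detected peak are excluded before the line is
#' refit. Falls back to the stage-1 fit (with a flag) when fewer than 5
#' bins survive masking.
#'
#' @param ps a `power_spectrum` with positive density over the fit range.
#' @param fit_range frequency range, Hz (default `c(1, 30)`).
#' @return An `aperiodic_fit`: `offset` (intercept at 1 Hz,
#'   log10(uV^2/Hz)), `exponent` (negated slope), `fit_lo`, `fit_hi`, `r2`
#'   (of the line on log10 power), `fallback` flag.
#' @export
fit_aperiodic_robust <- function(ps, fit_range = c(1, 30)) {
  sel <- ps$freqs >= fit_range[1] & ps$freqs <= fit_range[2]
  f <- ps$freqs[sel]; d <- ps$density[sel]
  if (length(f) < 5) stop("fewer than 5 bins in the aperiodic fit range")
  if (any(d <= 0)) stop("non-positive density inside the aperiodic fit range")
  lf <- log10(f); lp <- log10(d)
  s1 <- ols_line(lf, lp)
  r1 <- lp - (s1[1] + s1[2] * lf)
  # Broad oscillatory peaks can cover most of the band and tilt the stage-1
  # line; robustify it by refitting on the lower envelope (bins at or below
  # the line, up to the 2.5th percentile of the positive residuals) before
  # peak detection.
  thr <- stats::quantile(pmax(r1, 0), 0.025)
  keep0 <- r1 <= thr
  if (sum(keep0) >= 5) s1 <- ols_line(lf[keep0], lp[keep0])
  resid1 <- lp - (s1[1] + s1[2] * lf)
  pks <- detect_gaussian_peaks(f, resid1)
  keep <- peak_mask(f, pks)
  fallback <- !mask_usable(lf, keep)
  co <- if (fallback) s1 else ols_line(lf[keep], lp[keep])
  line <- co[1] + co[2] * lf
  r2 <- 1 - sum((lp - line)^2) / sum((lp - mean(lp))^2)
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                 fit_lo = fit_range[1], fit_hi = fit_range[2],
                 r2 = r2, fallback = fallback),
            class = "aperiodic_fit")
}

#' Extract Gaussian oscillatory peaks above a fitted background
#'
#' Iteratively fits Gaussians (center, height in log10-power units, sd
#' bounded 0.5--6 Hz) to the positive residual of the log spectrum over the
#' aperiodic line, stopping when the largest residual falls below
#' `max(2 x SD(residual), 0.05)` or after 6 peaks.
#'
#' @param ps a `power_spectrum`.
#' @param fit an [fit_aperiodic_robust()] result.
#' @return List of peaks (`center`, `height`, `sd`), sorted by height
#'   descending; possibly empty.
#' @export
extract_peaks <- function(ps, fit) {
  sel <- ps$freqs >= fit$fit_lo & ps$freqs <= fit$fit_hi
  f <- ps$freqs[sel]
  lp <- log10(ps$density[sel])
  resid <- lp - (fit$offset - fit$exponent * log10(f))
  pks <- detect_gaussian_peaks(f, resid)
  pks[order(-vapply(pks, `[[`, numeric(1), "height"))]
}

#' Full spectral parameterization: background, peaks, flattened spectrum
#'
#' Runs the robust background fit, extracts peaks, refits the background
#' once on peak-masked bins, and re-extracts peaks against the refit
#' background. The flattened spectrum is the log10 residual after removing
#' both components, so background + peaks + flattened reconstructs the
#' input log spectrum identically.
#'
#' @param ps a `power_spectrum`.
#' @param fit_range frequency range, Hz (default `c(1, 30)`).
#' @return A `spectral_model`: `aperiodic` (`aperiodic_fit`), `peaks`
#'   (height-sorted), `freqs`, `log_psd`, `aperiodic_line`, `peak_line`,
#'   `flattened`, `r2` (input vs full reconstruction).
#' @export
parameterize_spectrum <- function(ps, fit_range = c(1, 30)) {
  ap1 <- fit_aperiodic_robust(ps, fit_range)
  pk1 <- extract_peaks(ps, ap1)
  sel <- ps$freqs >= fit_range[1] & ps$freqs <= fit_range[2]
  f <- ps$freqs[sel]; lf <- log10(f); lp <- log10(ps$density[sel])
  keep <- peak_mask(f, pk1)
  ap <- ap1
  if (mask_usable(lf, keep)) {
    co <- ols_line(lf[keep], lp[keep])
    line <- co[1] + co[2] * lf
    ap <- structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                         fit_lo = fit_range[1], fit_hi = fit_range[2],
                         r2 = 1 - sum((lp - line)^2) / sum((lp - mean(lp))^2),
                         fallback = FALSE),
                    class = "aperiodic_fit")
  }
  peaks <- extract_peaks(ps, ap)
  ap_line <- ap$offset - ap$exponent * lf
  pk_line <- rep(0, length(f))
  for (pk in peaks) {
    pk_line <- pk_line + pk$height * exp(-(f - pk$center)^2 / (2 * pk$sd^2))
  }
  recon <- ap_line + pk_line
  flattened <- lp - recon
  r2 <- 1 - sum(flattened^2) / sum((lp - mean(lp))^2)
  structure(list(
    aperiodic = ap, peaks = peaks, freqs = f, log_psd = lp,
    aperiodic_line = ap_line, peak_line = pk_line, flattened = flattened,
    r2 = r2
  ), class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf(
    "Spectral model: offset %.3f, exponent %.3f, %d peak(s), R^2 = %.4f\n",
    x$aperiodic$offset, x$aperiodic$exponent, length(x$peaks), x$r2))
  for (pk in x$peaks) {
    cat(sprintf("  peak: %.2f Hz, height %.3f, sd %.2f Hz\n",
                pk$center, pk$height, pk$sd))
  }
  invisible(x)
}

#' Plot a spectral parameterization
#'
#' Log-log PSD with the fitted aperiodic line, plus the flattened spectrum
#' in a lower panel.
#'
#' @param x a `spectral_model`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.spectral_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(log10(x$freqs), x$log_psd, type = "l",
       xlab = "log10 frequency (Hz)", ylab = "log10 power (uV^2/Hz)")
  graphics::lines(log10(x$freqs), x$aperiodic_line, lty = 2, col = 2)
  plot(x$freqs, x$peak_line + x$flattened, type = "l",
       xlab = "frequency (Hz)", ylab = "flattened log10 power")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
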
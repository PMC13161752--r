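#' Welch power spectral density estimate
#'
#' Welch's method with 4-s Hann-windowed segments at 50% overlap and
#' per-segment constant detrending, returning a one-sided density in
#' uV^2/Hz. With the default 4-s segment the grid resolution is exactly
#' 1/4 Hz, so every canonical band edge falls on a grid point; a 30-s epoch
#' yields 13 averaged segments.
#'
#' @param x numeric signal vector, uV.
#' @param fs sampling rate, Hz.
#' @param seg_len_s segment length, seconds (default 4).
#' @return A `power_spectrum`: list with `freqs` (Hz, uniform, from 0 to
#'   Nyquist), `density` (uV^2/Hz), `resolution` (Hz).
#' @export
welch_psd <- function(x, fs, seg_len_s = 4) {
  nper <- round(seg_len_s * fs)
  if (length(x) < nper) {
    stop("signal shorter than one Welch segment (", seg_len_s, " s)")
  }
  step <- nper %/% 2
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)
  U <- sum(w^2)
  nf <- nper %/% 2
  # segments as columns; detrend (constant), window, FFT all at once
  seg <- vapply(starts, function(s) x[s:(s + nper - 1)], numeric(nper))
  seg <- sweep(seg, 2, colMeans(seg))
  F <- stats::mvfft(seg * w)[1:(nf + 1), , drop = FALSE]
  P <- Mod(F)^2 / (fs * U)
  P[2:nf, ] <- 2 * P[2:nf, , drop = FALSE] # one-sided: double interior bins
  structure(list(
    freqs = (0:nf) * fs / nper,
    density = rowMeans(P),
    resolution = fs / nper
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d bins, %.4g-%.4g Hz, resolution %.3g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Construct a power spectrum from an explicit grid and density
#'
#' Mainly useful for analytic model spectra (e.g. from [model_psd()]) and
#' for validating the feature extractors against closed-form oracles.
#'
#' @param freqs strictly increasing uniform frequency grid, Hz.
#' @param density one-sided power density, uV^2/Hz (nonnegative).
#' @return A `power_spectrum`.
#' @export
power_spectrum <- function(freqs, density) {
  stopifnot(length(freqs) == length(density), all(diff(freqs) > 0),
            all(density >= 0))
  structure(list(freqs = freqs, density = density,
                 resolution = freqs[2] - freqs[1]),
            class = "power_spectrum")
}
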
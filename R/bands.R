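#' Canonical EEG frequency bands
#'
#' The five bands partition the analysis range 0.5--30 Hz used for all
#' relative-power features: delta 0.5--4, theta 4--8, alpha 8--13,
#' beta 13--25, gamma 25--30 Hz. Bands are half-open `[lo, hi)` except the
#' last, which is closed, so they tile the range without overlap.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 13, 25),
    hi = c(4, 8, 13, 25, 30),
    stringsAsFactors = FALSE
  )
}

# Analysis range shared by relative power, spectral edges and entropy.
TOTAL_RANGE <- c(0.5, 30)
# QC total-power screen integrates over the wider recording band.
QC_RANGE <- c(0.5, 45)

#' Feature names in their fixed table order
#'
#' The 17 per-epoch features, in the order used by every table, model matrix
#' and ranking in the package: five relative band powers, five band-power
#' ratios, alpha peak frequency and bandwidth, spectral edge frequencies,
#' the two aperiodic parameters and spectral entropy.
#'
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c(
    "Delta_Rel", "Theta_Rel", "Alpha_Rel", "Beta_Rel", "Gamma_Rel",
    "Theta_Alpha_Ratio", "Theta_Delta_Ratio", "Beta_Delta_Ratio",
    "Beta_Alpha_Ratio", "Alpha_Delta_Ratio",
    "Peak_Freq", "Alpha_Bandwidth", "SEF95", "SEF50",
    "Exponent", "Offset", "SpecEn"
  )
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a per-unit child seed from a base seed; stays inside 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483587L) + 1L
}
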
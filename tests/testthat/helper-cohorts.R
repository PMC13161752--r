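# Shared fixtures, built once per test run and cached.
#
# The heavy objects (fixed-mode cohorts at the two presets, the default
# variable cohort and their feature tables) are used by several test files;
# they are generated lazily and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Fixed-mode single-preset cohort: subject parameters pinned at preset means,
# clean (no artifacts), 20 subjects x 30 epochs.
fixed_cohort <- function(group = c("propofol", "sevoflurane"), seed = 42) {
  group <- match.arg(group)
  memo(paste0("fixed_", group, "_", seed), {
    generate_cohort(default_presets()[group], seed = seed, fixed = TRUE,
                    artifact_rate = 0)
  })
}

fixed_features <- function(group = c("propofol", "sevoflurane"), seed = 42) {
  group <- match.arg(group)
  memo(paste0("fixedfeat_", group, "_", seed), {
    extract_cohort_features(fixed_cohort(group, seed))
  })
}

# Default variable cohort (preset SDs active, artifacts injected) and its
# feature table.
variable_cohort <- function(seed = 42) {
  memo(paste0("var_", seed), generate_cohort(seed = seed))
}

variable_features <- function(seed = 42) {
  memo(paste0("varfeat_", seed), {
    extract_cohort_features(variable_cohort(seed))
  })
}

classification_result <- function() {
  memo("classify", classify_cohort(variable_features(), seed = 7))
}

# Analytic power-law spectrum on a grid (for oracle tests).
powerlaw_spectrum <- function(offset = 1, exponent = 2,
                              freqs = seq(0.25, 45, by = 0.25)) {
  power_spectrum(freqs, 10^offset * freqs^(-exponent))
}

# Dense-grid trapezoid oracle for band power of an arbitrary density function.
oracle_band_power <- function(dens_fun, lo, hi, df = 0.001) {
  f <- seq(lo, hi, by = df)
  d <- dens_fun(f)
  sum(diff(f) * (d[-1] + d[-length(d)]) / 2)
}

# Null feature table: both groups drawn from one subject-level distribution
# (used for type-I calibration of the group-comparison pipeline).
null_feature_table <- function(seed, n_per_group = 8, epochs = 5) {
  with_seed_local(seed, {
    fn <- feature_names()
    rows <- list()
    for (g in c("propofol", "sevoflurane")) {
      for (s in seq_len(n_per_group)) {
        mu <- stats::rnorm(length(fn)) # subject-level truth, group-free
        X <- matrix(stats::rnorm(epochs * length(fn), mean = rep(mu, each = epochs),
                                 sd = 0.3), epochs, length(fn))
        colnames(X) <- fn
        rows[[paste(g, s)]] <- data.frame(
          subject_id = paste0(g, "_", s), group = g,
          epoch_index = seq_len(epochs), X, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    class(out) <- c("cohort_features", "data.frame")
    out
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
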
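#' Group statistics: Welch's t, p-value ranking, correlation structure
#'
#' Feature comparisons between maintenance regimes use Welch's unequal-
#' variance t-test on subject-level feature means (one value per subject, so
#' epoch pseudo-replication cannot inflate significance), with features
#' ranked by p-value. Feature redundancy is summarized by the Spearman
#' correlation matrix over epochs with average-linkage hierarchical
#' clustering on the distance 1 - rho.
#'
#' @name group-stats
NULL

#' Welch's unequal-variance t-test
#'
#' \eqn{t = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch--Satterthwaite degrees of freedom and a two-tailed p-value from the
#' t distribution.
#'
#' @param x,y numeric samples (each `n >= 2` with nonzero variance).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) stop("zero variance in both samples; t undefined")
  se2x <- vx / nx; se2y <- vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Print a p-value to 3 decimals with the usual "<0.001" floor.
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Compare every feature between groups at subject level
#'
#' Features are first averaged within subject, then Welch-tested between the
#' two groups. Rows are sorted by ascending p and ranked 1..17. A
#' Benjamini--Hochberg adjusted column is appended as supplementary output.
#'
#' @param table a `cohort_features` data.frame.
#' @param level `"subject"` (default; one value per subject enters the test)
#'   or `"epoch"` (sensitivity analysis: epochs treated as independent).
#' @return data.frame with feature, per-group mean/SD, `t`, `df`, `p`,
#'   `p_formatted`, `p_rank`, `p_bh`, and an `ok` flag (FALSE where the test
#'   was undefined).
#' @export
compare_groups <- function(table, level = c("subject", "epoch")) {
  level <- match.arg(level)
  fn <- feature_names()
  groups <- sort(unique(table$group))
  stopifnot(length(groups) == 2)
  pull <- function(g, feat) {
    sub <- table[table$group == g, ]
    v <- sub[[feat]]
    if (level == "subject") {
      as.numeric(tapply(v, sub$subject_id, mean, na.rm = TRUE))
    } else {
      v[!is.na(v)]
    }
  }
  rows <- lapply(fn, function(feat) {
    a <- pull(groups[1], feat); b <- pull(groups[2], feat)
    res <- tryCatch(welch_t(a, b), error = function(e) NULL)
    data.frame(
      feature = feat,
      mean_1 = mean(a), sd_1 = stats::sd(a),
      mean_2 = mean(b), sd_2 = stats::sd(b),
      t = if (is.null(res)) NA_real_ else res$t,
      df = if (is.null(res)) NA_real_ else res$df,
      p = if (is.null(res)) NA_real_ else res$p,
      ok = !is.null(res),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                       paste0("mean_", groups[2]), paste0("sd_", groups[2]))
  out <- out[order(out$p, match(out$feature, fn)), ]
  out$p_rank <- seq_len(nrow(out))
  out$p_formatted <- format_p(out$p)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spearman correlation structure with hierarchical clustering
#'
#' Spearman's rho over epoch-level features, average-linkage agglomerative
#' clustering on the distance 1 - rho, and the resulting leaf order.
#' Constant features get zero correlation (flagged) rather than `NA`.
#'
#' @param table a `cohort_features` data.frame (>= 3 epochs).
#' @return List with `rho` (17x17), `tree` (`hclust`), `leaf_order`,
#'   `constant_features`.
#' @export
correlation_cluster <- function(table) {
  fn <- feature_names()
  X <- as.matrix(table[, fn])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete epochs")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  tree <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  list(rho = rho, tree = tree, leaf_order = fn[tree$order],
       constant_features = fn[const])
}
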
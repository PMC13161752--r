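#!/usr/bin/env Rscript

# Step 4 — group statistics and feature correlation structure.
#
# Welch's unequal-variance t-test per feature on subject-level means
# (avoiding epoch pseudo-replication), features ranked by p-value with the
# SHAP rank joined in, plus the epoch-level Spearman correlation matrix with
# average-linkage hierarchical clustering.

suppressPackageStartupMessages(library(anesEEG))

dir.create("results", showWarnings = FALSE)

feat <- read.csv("results/features.csv", stringsAsFactors = FALSE)
class(feat) <- c("cohort_features", "data.frame")

cmp <- compare_groups(feat)
if (file.exists("results/shap_importance.csv")) {
  shap <- read.csv("results/shap_importance.csv", stringsAsFactors = FALSE)
  cmp$shap_rank <- shap$rank[match(cmp$feature, shap$feature)]
}
write.csv(cmp, "results/group_comparison.csv", row.names = FALSE)
cat("Group comparison (subject-level Welch's t, sorted by p):\n")
print(cmp[, c("feature", "mean_propofol", "mean_sevoflurane",
              "t", "df", "p_formatted", "p_rank")], digits = 3)

cs <- correlation_cluster(feat)
write.csv(round(cs$rho, 4), "results/spearman_correlation.csv")
jsonlite::write_json(list(leaf_order = cs$leaf_order,
                          constant_features = cs$constant_features),
                     "results/dendrogram_order.json", auto_unbox = TRUE)
cat(sprintf("\n%d features significant at p < 0.05 (uncorrected)\n",
            sum(cmp$p < 0.05, na.rm = TRUE)))
cat("Dendrogram leaf order:", paste(cs$leaf_order, collapse = ", "), "\n")
cat("Wrote results/group_comparison.csv, spearman_correlation.csv, dendrogram_order.json\n")
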
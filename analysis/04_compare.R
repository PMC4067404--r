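#!/usr/bin/env Rscript
# Stage 4: cross-tissue comparison on V(D)J recombinant usage — feature
# filtering, complete-linkage clustering of features and tissues on Pearson
# correlation distances, row-standardized heatmap values, and negative-
# binomial GLM likelihood-ratio tests of mucosal vs non-mucosal usage with
# BH FDR control.

library(tissuerep)

files <- list.files("results/annotations", pattern = "_unique\\.tsv$", full.names = TRUE)
anns <- lapply(files, read.delim, stringsAsFactors = FALSE)
names(anns) <- sub("_unique\\.tsv$", "", basename(files))
pooled <- do.call(rbind, anns)
dir.create("results/compare", showWarnings = FALSE)

u <- usage_frequencies(pooled, "vdj_combo")
mucosal <- c("small_intestine", "lung", "stomach")
groups <- ifelse(colnames(u$counts) %in% mucosal, "mucosal", "other")

cr <- compare_repertoires(u, group_labels = groups, min_total = 10, k = 50)
message(sprintf("%d of %d V(D)J recombinants kept after the low-count/low-variation filter",
                length(cr$kept_features), nrow(u$counts)))

write.csv(cbind(feature = rownames(cr$standardized_matrix),
                as.data.frame(round(cr$standardized_matrix, 3))),
          "results/compare/standardized_matrix.csv", row.names = FALSE)
writeLines(cluster_newick(cr$sample_tree), "results/compare/sample_tree.nwk")
writeLines(cluster_newick(cr$feature_tree), "results/compare/feature_tree.nwk")
message("tissue dendrogram (complete linkage, 1 - Pearson r):")
message(cluster_newick(cr$sample_tree))

write.csv(cr$diffexp, "results/compare/diffexp_mucosal_vs_other.csv", row.names = FALSE)
write.csv(cr$top_k, "results/compare/top50_fold_changes.csv", row.names = FALSE)
n_sig <- sum(cr$diffexp$q_value < 0.05, na.rm = TRUE)
message(sprintf("%d recombinants differ between mucosal and non-mucosal pools at FDR < 0.05",
                n_sig))
message("largest fold changes (log10):")
print(head(cr$top_k, 5))
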
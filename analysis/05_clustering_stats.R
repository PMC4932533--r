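#!/usr/bin/env Rscript

# Step 5: the clustering and statistics layer — K-means (K = 15) of
# log2(FPKM+1) over expressed genes, hierarchical subclustering of the
# group-A photoreceptor genes on their histone scores (9 subclusters),
# per-subcluster TF peak-occupancy fractions, and the bound-vs-unbound
# expression comparison (Welch t with point-biserial r).

suppressPackageStartupMessages(library(retinomark))

ds <- read_dataset("results/dataset")
dir.create("results/clustering", showWarnings = FALSE, recursive = TRUE)
grouping <- read.delim("results/expression/grouping.tsv")
expressed <- readLines("results/expression/expressed_genes.txt")

expr_mat <- log2(ds$fpkm[expressed, , drop = FALSE] + 1)
km <- kmeans_profiles(expr_mat, k = 15, seed = 1)
write.table(data.frame(gene_id = names(km$labels),
                       cluster = unname(km$labels)),
            "results/clustering/kmeans_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("K-means (K=15) over %d expressed genes; cluster sizes:\n",
            nrow(expr_mat)))
print(sort(table(km$labels), decreasing = TRUE))

a_ids <- grouping$gene_id[grouping$temporal_group == "A"]
marks <- c("H3K4me3", "H3K27me3")
hist_mat <- do.call(cbind, lapply(marks, function(mk) {
  s <- read.delim(sprintf("results/chip/scores_%s.tsv", mk),
                  check.names = FALSE)
  m <- as.matrix(s[match(a_ids, s$gene_id), -1])
  colnames(m) <- paste(mk, colnames(m), sep = ":")
  m
}))
rownames(hist_mat) <- a_ids
hist_mat <- hist_mat[complete.cases(hist_mat), , drop = FALSE]
sub <- hierarchical_subcluster(hist_mat, 9)
write.table(data.frame(gene_id = names(sub$labels),
                       subcluster = unname(sub$labels)),
            "results/clustering/groupA_subclusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d group-A genes split into 9 histone-score subclusters\n",
            nrow(hist_mat)))

rows <- list()
for (tf in names(ds$tf_peaks)) {
  occ_tab <- read.delim(sprintf("results/peaks/occupancy_%s.tsv", tf))
  occ <- setNames(occ_tab$occupied, occ_tab$gene_id)
  for (ci in sort(unique(sub$labels))) {
    ids <- names(sub$labels)[sub$labels == ci]
    rows[[paste(tf, ci)]] <- data.frame(
      tf = tf, subcluster = ci, n_genes = length(ids),
      occupancy_pct = peak_occupancy_fraction(ids, occ))
  }
}
occ_summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.table(occ_summary, "results/clustering/subcluster_occupancy.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPer-subcluster Nrl occupancy (%):\n")
print(occ_summary[occ_summary$tf == "Nrl", ])

# bound vs unbound group-A genes: P-fraction expression at P8. The
# generator plants TF binding independently of expression level, so this
# comparison is a null control here.
occ_nrl <- read.delim("results/peaks/occupancy_Nrl.tsv")
occ <- setNames(occ_nrl$occupied, occ_nrl$gene_id)
bound <- a_ids[occ[a_ids]]
unbound <- setdiff(a_ids, bound)
p8 <- log2(ds$fpkm[, sample_id("P8", "P")] + 1)
tt <- t_test_with_r(p8[bound], p8[unbound])
cat(sprintf("\nNrl-bound (n=%d) vs unbound (n=%d) group-A expression: t = %.2f, p = %.3f, r = %.3f\n",
            tt$n1, tt$n2, tt$statistic, tt$p_value, tt$r))
write.table(data.frame(comparison = "Nrl_bound_vs_unbound_P8_expression",
                       t = tt$statistic, df = tt$df, p_value = tt$p_value,
                       r = tt$r, n1 = tt$n1, n2 = tt$n2),
            "results/clustering/nrl_bound_expression_test.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
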
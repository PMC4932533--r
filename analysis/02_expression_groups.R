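#!/usr/bin/env Rscript

# Step 2: fold-change classification of the expression matrix — per-stage
# Cd73P/Cd73N specificity, temporal groups A-D, Ezh2-CKO up/down calls with
# their Venn partitions, the per-subtype regulation summary table, the
# expressed-gene filter, and the low-fold validation candidates.

suppressPackageStartupMessages(library(retinomark))

ds <- read_dataset("results/dataset")
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)
fpkm <- ds$fpkm

spec <- lapply(c(P2 = "P2", P5 = "P5", P8 = "P8"), function(st) {
  classify_fraction_specific(fpkm, st, fold = 1.5, pseudocount = 1)
})
groups <- assign_temporal_group(spec$P2, spec$P5, spec$P8)
cko <- lapply(c(P = "P", N = "N"), function(fr) {
  classify_cko_regulation(fpkm, fr, fold = 1.5, pseudocount = 1)
})

grouping <- data.frame(gene_id = rownames(fpkm),
                       spec_P2 = unname(spec$P2), spec_P5 = unname(spec$P5),
                       spec_P8 = unname(spec$P8),
                       temporal_group = unname(groups),
                       cko_P = unname(cko$P), cko_N = unname(cko$N))
write.table(grouping[order(grouping$gene_id), ],
            "results/expression/grouping.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Temporal groups called (vs planted):\n")
print(table(called = groups, planted = ds$truth$group))

genes <- rownames(fpkm)
up <- venn_partition(genes[cko$P == "up"], genes[cko$N == "up"])
down <- venn_partition(genes[cko$P == "down"], genes[cko$N == "down"])
cat(sprintf("\nCKO up: %d N-specific / %d common / %d P-specific\n",
            length(up$N_specific), length(up$common), length(up$P_specific)))

celltype <- lapply(ds$celltype_lists, function(g) {
  suppressMessages(celltype_relative_expression(fpkm, g))
})
for (ct in names(celltype)) {
  cat(sprintf("%s list: %d candidates -> %d retained as N-specific\n",
              ct, length(ds$celltype_lists[[ct]]),
              length(celltype[[ct]]$retained)))
}

subtypes <- c(
  lapply(stats::setNames(c("A", "B", "C", "D"),
                         paste0("Cd73P_", c("A", "B", "C", "D"))),
         function(g) genes[groups == g]),
  lapply(celltype, function(x) x$retained)
)
summ <- build_regulation_summary(subtypes, up, down)
write.table(summ, "results/expression/regulation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nRegulation summary (counts and integer percentages):\n")
print(summ)

expressed <- nonexpressed_filter(fpkm, threshold = 1)
cat(sprintf("\n%d of %d genes not expressed in any sample (%.1f%%)\n",
            length(expressed$not_expressed), nrow(fpkm),
            100 * length(expressed$not_expressed) / nrow(fpkm)))
writeLines(expressed$expressed, "results/expression/expressed_genes.txt")

cand <- select_validation_candidates(fpkm, subtypes$Cd73P_A, fold = 2.0)
cat(sprintf("%d group-A genes below 2.0-fold at >=2 stages (validation candidates)\n",
            length(cand)))
writeLines(cand, "results/expression/validation_candidates.txt")
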
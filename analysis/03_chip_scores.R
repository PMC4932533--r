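#!/usr/bin/env Rscript

# Step 3: the histone-modification score chain on every ChIP sample —
# 1050 bp windows sliding by 50 bp, tags-per-million input subtraction,
# floored log2, TSS +/-5 kb averaging, quantile normalization — followed by
# the Cd73PG-vs-Cd73NG signal comparisons (box plots + Kolmogorov-Smirnov)
# and the 10 kb H3K27me3 heatmap matrix with a browser track export.

suppressPackageStartupMessages(library(retinomark))

ds <- read_dataset("results/dataset")
dir.create("results/chip", showWarnings = FALSE, recursive = TRUE)
grouping <- read.delim("results/expression/grouping.tsv")

marks <- unique(vapply(strsplit(names(ds$chip), ":"), `[`, "", 1))
scores <- list()
for (mk in marks) {
  sel <- grep(paste0("^", mk, ":"), names(ds$chip), value = TRUE)
  scores[[mk]] <- score_matrix(ds$chip[sel], ds$annotation)
  colnames(scores[[mk]]) <- sub(paste0("^", mk, ":"), "", sel)
  m <- scores[[mk]]
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              sprintf("results/chip/scores_%s.tsv", mk), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes x %d samples scored\n", mk, nrow(m), ncol(m)))
}

pg <- grouping$gene_id[grouping$temporal_group %in% c("A", "B", "C", "D")]
ng <- grouping$gene_id[grouping$spec_P2 == "N" & grouping$spec_P5 == "N"]
cat(sprintf("\nCumulative TSS +/-5 kb signal, Cd73PG (n=%d) vs Cd73NG (n=%d):\n",
            length(pg), length(ng)))
rows <- list()
for (mk in marks) {
  for (cn in colnames(scores[[mk]])) {
    a <- scores[[mk]][pg, cn]; a <- a[!is.na(a)]
    b <- scores[[mk]][ng, cn]; b <- b[!is.na(b)]
    ks <- ks_two_sample(a, b)
    rows[[paste(mk, cn)]] <- data.frame(mark = mk, sample = cn,
                                        D = ks$statistic,
                                        p_value = ks$p_value)
    cat(sprintf("  %s %-5s  D = %.3f, p = %.3g\n", mk, cn, ks$statistic,
                ks$p_value))
  }
}
write.table(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            "results/chip/ks_pg_vs_ng.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

box <- boxplot_summary(list(
  PG_H3K4me3_P8 = scores$H3K4me3[pg, "P:P8"],
  NG_H3K4me3_P8 = scores$H3K4me3[ng, "P:P8"],
  PG_H3K27me3_P8 = scores$H3K27me3[pg, "P:P8"],
  NG_H3K27me3_P8 = scores$H3K27me3[ng, "P:P8"]))
write.table(box, "results/chip/signal_boxplots.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# H3K27me3 occupancy heatmap over 10 kb around the TSS of N-lineage genes,
# P fraction at P2, plus the genome-browser bedGraph of the log2 track
key <- grep("^H3K27me3:P:P2", names(ds$chip), value = TRUE)[1]
pr <- ds$chip[[key]]
track <- log2_transform(normalize_and_subtract(count_windows(pr$test),
                                               count_windows(pr$input)), 1)
heat <- tss_profile_matrix(track, ds$annotation, ng)
write.table(data.frame(gene_id = rownames(heat), heat, check.names = FALSE),
            "results/chip/h3k27me3_tss_heatmap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_bedgraph(track, "results/chip/h3k27me3_P_P2_log2.bedgraph")
cat(sprintf("\nHeatmap matrix: %d genes x %d bins; bedGraph track written\n",
            nrow(heat), ncol(heat)))
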
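#!/usr/bin/env Rscript

# Step 4: map the TF ChIP peak sets to genes — GREAT-style
# basal-plus-extension regulatory domains (5 kb up / 1 kb down basal,
# extension to 5 kb clipped at neighbouring basal domains), peak-to-gene
# assignment, and TSS +/-5 kb occupancy per gene.

suppressPackageStartupMessages(library(retinomark))

ds <- read_dataset("results/dataset")
dir.create("results/peaks", showWarnings = FALSE, recursive = TRUE)

domains <- build_regulatory_domains(ds$annotation)
write.table(domains, "results/peaks/regulatory_domains.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Built %d regulatory domains (median extended width %d bp)\n",
            nrow(domains),
            as.integer(median(domains$ext_end - domains$ext_start))))

for (tf in names(ds$tf_peaks)) {
  asg <- assign_peaks(ds$tf_peaks[[tf]], domains)
  write.table(asg, sprintf("results/peaks/assignments_%s.tsv", tf),
              sep = "\t", quote = FALSE, row.names = FALSE)
  occ <- tss_window_occupancy(ds$tf_peaks[[tf]], ds$annotation)
  write.table(data.frame(gene_id = names(occ), occupied = unname(occ)),
              sprintf("results/peaks/occupancy_%s.tsv", tf), sep = "\t",
              quote = FALSE, row.names = FALSE)
  planted <- ds$tf_bound[[tf]]
  cat(sprintf("%s: %d peaks, %d assigned; occupancy of planted bound set %.1f%%, of all genes %.1f%%\n",
              tf, length(ds$tf_peaks[[tf]]),
              sum(!is.na(asg$gene_id)),
              peak_occupancy_fraction(planted, occ),
              100 * mean(occ)))
}
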
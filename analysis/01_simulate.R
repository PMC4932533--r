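#!/usr/bin/env Rscript

# Step 1: generate the synthetic retina dataset the rest of the workflow
# analyses — annotation, planted FPKM matrix, H3K4me3/H3K27me3 tag tracks
# with matched inputs, TF peak sets, cell-type gene lists — and persist it
# with a checksummed manifest under results/dataset/.

suppressPackageStartupMessages(library(retinomark))

cfg <- sim_config(seed = 1L)
print(cfg)

ds <- simulate_dataset(cfg)
manifest <- write_dataset(ds, "results/dataset")

tab <- table(ds$truth$group)
cat("\nPlanted gene groups:\n")
print(tab)
cat(sprintf("\nChIP samples: %d (paired with %d shared inputs)\n",
            length(ds$chip), 6))
cat(sprintf("TF peak sets: %s\n",
            paste(sprintf("%s=%d", names(ds$tf_peaks),
                          lengths(ds$tf_peaks)), collapse = ", ")))
cat(sprintf("Wrote %d files to results/dataset (see manifest.json)\n",
            length(manifest$files)))
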
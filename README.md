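# retinomark

Lineage-resolved analysis of transcription and histone methylation in the
developing mouse retina.

During postnatal retinogenesis, rod photoreceptors can be FACS-sorted from
the other retinal cells by Cd73 surface expression, giving a Cd73-positive
(P, photoreceptor-lineage) and a Cd73-negative (N, interneurons / Müller
glia / RGC) fraction at each stage. `retinomark` implements the
computational pipeline for studying how gene expression and the
H3K4me3 (activating) / H3K27me3 (Polycomb-repressive) marks diverge between
these lineages at P2/P5/P8, and how expression responds to conditional
knockout of the H3K27 methyltransferase Ezh2:

* **Fold-change gene grouping** — a gene is fraction-specific at a stage iff
  `(FPKM_P + 1) / (FPKM_N + 1) > 1.5` (strict, pseudocounted); the pattern
  of P-calls over (P2, P5, P8) defines temporal groups A = (P,P,P),
  B = (–,P,P), C = (–,–,P), D = (P,–,–). The same 1.5-fold rule on P12
  CKO-vs-control calls knockout regulation, summarized per subtype as a
  Table-1-style count/percentage matrix.
* **Histone-modification score** — per sample, 1050 bp windows sliding by
  50 bp are tag-counted, scaled to tags-per-million, input-subtracted,
  floored-log2-transformed (`log2(max(v, 0) + c0)`), averaged over windows
  whose midpoint falls in TSS ± 5 kb, and quantile-normalized across
  samples into a gene × sample score matrix. TSS metaprofile/heatmap
  matrices and bedGraph browser tracks come from the same window track.
* **GREAT-style peak assignment** — basal domain 5 kb up / 1 kb down of the
  TSS, extension up to 5 kb clipped at neighbouring basal domains; plus
  simple TSS ± 5 kb peak occupancy and per-subcluster occupancy fractions.
* **Clustering & statistics** — K-means (k-means++/Lloyd, K = 15) of
  log2(FPKM+1), hierarchical (Euclidean/average) subclustering of histone
  scores, two-sample Kolmogorov–Smirnov, Welch *t* with point-biserial *r*,
  box-plot summaries.
* **A synthetic-data generator** — log-normal FPKM with planted
  fraction/stage/knockout structure realized by construction, Poisson ChIP
  tag tracks with sharp-TSS / TSS-domain / blanket enrichment kernels, and
  TF peak sets with known bound genes — so the whole workflow runs offline
  with a testable ground truth.

The methods vignette (`vignettes/retinal-histone-workflow.Rmd`) documents
the model, every tunable parameter, and the design decisions in detail.

## Worked example

Simulate the default study (2,000 genes, two 10 Mb chromosomes, P/N
fractions at P2/P5/P8, P12 control/CKO, twelve ChIP samples with matched
inputs), classify genes, and compare promoter H3K4me3 between the
photoreceptor-lineage genes (Cd73PG) and the N-lineage genes (Cd73NG):

```r
library(retinomark)

ds <- simulate_dataset(sim_config(seed = 1))

spec <- lapply(c(P2 = "P2", P5 = "P5", P8 = "P8"),
               function(st) classify_fraction_specific(ds$fpkm, st))
groups <- assign_temporal_group(spec$P2, spec$P5, spec$P8)
table(groups)
#> groups
#>          A          B          C          D unassigned
#>        200         99        100        100       1501

k4 <- score_matrix(ds$chip[grep("^H3K4me3:", names(ds$chip))],
                   ds$annotation)
pg <- names(groups)[groups %in% c("A", "B", "C", "D")]
ng <- ds$truth$gene_id[ds$truth$group == "N"]
ks_two_sample(k4[pg, 5], k4[ng, 5])   # P fraction at P8
#> D = 0.551, p = 5.09e-38  (n = 499 vs 200)
```

The 500 genes planted into groups A–D are recovered almost perfectly (499
called; the one missed group-B gene has a baseline so low that the
pseudocount neutralizes its ratio), and the planted sharp-TSS H3K4me3 at
photoreceptor genes separates the two gene sets with D = 0.55 in the P
fraction at P8.

The `analysis/` directory holds the end-to-end workflow as numbered
drivers, each a thin narrative over the package functions, writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # dataset + manifest
Rscript analysis/02_expression_groups.R # specificity, groups, CKO summary
Rscript analysis/03_chip_scores.R       # score matrices, KS, heatmap, tracks
Rscript analysis/04_peak_annotation.R   # GREAT domains, assignment, occupancy
Rscript analysis/05_clustering_stats.R  # K-means, subclusters, t/r tests
```

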
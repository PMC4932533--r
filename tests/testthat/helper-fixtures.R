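# Shared fixtures: small configs, hand-built annotations/matrices, and
# independent oracles used across tests.

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 5e5,
               n_genes = 40L, gene_length = 1000L, gene_spacing = 8000L,
               group_sizes = c(A = 8L, B = 4L, C = 4L, D = 4L, N = 8L),
               silent_fraction = 0.1, background_rate = 0.02)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# annotation data.frame with a chrom_sizes attribute, hand-specified
mk_ann <- function(gene_id, chrom, strand, tss, sizes,
                   start = NULL, end = NULL) {
  if (is.null(start)) start <- ifelse(strand == "+", tss, tss - 1000)
  if (is.null(end)) end <- ifelse(strand == "+", tss + 1000, tss)
  ann <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    start = start, end = end, tss = tss,
                    stringsAsFactors = FALSE)
  attr(ann, "chrom_sizes") <- sizes
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

# expression matrix with "stage:fraction:genotype" columns
mk_expr <- function(genes, ...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  m
}

# brute-force window counter: O(tags x windows)
brute_count_windows <- function(positions, chrom_len, window, step) {
  nw <- if (chrom_len < window) 0L else floor((chrom_len - window) / step) + 1
  vapply(seq_len(nw), function(i) {
    s <- (i - 1) * step
    sum(positions >= s & positions < s + window)
  }, numeric(1))
}

# brute-force quantile normalization (rank-and-average), tie-free columns
brute_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(x) ref[rank(x)])
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# full scoring-chain brute force used by the oracle-equivalence checks:
# window counts, per-million subtraction, floored log2, midpoint-mean per
# gene, computed with plain loops
brute_histone_score <- function(test_pos, input_pos, chrom_len, ann,
                                window = 1050, step = 50, flank = 5000,
                                floor_c = 1, scale = 1e6,
                                test_total = length(test_pos),
                                input_total = length(input_pos)) {
  ct <- brute_count_windows(test_pos, chrom_len, window, step)
  ci <- brute_count_windows(input_pos, chrom_len, window, step)
  sub <- scale * ct / test_total - scale * ci / input_total
  lg <- log2(pmax(sub, 0) + floor_c)
  mids <- (seq_along(lg) - 1) * step + window / 2
  out <- vapply(seq_len(nrow(ann)), function(g) {
    keep <- mids >= ann$tss[g] - flank & mids < ann$tss[g] + flank
    if (!any(keep)) NA_real_ else mean(lg[keep])
  }, numeric(1))
  stats::setNames(out, ann$gene_id)
}
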
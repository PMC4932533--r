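# Fold-change-based gene classification: fraction specificity per stage,
# temporal groups A-D, knockout regulation calls, and Table-1-style
# summaries. The rule throughout is a pure fold-change filter (strict ">")
# on pseudocounted FPKM ratios; no dispersion modelling or p-values.

expr_column <- function(expr, stage, fraction, genotype = "control") {
  id <- sample_id(stage, fraction, genotype)
  if (!id %in% colnames(expr)) {
    stop(sprintf("missing sample column '%s' in expression matrix", id),
         call. = FALSE)
  }
  expr[, id]
}

#' Classify genes as fraction-specific at one stage
#'
#' A gene is called `P` if `(FPKM_P + c) / (FPKM_N + c) > fold`, `N` if the
#' reciprocal ratio exceeds `fold`, and `none` otherwise. The pseudocount
#' keeps zero-FPKM genes finite; the inequality is strict, so a ratio of
#' exactly `fold` is `none`.
#'
#' @param expr Gene x sample FPKM matrix with `"stage:fraction:genotype"`
#'   column names.
#' @param stage Stage with both `P` and `N` control samples (e.g. `"P2"`).
#' @param fold Fold-change threshold (> 1); default 1.5.
#' @param pseudocount Pseudocount `c` added to numerator and denominator
#'   (FPKM units); default 1.
#' @return Character vector (`"P"`, `"N"`, `"none"`) named by gene.
#' @export
classify_fraction_specific <- function(expr, stage, fold = 1.5,
                                       pseudocount = 1) {
  stopifnot(fold > 1, pseudocount >= 0)
  p <- expr_column(expr, stage, "P") + pseudocount
  n <- expr_column(expr, stage, "N") + pseudocount
  lab <- rep("none", nrow(expr))
  lab[p / n > fold] <- "P"
  lab[n / p > fold] <- "N"
  stats::setNames(lab, rownames(expr))
}

#' Assign temporal groups A-D from per-stage specificity
#'
#' Groups are the four exclusive patterns of P-fraction specificity across
#' P2/P5/P8: `A` = P at all three stages; `B` = P at P5 and P8 but not P2;
#' `C` = P at P8 only; `D` = P at P2 only. Any other pattern (including
#' no P call anywhere) is `unassigned`.
#'
#' @param spec_p2,spec_p5,spec_p8 Per-stage labels from
#'   [classify_fraction_specific()], aligned by gene.
#' @return Character vector of group labels named by gene.
#' @export
assign_temporal_group <- function(spec_p2, spec_p5, spec_p8) {
  stopifnot(length(spec_p2) == length(spec_p5),
            length(spec_p5) == length(spec_p8))
  p2 <- spec_p2 == "P"; p5 <- spec_p5 == "P"; p8 <- spec_p8 == "P"
  out <- rep("unassigned", length(p2))
  out[p2 & p5 & p8] <- "A"
  out[!p2 & p5 & p8] <- "B"
  out[!p2 & !p5 & p8] <- "C"
  out[p2 & !p5 & !p8] <- "D"
  stats::setNames(out, names(spec_p2))
}

#' Call knockout regulation per gene
#'
#' A gene is `up` if `(FPKM_CKO + c) / (FPKM_control + c) > fold`, `down` if
#' the reciprocal exceeds `fold`, else `unchanged`; evaluated on the P12
#' samples of one fraction.
#'
#' @inheritParams classify_fraction_specific
#' @param fraction `"P"` or `"N"`.
#' @param stage Stage carrying the control/CKO contrast; default `"P12"`.
#' @return Character vector (`"up"`, `"down"`, `"unchanged"`) named by gene.
#' @export
classify_cko_regulation <- function(expr, fraction, fold = 1.5,
                                    pseudocount = 1, stage = "P12") {
  stopifnot(fold > 1, pseudocount >= 0)
  ctrl <- expr_column(expr, stage, fraction, "control") + pseudocount
  cko <- expr_column(expr, stage, fraction, "CKO") + pseudocount
  lab <- rep("unchanged", nrow(expr))
  lab[cko / ctrl > fold] <- "up"
  lab[ctrl / cko > fold] <- "down"
  stats::setNames(lab, rownames(expr))
}

#' Partition two gene sets into Venn regions
#'
#' @param calls_P,calls_N Character vectors of gene ids (e.g. genes called
#'   up in each fraction).
#' @return `list(N_specific, common, P_specific)` of disjoint gene-id
#'   vectors whose union is `calls_P` and `calls_N` combined.
#' @export
venn_partition <- function(calls_P, calls_N) {
  calls_P <- unique(calls_P); calls_N <- unique(calls_N)
  list(N_specific = setdiff(calls_N, calls_P),
       common = intersect(calls_P, calls_N),
       P_specific = setdiff(calls_P, calls_N))
}

#' Tabulate knockout regulation per gene subtype
#'
#' For each subtype gene list, counts its overlap with the N-specific,
#' common, and P-specific regions of the up- and down-regulated Venn
#' partitions, plus integer percentages of the subtype size (rounded half
#' away from zero).
#'
#' @param subtypes Named list of gene-id vectors (e.g. `Cd73P_A` ... plus
#'   cell-type lists).
#' @param up,down Venn partitions from [venn_partition()] of the up- and
#'   down-regulated calls in the two fractions.
#' @return Data frame, one row per subtype: `gene_number`, then
#'   `{up,down}_{N_specific,common,P_specific}_{n,pct}`.
#' @export
build_regulation_summary <- function(subtypes, up, down) {
  stopifnot(is.list(subtypes), !is.null(names(subtypes)))
  regions <- c("N_specific", "common", "P_specific")
  rows <- lapply(names(subtypes), function(nm) {
    genes <- unique(subtypes[[nm]])
    total <- length(genes)
    row <- list(subtype = nm, gene_number = total)
    for (dir in c("up", "down")) {
      part <- if (dir == "up") up else down
      for (reg in regions) {
        cnt <- length(intersect(genes, part[[reg]]))
        row[[paste(dir, reg, "n", sep = "_")]] <- cnt
        row[[paste(dir, reg, "pct", sep = "_")]] <- percentage_of(cnt, total)
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative N/P expression of a cell-type gene list, clustered
#'
#' Computes each listed gene's pseudocounted Cd73N/Cd73P FPKM ratio at
#' P2/P5/P8, clusters the log2 ratio profiles hierarchically, and retains
#' only clusters whose mean linear N/P ratio exceeds 1 at one or more
#' postnatal stages (i.e. drops clusters without N-fraction-specific
#' expression). Genes absent from the matrix are reported and skipped.
#'
#' @inheritParams classify_fraction_specific
#' @param genes Character vector of candidate cell-type genes.
#' @param n_clusters Number of clusters to cut the tree into.
#' @param stages Postnatal stages used for the profile.
#' @return List with `profile` (gene x stage matrix of linear N/P ratios),
#'   `cluster` (labels for all profiled genes), `retained` (gene ids in
#'   retained clusters), and `missing` (ids absent from the matrix).
#' @export
celltype_relative_expression <- function(expr, genes, n_clusters = 3,
                                         stages = c("P2", "P5", "P8"),
                                         pseudocount = 1) {
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    message("celltype_relative_expression: skipping ", length(missing),
            " gene(s) absent from the matrix")
  }
  genes <- intersect(genes, rownames(expr))
  ratio <- sapply(stages, function(st) {
    (expr_column(expr, st, "N")[match(genes, rownames(expr))] + pseudocount) /
      (expr_column(expr, st, "P")[match(genes, rownames(expr))] + pseudocount)
  })
  if (length(genes) == 0L) {
    return(list(profile = matrix(numeric(), 0, length(stages),
                                 dimnames = list(NULL, stages)),
                cluster = integer(), retained = character(),
                missing = missing))
  }
  ratio <- matrix(ratio, nrow = length(genes),
                  dimnames = list(genes, stages))
  k <- min(n_clusters, length(genes))
  if (length(genes) == 1L) {
    cl <- stats::setNames(1L, genes)
  } else {
    hc <- stats::hclust(stats::dist(log2(ratio)), method = "average")
    cl <- stats::cutree(hc, k = k)
  }
  keep_cluster <- vapply(seq_len(k), function(ci) {
    any(colMeans(ratio[cl == ci, , drop = FALSE]) > 1)
  }, logical(1))
  list(profile = ratio, cluster = cl,
       retained = genes[keep_cluster[cl]], missing = missing)
}

#' Select low-fold group-A genes for validation
#'
#' Returns the group-A genes whose pseudocounted P/N ratio falls below
#' `fold` (default 2.0) at two or more of the three postnatal stages — the
#' borderline calls worth re-testing by qPCR.
#'
#' @inheritParams classify_fraction_specific
#' @param group_a_genes Character vector of group-A gene ids.
#' @param stages Postnatal stages examined.
#' @return Character vector of selected gene ids.
#' @export
select_validation_candidates <- function(expr, group_a_genes, fold = 2.0,
                                         stages = c("P2", "P5", "P8"),
                                         pseudocount = 1) {
  group_a_genes <- intersect(unique(group_a_genes), rownames(expr))
  if (!length(group_a_genes)) return(character())
  idx <- match(group_a_genes, rownames(expr))
  low <- sapply(stages, function(st) {
    r <- (expr_column(expr, st, "P")[idx] + pseudocount) /
      (expr_column(expr, st, "N")[idx] + pseudocount)
    r < fold
  })
  low <- matrix(low, nrow = length(group_a_genes))
  group_a_genes[rowSums(low) >= 2]
}

#' Flag genes not expressed in any sample
#'
#' A gene is flagged not-expressed when its maximum FPKM across all samples
#' is below `threshold`; such genes are excluded from clustering.
#'
#' @inheritParams classify_fraction_specific
#' @param threshold FPKM floor; default 1.
#' @return List with `expressed` and `not_expressed` gene-id vectors.
#' @export
nonexpressed_filter <- function(expr, threshold = 1) {
  mx <- apply(expr, 1, max)
  list(expressed = rownames(expr)[mx >= threshold],
       not_expressed = rownames(expr)[mx < threshold])
}
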
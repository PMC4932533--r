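# Synthetic FPKM matrix with planted fraction-specific, temporal, and
# knockout structure.

#' Sample descriptor helpers
#'
#' Sample columns are identified as `"stage:fraction:genotype"`, e.g.
#' `"P2:P:control"` or `"P12:N:CKO"`. `retina_samples()` lists the full
#' simulated design: whole retina at E15/E18, Cd73 P/N fractions at P2/P5/P8,
#' and a P12 control-vs-CKO contrast in both fractions.
#'
#' @param stage,fraction,genotype Descriptor fields.
#' @return `sample_id()` a character id; `retina_samples()` a data.frame with
#'   columns `stage`, `fraction`, `genotype`, `sample`.
#' @export
sample_id <- function(stage, fraction, genotype = "control") {
  paste(stage, fraction, genotype, sep = ":")
}

#' @rdname sample_id
#' @export
retina_samples <- function() {
  s <- rbind(
    data.frame(stage = c("E15", "E18"), fraction = "whole",
               genotype = "control"),
    expand.grid(fraction = c("P", "N"), stage = c("P2", "P5", "P8"),
                genotype = "control", stringsAsFactors = FALSE)[,
                c("stage", "fraction", "genotype")],
    expand.grid(genotype = c("control", "CKO"), fraction = c("P", "N"),
                stage = "P12", stringsAsFactors = FALSE)[,
                c("stage", "fraction", "genotype")]
  )
  s$sample <- sample_id(s$stage, s$fraction, s$genotype)
  rownames(s) <- NULL
  s
}

# Per-stage specificity pattern implied by each planted group.
group_spec_pattern <- function(group, stage) {
  p_stages <- switch(group,
    A = c("P2", "P5", "P8"),
    B = c("P5", "P8"),
    C = "P8",
    D = "P2",
    character()
  )
  if (group == "N") return("N")
  if (stage %in% p_stages) "P" else "none"
}

#' Simulate the FPKM expression matrix
#'
#' Draws a gene x sample FPKM matrix (linear scale) with known planted
#' structure. Baseline abundance is log-normal per gene; a configured
#' fraction of genes is silent (0 FPKM everywhere). At each postnatal stage,
#' genes planted P- (or N-) specific realize a P/N ratio of at least
#' `fold_planted`, while unspecific stages draw a symmetric log-ratio
#' truncated at `null_fold_max`, so every planted label is true of the
#' emitted matrix by construction. The P12 knockout contrast is planted the
#' same way per fraction.
#'
#' @param cfg A [sim_config()].
#' @param annotation Annotation from [generate_annotation()]; supplies gene
#'   ids (its gene count must equal `cfg$n_genes`).
#' @return A list with `fpkm` (gene x sample matrix, columns ordered as
#'   [retina_samples()]) and `truth` (data.frame: `gene_id`, `group`
#'   in A/B/C/D/N/background/silent, per-stage specificity `spec_P2/P5/P8`,
#'   and knockout calls `cko_P`, `cko_N`).
#' @export
simulate_expression <- function(cfg, annotation) {
  cfg <- validate_sim_config(cfg)
  n <- nrow(annotation)
  if (n != cfg$n_genes) {
    stop("simulate_expression: annotation gene count differs from cfg$n_genes")
  }
  samples <- retina_samples()
  fpkm <- matrix(0, nrow = n, ncol = nrow(samples),
                 dimnames = list(annotation$gene_id, samples$sample))
  truth <- data.frame(gene_id = annotation$gene_id,
                      group = rep("background", n),
                      spec_P2 = rep("none", n), spec_P5 = rep("none", n),
                      spec_P8 = rep("none", n), cko_P = rep("unchanged", n),
                      cko_N = rep("unchanged", n),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(fpkm = fpkm, truth = truth))
  }

  withr::with_seed(cfg$seed + 1L, {
    # --- planted membership -------------------------------------------------
    perm <- sample.int(n)
    gs <- cfg$group_sizes
    at <- 0L
    for (g in names(gs)) {
      k <- as.integer(gs[[g]])
      if (k > 0L) truth$group[perm[at + seq_len(k)]] <- g
      at <- at + k
    }
    n_silent <- round(cfg$silent_fraction * n)
    if (n_silent > 0L) truth$group[perm[at + seq_len(n_silent)]] <- "silent"

    baseline <- exp(stats::rnorm(n, cfg$fpkm_log_mean, cfg$fpkm_log_sd))
    baseline[truth$group == "silent"] <- 0

    bound <- log(cfg$null_fold_max)
    sd2 <- sqrt(2) * cfg$noise_sd

    # Draw a P/N (or control/CKO) pair per gene honouring planted labels.
    draw_pair <- function(spec) {
      v <- baseline * exp(stats::rnorm(n, 0, cfg$noise_sd))
      lam <- rnorm_trunc(n, sd2, bound)
      hi <- v * exp(lam / 2)
      lo <- v * exp(-lam / 2)
      up <- v * cfg$fold_planted * exp(abs(stats::rnorm(n, 0, cfg$noise_sd)))
      p_val <- ifelse(spec == "P", up, ifelse(spec == "N", v, hi))
      n_val <- ifelse(spec == "P", v, ifelse(spec == "N", up, lo))
      list(P = p_val, N = n_val)
    }

    # --- embryonic whole retina --------------------------------------------
    for (st in c("E15", "E18")) {
      fpkm[, sample_id(st, "whole")] <-
        baseline * exp(stats::rnorm(n, 0, cfg$noise_sd))
    }

    # --- postnatal P/N fractions -------------------------------------------
    for (st in c("P2", "P5", "P8")) {
      spec <- vapply(truth$group, group_spec_pattern, character(1), stage = st)
      truth[[paste0("spec_", st)]] <- unname(spec)
      pair <- draw_pair(spec)
      fpkm[, sample_id(st, "P")] <- pair$P
      fpkm[, sample_id(st, "N")] <- pair$N
    }

    # --- P12 knockout contrast ---------------------------------------------
    for (fr in c("P", "N")) {
      u <- stats::runif(n)
      call <- ifelse(u < cfg$cko_up_fraction, "up",
                     ifelse(u < cfg$cko_up_fraction + cfg$cko_down_fraction,
                            "down", "unchanged"))
      call[truth$group == "silent"] <- "unchanged"
      truth[[paste0("cko_", fr)]] <- call
      # reuse the pair sampler: "P" slot plays CKO-up, "N" slot control
      spec <- ifelse(call == "up", "P", ifelse(call == "down", "N", "none"))
      pair <- draw_pair(spec)
      fpkm[, sample_id("P12", fr, "control")] <- pair$N
      fpkm[, sample_id("P12", fr, "CKO")] <- pair$P
    }
  })

  list(fpkm = fpkm, truth = truth)
}

#' Read/write an FPKM matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns named
#' `"stage:fraction:genotype"`.
#'
#' @param fpkm Gene x sample matrix.
#' @param path File path.
#' @export
write_fpkm <- function(fpkm, path) {
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fpkm
#' @export
read_fpkm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
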
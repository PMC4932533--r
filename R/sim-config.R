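#' Configuration for the synthetic retina dataset generator
#'
#' Bundles every knob of the simulator: genome geometry, planted gene-group
#' sizes, the log-normal expression model, the Poisson ChIP tag model, and the
#' transcription-factor peak placement. Defaults emulate the study design the
#' pipeline targets at desk scale: two Cd73 fractions (P = photoreceptor
#' lineage, N = other retinal cells) sampled at P2/P5/P8, whole retina at
#' E15/E18, and a P12 control-vs-Ezh2-CKO contrast, over ~2,000 genes of which
#' roughly a third are silent.
#'
#' @param seed Integer seed; every generator call derives its randomness from
#'   it, so identical configs give byte-identical outputs.
#' @param n_chroms,chrom_length Number of chromosomes and their common length
#'   in bp.
#' @param n_genes Number of genes laid out across the genome.
#' @param gene_length,gene_spacing Gene body length and minimum intergenic gap
#'   (bp); genes are placed non-overlapping on a regular grid.
#' @param group_sizes Named integer vector of planted group sizes. `A`-`D` are
#'   the temporal photoreceptor groups (P-fraction-specific at P2+P5+P8,
#'   P5+P8, P8 only, P2 only respectively); `N` is an N-fraction-specific
#'   group at all three stages (the Cd73NG pool from which cell-type lists
#'   are drawn). Remaining non-silent genes are unspecific background.
#' @param silent_fraction Fraction of genes with 0 FPKM in every sample.
#' @param fold_planted Realized specificity ratio at planted stages (> 1).
#' @param null_fold_max Upper bound on the realized P/N (or CKO/control)
#'   ratio at non-specific stages; the symmetric truncation that makes
#'   planted "none" labels true by construction.
#' @param fpkm_log_mean,fpkm_log_sd Natural-log mean and across-gene spread of
#'   the baseline FPKM (log-normal).
#' @param noise_sd Per-observation log-normal measurement noise.
#' @param background_rate ChIP background tag density (tags per bp).
#' @param enrichment_fold Tag-density fold over background inside the
#'   enrichment kernel at target genes.
#' @param peak_shape Default enrichment kernel: `"sharp_tss"` (+/-500 bp of
#'   TSS, H3K4me3-like), `"tss_domain"` (+/-2.5 kb, promoter H3K27me3-like),
#'   or `"blanket"` (gene body +/-5 kb, broad weak H3K27me3).
#' @param n_tags_test,n_tags_input Background tag totals for test and input
#'   tracks; `NULL` means `round(background_rate * genome_length)`.
#' @param cko_up_fraction,cko_down_fraction Per-fraction probabilities that a
#'   non-silent gene is planted up- or down-regulated in the knockout.
#' @param tf_peak_radius Half-width (bp) of the window around the TSS within
#'   which TF peaks are placed (must be <= 5000 so peaks stay inside the
#'   +/-5 kb association window).
#' @param tf_peak_width Length-2 integer range of simulated peak widths (bp).
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e7,
                       n_genes = 2000L,
                       gene_length = 2000L,
                       gene_spacing = 5000L,
                       group_sizes = c(A = 200L, B = 100L, C = 100L,
                                       D = 100L, N = 200L),
                       silent_fraction = 0.35,
                       fold_planted = 3,
                       null_fold_max = 1.5,
                       fpkm_log_mean = 2,
                       fpkm_log_sd = 1,
                       noise_sd = 0.3,
                       background_rate = 0.005,
                       enrichment_fold = 8,
                       peak_shape = c("sharp_tss", "tss_domain", "blanket"),
                       n_tags_test = NULL,
                       n_tags_input = NULL,
                       cko_up_fraction = 0.07,
                       cko_down_fraction = 0.03,
                       tf_peak_radius = 1000L,
                       tf_peak_width = c(200L, 600L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    gene_spacing = as.integer(gene_spacing),
    group_sizes = group_sizes,
    silent_fraction = silent_fraction,
    fold_planted = fold_planted,
    null_fold_max = null_fold_max,
    fpkm_log_mean = fpkm_log_mean,
    fpkm_log_sd = fpkm_log_sd,
    noise_sd = noise_sd,
    background_rate = background_rate,
    enrichment_fold = enrichment_fold,
    peak_shape = match.arg(peak_shape),
    n_tags_test = if (is.null(n_tags_test)) NULL else as.numeric(n_tags_test),
    n_tags_input = if (is.null(n_tags_input)) NULL else as.numeric(n_tags_input),
    cko_up_fraction = cko_up_fraction,
    cko_down_fraction = cko_down_fraction,
    tf_peak_radius = as.integer(tf_peak_radius),
    tf_peak_width = as.integer(tf_peak_width)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("n_chroms", "chrom_length", "gene_length", "gene_spacing",
           "fold_planted", "null_fold_max")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop(sprintf("sim_config: '%s' must be a positive scalar", f),
           call. = FALSE)
    }
  }
  if (cfg$n_genes < 0) stop("sim_config: 'n_genes' must be >= 0", call. = FALSE)
  if (cfg$fold_planted <= 1) {
    stop("sim_config: 'fold_planted' must be > 1", call. = FALSE)
  }
  if (cfg$null_fold_max <= 1) {
    stop("sim_config: 'null_fold_max' must be > 1", call. = FALSE)
  }
  gs <- cfg$group_sizes
  if (length(gs) && (is.null(names(gs)) || any(!names(gs) %in%
                                               c("A", "B", "C", "D", "N")))) {
    stop("sim_config: 'group_sizes' names must be among A, B, C, D, N",
         call. = FALSE)
  }
  if (any(gs < 0)) stop("sim_config: group sizes must be >= 0", call. = FALSE)
  if (cfg$silent_fraction < 0 || cfg$silent_fraction > 1) {
    stop("sim_config: 'silent_fraction' must lie in [0, 1]", call. = FALSE)
  }
  n_silent <- round(cfg$silent_fraction * cfg$n_genes)
  if (sum(gs) + n_silent > cfg$n_genes) {
    stop("sim_config: group_sizes plus silent genes exceed n_genes",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$fpkm_log_sd < 0) {
    stop("sim_config: noise/baseline sd must be >= 0", call. = FALSE)
  }
  if (cfg$background_rate < 0 || cfg$enrichment_fold <= 0) {
    stop("sim_config: invalid ChIP tag parameters", call. = FALSE)
  }
  for (f in c("cko_up_fraction", "cko_down_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("sim_config: '%s' must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (cfg$cko_up_fraction + cfg$cko_down_fraction > 1) {
    stop("sim_config: CKO up + down fractions exceed 1", call. = FALSE)
  }
  if (cfg$tf_peak_radius <= 0 || cfg$tf_peak_radius > 5000L) {
    stop("sim_config: 'tf_peak_radius' must lie in (0, 5000]", call. = FALSE)
  }
  if (length(cfg$tf_peak_width) != 2L || any(cfg$tf_peak_width <= 0) ||
      cfg$tf_peak_width[1] > cfg$tf_peak_width[2]) {
    stop("sim_config: 'tf_peak_width' must be an increasing positive pair",
         call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chrom(s) x %s bp, %d genes (%d bp, %d bp spacing)\n",
              x$n_chroms, format(x$chrom_length, big.mark = ","), x$n_genes,
              x$gene_length, x$gene_spacing))
  cat(sprintf("  groups: %s; silent fraction %.2f\n",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "), x$silent_fraction))
  cat(sprintf("  expression: baseline lnN(%.2f, %.2f), noise sd %.2f, planted fold %.1f\n",
              x$fpkm_log_mean, x$fpkm_log_sd, x$noise_sd, x$fold_planted))
  cat(sprintf("  ChIP: background %.4f tags/bp, enrichment x%.1f (%s)\n",
              x$background_rate, x$enrichment_fold, x$peak_shape))
  invisible(x)
}
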
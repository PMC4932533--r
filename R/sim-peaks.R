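#' Simulate transcription-factor ChIP peaks near bound genes
#'
#' Places one peak of 200-600 bp (configurable) fully inside a window of
#' `cfg$tf_peak_radius` bp around each bound gene's TSS. With the default
#' 1 kb radius and default gene spacing, planted peaks stay inside their own
#' gene's +/-5 kb TSS window and outside every other gene's, so the planted
#' bound set is exactly recoverable by [tss_window_occupancy()].
#'
#' @param cfg A [sim_config()].
#' @param annotation Annotation from [generate_annotation()].
#' @param bound_genes Character vector of bound gene ids.
#' @param seed Seed for peak placement; defaults to `cfg$seed + 5`.
#' @param label Source-factor label stored in the peak names.
#' @return A BED-sorted `GRanges` of peaks (1-based closed, as GRanges
#'   convention; exported BED files are 0-based half-open) with metadata
#'   columns `name` (peak id) and `gene_id` (the planted target).
#' @export
simulate_tf_peaks <- function(cfg, annotation, bound_genes,
                              seed = cfg$seed + 5L, label = "TF") {
  cfg <- validate_sim_config(cfg)
  stopifnot(all(bound_genes %in% annotation$gene_id))
  sizes <- chrom_sizes(annotation)
  seqinfo <- GenomeInfoDb::Seqinfo(names(sizes), unname(sizes))
  targets <- annotation[annotation$gene_id %in% bound_genes, , drop = FALSE]
  if (nrow(targets) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = seqinfo)
    gr$name <- character()
    gr$gene_id <- character()
    return(gr)
  }
  withr::with_seed(as.integer(seed), {
    w <- cfg$tf_peak_width
    width <- floor(stats::runif(nrow(targets), w[1], w[2] + 1))
    span <- 2 * cfg$tf_peak_radius - width
    start0 <- targets$tss - cfg$tf_peak_radius +
      floor(stats::runif(nrow(targets)) * pmax(span, 1))
    start0 <- pmax(0, pmin(start0, sizes[targets$chrom] - width))
    gr <- GenomicRanges::GRanges(
      targets$chrom, IRanges::IRanges(start = start0 + 1, width = width),
      seqinfo = seqinfo
    )
    gr$name <- sprintf("%s_peak_%04d", label, seq_len(nrow(targets)))
    gr$gene_id <- targets$gene_id
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
}

#' Read/write peak sets as BED
#'
#' @param peaks A `GRanges` of peaks.
#' @param path BED file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' @rdname write_peaks_bed
#' @param chrom_sizes Optional named chromosome lengths to attach.
#' @export
read_peaks_bed <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
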
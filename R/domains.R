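# GREAT-style basal-plus-extension regulatory domains and peak-to-gene
# assignment. All stored coordinates are 0-based half-open; GRanges objects
# built for overlap queries use the usual 1-based closed convention.

#' Build basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-oriented basal domain (`basal_up` bp upstream to
#' `basal_down` bp downstream of the TSS) and an extended domain reaching up
#' to `max_ext` bp from the TSS on each side. Extension is clipped at the
#' nearest neighbouring basal domain boundary (regardless of strand) and at
#' chromosome edges; a gene's own basal domain is never clipped.
#'
#' @param annotation Gene annotation (`gene_id`, `chrom`, `strand`, `tss`),
#'   with a `chrom_sizes` attribute.
#' @param basal_up,basal_down Basal span upstream/downstream of the TSS (bp);
#'   defaults 5000 and 1000.
#' @param max_ext Maximum extension distance from the TSS (bp); default 5000.
#' @return Data frame with per-gene `basal_start`, `basal_end`, `ext_start`,
#'   `ext_end` (0-based half-open), ordered as the input annotation.
#' @export
build_regulatory_domains <- function(annotation, basal_up = 5000,
                                     basal_down = 1000, max_ext = 5000) {
  stopifnot(basal_up >= 0, basal_down >= 0, max_ext >= 0)
  sizes <- chrom_sizes(annotation)
  n <- nrow(annotation)
  tss <- annotation$tss
  plus <- annotation$strand == "+"
  len <- unname(sizes[annotation$chrom])
  basal_start <- pmax(0, ifelse(plus, tss - basal_up, tss - basal_down))
  basal_end <- pmin(len, ifelse(plus, tss + basal_down, tss + basal_up))
  cand_start <- pmax(0, pmin(basal_start, tss - max_ext))
  cand_end <- pmin(len, pmax(basal_end, tss + max_ext))
  ext_start <- cand_start
  ext_end <- cand_end
  for (chr in unique(annotation$chrom)) {
    sel <- which(annotation$chrom == chr)
    if (length(sel) < 2L) next
    ord <- sel[order(basal_start[sel], basal_end[sel])]
    bs <- basal_start[ord]
    be <- basal_end[ord]
    k <- length(ord)
    # nearest preceding basal end (max over all predecessors), and the
    # following basal start (min over all successors = next start, sorted)
    left_clip <- c(-Inf, cummax(be[-k]))
    right_clip <- c(bs[-1], Inf)
    es <- pmin(bs, pmax(cand_start[ord], left_clip))
    ee <- pmax(be, pmin(cand_end[ord], right_clip))
    ext_start[ord] <- es
    ext_end[ord] <- ee
  }
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             strand = annotation$strand, tss = tss,
             basal_start = basal_start, basal_end = basal_end,
             ext_start = pmax(0, ext_start), ext_end = ext_end,
             stringsAsFactors = FALSE)
}

domains_granges <- function(domains, which = c("ext", "basal")) {
  which <- match.arg(which)
  s <- domains[[paste0(which, "_start")]]
  e <- domains[[paste0(which, "_end")]]
  GenomicRanges::GRanges(domains$chrom,
                         IRanges::IRanges(start = s + 1, end = e))
}

peaks_granges <- function(peaks) {
  if (inherits(peaks, "GRanges")) return(peaks)
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1,
                                          end = peaks$end))
}

#' Assign peaks to genes via regulatory-domain overlap
#'
#' A peak is assigned to every gene whose extended regulatory domain it
#' overlaps by at least 1 bp; peaks overlapping no domain are returned with
#' an `NA` gene.
#'
#' @param peaks A `GRanges` of peaks (or a data.frame with 0-based `chrom`,
#'   `start`, `end`).
#' @param domains Output of [build_regulatory_domains()].
#' @return Data frame with `peak` (name or index), `gene_id`, and
#'   `distance_to_tss` (bp from peak midpoint to the gene TSS; `NA` for
#'   unassigned peaks).
#' @export
assign_peaks <- function(peaks, domains) {
  gr <- peaks_granges(peaks)
  dom <- domains_granges(domains, "ext")
  hits <- GenomicRanges::findOverlaps(gr, dom, minoverlap = 1L)
  peak_names <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  mid0 <- (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
  assigned <- data.frame(
    peak = peak_names[qh],
    gene_id = domains$gene_id[sh],
    distance_to_tss = round(abs(mid0[qh] - domains$tss[sh])),
    stringsAsFactors = FALSE
  )
  orphan <- setdiff(seq_along(gr), unique(qh))
  if (length(orphan)) {
    assigned <- rbind(assigned, data.frame(
      peak = peak_names[orphan], gene_id = NA_character_,
      distance_to_tss = NA_real_, stringsAsFactors = FALSE))
  }
  assigned[order(match(assigned$peak, peak_names)), , drop = FALSE]
}

#' Peak presence in the TSS +/- flank window
#'
#' @param peaks Peaks as in [assign_peaks()].
#' @param annotation Gene annotation.
#' @param flank Window half-width (bp); default 5000.
#' @return Named logical vector: `TRUE` for genes with >= 1 peak
#'   overlapping `[TSS - flank, TSS + flank)`.
#' @export
tss_window_occupancy <- function(peaks, annotation, flank = 5000) {
  gr <- peaks_granges(peaks)
  sizes <- chrom_sizes(annotation)
  len <- unname(sizes[annotation$chrom])
  s <- pmax(0, annotation$tss - flank)
  e <- pmin(len, annotation$tss + flank)
  win <- GenomicRanges::GRanges(annotation$chrom,
                                IRanges::IRanges(start = s + 1, end = e))
  occ <- IRanges::overlapsAny(win, gr, minoverlap = 1L)
  stats::setNames(occ, annotation$gene_id)
}

#' Percentage of a gene subset with peak occupancy
#'
#' @param genes Gene ids of the subset (e.g. one subcluster).
#' @param occupancy Named logical vector from [tss_window_occupancy()].
#' @return Percentage in \[0, 100\]; `NA` for an empty subset.
#' @export
peak_occupancy_fraction <- function(genes, occupancy) {
  genes <- unique(genes)
  if (!length(genes)) return(NA_real_)
  if (!all(genes %in% names(occupancy))) {
    stop("peak_occupancy_fraction: occupancy missing for some genes")
  }
  100 * sum(occupancy[genes]) / length(genes)
}
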
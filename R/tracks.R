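# Tag tracks: per-chromosome 0-based tag (read 5') positions plus totals.

#' Construct a tag track
#'
#' A ChIP sample is represented by the sorted 0-based positions of its tag
#' 5' ends per chromosome, together with the recorded total tag count.
#'
#' @param positions Named list (one entry per chromosome) of integer-valued
#'   0-based positions; sorted internally.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param sample_id Free-text sample label.
#' @return An object of class `tag_track`.
#' @export
tag_track <- function(positions, chrom_sizes, sample_id = "sample") {
  stopifnot(is.list(positions), !is.null(names(chrom_sizes)))
  missing_chr <- setdiff(names(positions), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("tag_track: positions on unknown chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  for (chr in names(positions)) {
    p <- positions[[chr]]
    bad <- which(p < 0 | p >= chrom_sizes[[chr]])
    if (length(bad)) {
      stop(sprintf("tag_track: tag beyond chrom end on %s at position %s",
                   chr, format(p[bad[1]], scientific = FALSE)))
    }
  }
  # every chromosome present, possibly empty
  full <- stats::setNames(vector("list", length(chrom_sizes)),
                          names(chrom_sizes))
  for (chr in names(chrom_sizes)) full[[chr]] <- positions[[chr]] %||% numeric()
  structure(list(sample_id = sample_id,
                 positions = full,
                 chrom_sizes = chrom_sizes,
                 total_tags = sum(lengths(full))),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("<tag_track '%s'>: %s tags on %d chromosome(s)\n",
              x$sample_id, format(x$total_tags, big.mark = ","),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Read/write tag tracks as BED
#'
#' Tags are persisted as 1-bp BED intervals (0-based half-open on disk, via
#' `rtracklayer`).
#'
#' @param track A [tag_track()].
#' @param path BED file path.
#' @param chrom_sizes Named chromosome lengths for the reader.
#' @param sample_id Label for the reconstructed track.
#' @export
write_tag_bed <- function(track, path) {
  chrs <- rep(names(track$positions), lengths(track$positions))
  pos <- unlist(track$positions, use.names = FALSE)
  if (!length(pos)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    chrs, IRanges::IRanges(start = pos + 1, width = 1),
    seqinfo = GenomeInfoDb::Seqinfo(names(track$chrom_sizes),
                                    unname(track$chrom_sizes))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_tag_bed
#' @export
read_tag_bed <- function(path, chrom_sizes, sample_id = basename(path)) {
  if (file.size(path) == 0) {
    return(tag_track(list(), chrom_sizes, sample_id))
  }
  gr <- rtracklayer::import(path, format = "BED")
  pos <- split(GenomicRanges::start(gr) - 1,
               as.character(GenomicRanges::seqnames(gr)))
  tag_track(as.list(pos), chrom_sizes, sample_id)
}
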
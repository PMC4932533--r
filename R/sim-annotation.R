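#' Generate a synthetic gene annotation
#'
#' Lays `n_genes` non-overlapping gene bodies on a regular grid across the
#' simulated chromosomes, with at least `gene_spacing` bp between bodies and
#' random strands. Coordinates are 0-based half-open; the TSS is `start` for
#' `+` genes and `end` for `-` genes.
#'
#' @param cfg A [sim_config()].
#' @return A `data.frame` (class `genome_annotation`) with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, and a `chrom_sizes` attribute
#'   (named vector of chromosome lengths).
#' @export
generate_annotation <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))
  if (cfg$n_genes == 0L) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), tss = numeric(),
                      stringsAsFactors = FALSE)
    attr(ann, "chrom_sizes") <- sizes
    class(ann) <- c("genome_annotation", "data.frame")
    return(ann)
  }
  span <- cfg$gene_length + cfg$gene_spacing
  capacity <- floor((cfg$chrom_length - cfg$gene_spacing) / span)
  chrom_idx <- sort(rep_len(seq_len(cfg$n_chroms), cfg$n_genes))
  if (capacity < 1 || max(tabulate(chrom_idx, cfg$n_chroms)) > capacity) {
    stop("generate_annotation: genes cannot fit in chrom_length with the ",
         "requested gene_length and gene_spacing", call. = FALSE)
  }
  within <- stats::ave(seq_along(chrom_idx), chrom_idx, FUN = seq_along)
  start <- cfg$gene_spacing + (within - 1) * span
  end <- start + cfg$gene_length
  strand <- withr::with_seed(cfg$seed,
                             sample(c("+", "-"), cfg$n_genes, replace = TRUE))
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
    chrom = names(sizes)[chrom_idx],
    strand = strand,
    start = start,
    end = end,
    tss = ifelse(strand == "+", start, end),
    stringsAsFactors = FALSE
  )
  attr(ann, "chrom_sizes") <- sizes
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Chromosome sizes of an annotation
#'
#' @param ann A `genome_annotation` (or any object carrying a `chrom_sizes`
#'   attribute).
#' @return Named numeric vector of chromosome lengths.
#' @export
chrom_sizes <- function(ann) {
  cs <- attr(ann, "chrom_sizes")
  if (is.null(cs)) stop("object carries no 'chrom_sizes' attribute")
  cs
}

#' Read/write annotation and chromosome-size files
#'
#' Plain-TSV persistence for the annotation (columns `gene_id`, `chrom`,
#' `strand`, `start`, `end`, `tss`; 0-based half-open) and a two-column
#' chromosome-sizes TSV.
#'
#' @param ann Annotation data.frame.
#' @param path,sizes_path Output/input file paths.
#' @return `read_annotation()` returns the annotation with its `chrom_sizes`
#'   attribute restored.
#' @export
write_annotation <- function(ann, path, sizes_path) {
  utils::write.table(as.data.frame(ann)[, c("gene_id", "chrom", "strand",
                                            "start", "end", "tss")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- chrom_sizes(ann)
  utils::write.table(data.frame(chrom = names(sizes), size = unname(sizes)),
                     sizes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, sizes_path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  sz <- utils::read.delim(sizes_path, header = FALSE,
                          stringsAsFactors = FALSE)
  attr(ann, "chrom_sizes") <- stats::setNames(as.numeric(sz[[2]]), sz[[1]])
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}
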
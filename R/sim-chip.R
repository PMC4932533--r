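# Synthetic ChIP tag tracks: Poisson background plus shaped enrichment at
# target genes, paired with a uniform input track.

# Enrichment kernel (0-based half-open genomic interval) for one gene.
enrichment_kernel <- function(shape, tss, start, end, chrom_len) {
  win <- switch(shape,
    sharp_tss  = c(tss - 500, tss + 500),
    tss_domain = c(tss - 2500, tss + 2500),
    blanket    = c(start - 5000, end + 5000),
    stop("unknown peak shape: ", shape)
  )
  c(max(0, win[1]), min(chrom_len, win[2]))
}

#' Simulate a test/input ChIP tag track pair
#'
#' The input track is a uniform field of `n_tags_input` tags. The test track
#' is the same uniform background (`n_tags_test` tags) plus, at each target
#' gene, extra tags whose expected count raises the local density to
#' `enrichment_fold` times background inside the shape kernel:
#' `sharp_tss` = +/-500 bp of the TSS (H3K4me3-like), `tss_domain` =
#' +/-2.5 kb (promoter H3K27me3-like), `blanket` = gene body +/-5 kb (broad
#' weak H3K27me3). Realized totals are recorded on each track.
#'
#' @param cfg A [sim_config()].
#' @param annotation Annotation from [generate_annotation()].
#' @param target_genes Character vector of enriched gene ids (subset of the
#'   annotation).
#' @param shape Enrichment kernel; defaults to `cfg$peak_shape`.
#' @param seed Seed for this track pair (distinct samples should pass
#'   distinct seeds); defaults to `cfg$seed`.
#' @param sample_id Label prefix for the two tracks.
#' @return `list(test = <tag_track>, input = <tag_track>)`.
#' @export
simulate_chip_tags <- function(cfg, annotation, target_genes,
                               shape = cfg$peak_shape, seed = cfg$seed,
                               sample_id = "chip") {
  cfg <- validate_sim_config(cfg)
  stopifnot(all(target_genes %in% annotation$gene_id))
  sizes <- chrom_sizes(annotation)
  genome_len <- sum(sizes)
  n_bg_test <- cfg$n_tags_test %||% round(cfg$background_rate * genome_len)
  n_bg_input <- cfg$n_tags_input %||% round(cfg$background_rate * genome_len)

  uniform_positions <- function(n_tags) {
    if (n_tags <= 0) return(stats::setNames(
      rep(list(numeric()), length(sizes)), names(sizes)))
    chr <- sample(names(sizes), n_tags, replace = TRUE,
                  prob = sizes / genome_len)
    pos <- floor(stats::runif(n_tags) * sizes[chr])
    split(unname(pos), chr)
  }

  withr::with_seed(as.integer(seed), {
    input_pos <- uniform_positions(n_bg_input)
    test_pos <- uniform_positions(n_bg_test)
    targets <- annotation[annotation$gene_id %in% target_genes, , drop = FALSE]
    if (nrow(targets) && cfg$enrichment_fold > 1 && cfg$background_rate > 0) {
      for (i in seq_len(nrow(targets))) {
        chr <- targets$chrom[i]
        ker <- enrichment_kernel(shape, targets$tss[i], targets$start[i],
                                 targets$end[i], sizes[[chr]])
        width <- ker[2] - ker[1]
        if (width <= 0) next
        lambda <- (cfg$enrichment_fold - 1) * cfg$background_rate * width
        k <- stats::rpois(1, lambda)
        if (k > 0) {
          extra <- floor(ker[1] + stats::runif(k) * width)
          test_pos[[chr]] <- c(test_pos[[chr]], extra)
        }
      }
    }
    list(
      test = tag_track(test_pos, sizes, paste0(sample_id, ":test")),
      input = tag_track(input_pos, sizes, paste0(sample_id, ":input"))
    )
  })
}
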
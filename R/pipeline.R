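# End-to-end orchestration: simulate a complete synthetic dataset
# (annotation, FPKM, ChIP tag tracks, TF peaks, ground truth), persist it as
# plain-text files, and run the full analysis graph over it.

#' Analysis parameters
#'
#' All numeric constants of the analysis in one place; defaults are the
#' canonical values used throughout (1.5-fold specificity/knockout rule,
#' 2.0-fold validation filter, 1050/50 bp windows, +/-5 kb TSS averaging,
#' K = 15 K-means, 9 subclusters, GREAT basal 5 kb up / 1 kb down with 5 kb
#' extension).
#'
#' @param fold Fraction-specificity and knockout fold threshold.
#' @param validation_fold Low-fold validation filter threshold.
#' @param pseudocount FPKM pseudocount in all ratio rules.
#' @param window,step,flank ChIP scoring geometry (bp).
#' @param floor_c log2 floor offset (per-million units).
#' @param scale Library scaling constant (tags-per-million).
#' @param k K-means cluster count.
#' @param n_subclusters Hierarchical subcluster count for group-A genes.
#' @param basal_up,basal_down,max_ext Regulatory-domain geometry (bp).
#' @param not_expressed_threshold FPKM floor for the expressed-gene filter.
#' @param seed Seed for the clustering steps.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(fold = 1.5, validation_fold = 2.0,
                            pseudocount = 1, window = 1050, step = 50,
                            flank = 5000, floor_c = 1, scale = 1e6,
                            k = 15, n_subclusters = 9,
                            basal_up = 5000, basal_down = 1000,
                            max_ext = 5000, not_expressed_threshold = 1,
                            seed = 1L) {
  p <- as.list(environment())
  num <- vapply(p, is.numeric, logical(1))
  if (any(vapply(p[num], function(x) any(x <= 0), logical(1)) &
          !names(p)[num] %in% "seed")) {
    stop("pipeline_params: parameters must be positive")
  }
  class(p) <- "pipeline_params"
  p
}

# ChIP sample plan: marks x fractions x stages, with the planted target set
# and kernel shape per sample. H3K4me3 marks the genes active in that
# fraction at that stage (sharp TSS peaks); H3K27me3 in the P fraction
# blankets the N-lineage genes (TSS-proximal domains), while the N fraction
# carries no planted H3K27me3 enrichment.
chip_targets <- function(truth, mark, fraction, stage) {
  spec <- truth[[paste0("spec_", stage)]]
  if (mark == "H3K4me3") {
    truth$gene_id[spec == fraction]
  } else if (fraction == "P") {
    truth$gene_id[spec == "N"]
  } else {
    character()
  }
}

chip_shape <- function(mark) if (mark == "H3K4me3") "sharp_tss" else "tss_domain"

#' Simulate the complete synthetic dataset
#'
#' Generates, from one [sim_config()], the annotation, the planted FPKM
#' matrix with ground truth, paired test/input ChIP tag tracks for H3K4me3
#' and H3K27me3 in both Cd73 fractions at P2/P5/P8 (one shared input per
#' fraction/stage), three TF peak sets (Nrl/Crx/Otx2-like, bound to
#' overlapping subsets of the group-A genes), and synthetic bipolar /
#' amacrine / RGC cell-type gene lists drawn mostly from the planted
#' N-lineage genes.
#'
#' @param cfg A [sim_config()].
#' @return A list: `cfg`, `annotation`, `fpkm`, `truth`, `chip` (named list
#'   `mark:fraction:stage -> list(test, input)`), `tf_peaks` (named list of
#'   `GRanges`), `tf_bound` (named list of planted bound gene ids),
#'   `celltype_lists` (named list of gene ids).
#' @export
simulate_dataset <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  annotation <- generate_annotation(cfg)
  ex <- simulate_expression(cfg, annotation)
  truth <- ex$truth

  marks <- c("H3K4me3", "H3K27me3")
  fractions <- c("P", "N")
  stages <- c("P2", "P5", "P8")
  chip <- list()
  seed_off <- 100L
  for (st in stages) {
    for (fr in fractions) {
      input_seed <- cfg$seed + seed_off
      seed_off <- seed_off + 1L
      input <- NULL
      for (mk in marks) {
        pair <- simulate_chip_tags(
          cfg, annotation, chip_targets(truth, mk, fr, st),
          shape = chip_shape(mk), seed = cfg$seed + seed_off,
          sample_id = paste(mk, fr, st, sep = ":")
        )
        seed_off <- seed_off + 1L
        if (is.null(input)) {
          # one shared input per fraction/stage
          input <- simulate_chip_tags(
            cfg, annotation, character(), seed = input_seed,
            sample_id = paste("input", fr, st, sep = ":"))$input
        }
        chip[[paste(mk, fr, st, sep = ":")]] <-
          list(test = pair$test, input = input)
      }
    }
  }

  a_genes <- truth$gene_id[truth$group == "A"]
  n_genes_pool <- truth$gene_id[truth$group == "N"]
  bg_pool <- truth$gene_id[truth$group == "background"]
  tf_bound <- withr::with_seed(cfg$seed + 7L, {
    list(
      Nrl = sample(a_genes, round(0.6 * length(a_genes))),
      Crx = sample(a_genes, round(0.7 * length(a_genes))),
      Otx2 = sample(a_genes, round(0.65 * length(a_genes)))
    )
  })
  tf_peaks <- list()
  for (i in seq_along(tf_bound)) {
    tf <- names(tf_bound)[i]
    tf_peaks[[tf]] <- simulate_tf_peaks(cfg, annotation, tf_bound[[tf]],
                                        seed = cfg$seed + 20L + i, label = tf)
  }

  celltype_lists <- withr::with_seed(cfg$seed + 8L, {
    take <- function(pool, n) sample(pool, min(n, length(pool)))
    avail <- n_genes_pool
    mk_list <- function(n_spec, n_bg) {
      spec <- take(avail, n_spec)
      avail <<- setdiff(avail, spec)
      c(spec, take(bg_pool, n_bg))
    }
    list(bipolar = mk_list(32, 8), amacrine = mk_list(32, 8),
         RGC = mk_list(24, 6))
  })

  list(cfg = cfg, annotation = annotation, fpkm = ex$fpkm, truth = truth,
       chip = chip, tf_peaks = tf_peaks, tf_bound = tf_bound,
       celltype_lists = celltype_lists)
}

#' Write a simulated dataset to disk
#'
#' Persists every component as plain text: annotation and chromosome-size
#' TSVs, FPKM TSV, per-sample tag BEDs, TF peak BEDs, cell-type gene lists
#' (one id per line), ground-truth JSON, the config as YAML, and a manifest
#' JSON listing all files with their md5 checksums.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  files <- character()
  add <- function(f) files <<- c(files, f)

  write_annotation(ds$annotation, pth("annotation.tsv"), pth("chrom.sizes"))
  add("annotation.tsv"); add("chrom.sizes")
  write_fpkm(ds$fpkm, pth("fpkm.tsv")); add("fpkm.tsv")

  dir.create(pth("tags"), showWarnings = FALSE)
  for (nm in names(ds$chip)) {
    safe <- gsub(":", "_", nm)
    write_tag_bed(ds$chip[[nm]]$test, pth("tags", paste0(safe, "_test.bed")))
    add(file.path("tags", paste0(safe, "_test.bed")))
    write_tag_bed(ds$chip[[nm]]$input, pth("tags", paste0(safe, "_input.bed")))
    add(file.path("tags", paste0(safe, "_input.bed")))
  }
  dir.create(pth("peaks"), showWarnings = FALSE)
  for (tf in names(ds$tf_peaks)) {
    write_peaks_bed(ds$tf_peaks[[tf]], pth("peaks", paste0(tf, ".bed")))
    add(file.path("peaks", paste0(tf, ".bed")))
  }
  dir.create(pth("gene_lists"), showWarnings = FALSE)
  for (ct in names(ds$celltype_lists)) {
    writeLines(ds$celltype_lists[[ct]], pth("gene_lists", paste0(ct, ".txt")))
    add(file.path("gene_lists", paste0(ct, ".txt")))
  }
  jsonlite::write_json(
    list(truth = ds$truth, tf_bound = ds$tf_bound),
    pth("ground_truth.json"), dataframe = "columns", auto_unbox = FALSE)
  add("ground_truth.json")
  cfg_plain <- unclass(ds$cfg)
  cfg_plain$group_sizes <- as.list(cfg_plain$group_sizes)
  yaml::write_yaml(cfg_plain, pth("config.yaml")); add("config.yaml")

  manifest <- list(
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(pth(f))))
    }),
    config_md5 = unname(tools::md5sum(pth("config.yaml")))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  pth <- function(...) file.path(dir, ...)
  annotation <- read_annotation(pth("annotation.tsv"), pth("chrom.sizes"))
  sizes <- chrom_sizes(annotation)
  cfg_plain <- yaml::read_yaml(pth("config.yaml"))
  cfg_plain$group_sizes <- unlist(cfg_plain$group_sizes)
  cfg <- do.call(sim_config, cfg_plain[setdiff(names(cfg_plain), NULL)])
  gt <- jsonlite::read_json(pth("ground_truth.json"), simplifyVector = TRUE)
  chip <- list()
  for (f in list.files(pth("tags"), pattern = "_test\\.bed$")) {
    nm <- gsub("_test\\.bed$", "", f)
    key <- gsub("_", ":", nm)
    chip[[key]] <- list(
      test = read_tag_bed(pth("tags", f), sizes, paste0(key, ":test")),
      input = read_tag_bed(pth("tags", paste0(nm, "_input.bed")), sizes,
                           paste0(key, ":input"))
    )
  }
  tf_peaks <- list()
  for (f in list.files(pth("peaks"), pattern = "\\.bed$")) {
    tf_peaks[[sub("\\.bed$", "", f)]] <- read_peaks_bed(pth("peaks", f), sizes)
  }
  celltype_lists <- list()
  for (f in list.files(pth("gene_lists"), pattern = "\\.txt$")) {
    celltype_lists[[sub("\\.txt$", "", f)]] <- readLines(pth("gene_lists", f))
  }
  list(cfg = cfg, annotation = annotation, fpkm = read_fpkm(pth("fpkm.tsv")),
       truth = gt$truth, chip = chip, tf_peaks = tf_peaks,
       tf_bound = gt$tf_bound, celltype_lists = celltype_lists)
}

#' Run the full analysis over a dataset
#'
#' Reproduces the analysis graph end-to-end on one dataset: per-stage
#' fraction specificity and temporal groups, knockout up/down calls with
#' Venn partitions and the regulation summary table, the expressed-gene
#' filter, per-mark quantile-normalized histone score matrices with
#' KS comparisons and box-plot summaries of Cd73PG vs Cd73NG signal,
#' K-means clustering of log2(FPKM + 1), hierarchical subclustering of
#' group-A genes on their histone scores, TF peak assignment and
#' per-subcluster occupancy fractions, the bound-vs-unbound expression
#' comparison (Welch t + point-biserial r), the validation-candidate
#' filter, and the H3K27me3 TSS profile heatmap matrix.
#'
#' @param ds Dataset from [simulate_dataset()] or [read_dataset()].
#' @param params A [pipeline_params()].
#' @param out_dir Optional directory; when given, every result table is
#'   also written as TSV (sorted, diff-stable).
#' @return A named list of result objects.
#' @export
run_pipeline <- function(ds, params = pipeline_params(), out_dir = NULL) {
  fpkm <- ds$fpkm
  ann <- ds$annotation
  res <- list()

  # --- expression classification ------------------------------------------
  spec <- lapply(c(P2 = "P2", P5 = "P5", P8 = "P8"), function(st) {
    classify_fraction_specific(fpkm, st, params$fold, params$pseudocount)
  })
  groups <- assign_temporal_group(spec$P2, spec$P5, spec$P8)
  cko <- lapply(c(P = "P", N = "N"), function(fr) {
    classify_cko_regulation(fpkm, fr, params$fold, params$pseudocount)
  })
  genes <- rownames(fpkm)
  up <- venn_partition(genes[cko$P == "up"], genes[cko$N == "up"])
  down <- venn_partition(genes[cko$P == "down"], genes[cko$N == "down"])

  grouping <- data.frame(
    gene_id = genes, spec_P2 = unname(spec$P2), spec_P5 = unname(spec$P5),
    spec_P8 = unname(spec$P8), temporal_group = unname(groups),
    cko_P = unname(cko$P), cko_N = unname(cko$N), stringsAsFactors = FALSE)
  res$grouping <- grouping

  # cell-type lists: keep N-specific clusters only
  celltype <- lapply(ds$celltype_lists, function(g) {
    celltype_relative_expression(fpkm, g, pseudocount = params$pseudocount)
  })
  res$celltype <- celltype

  subtypes <- c(
    lapply(stats::setNames(c("A", "B", "C", "D"),
                           paste0("Cd73P_", c("A", "B", "C", "D"))),
           function(g) genes[groups == g]),
    lapply(celltype, function(x) x$retained)
  )
  res$regulation_summary <- build_regulation_summary(subtypes, up, down)
  res$venn <- list(up = up, down = down)

  expressed <- nonexpressed_filter(fpkm, params$not_expressed_threshold)
  res$expressed <- expressed

  res$validation_candidates <- select_validation_candidates(
    fpkm, subtypes$Cd73P_A, params$validation_fold,
    pseudocount = params$pseudocount)

  # --- histone scores ------------------------------------------------------
  marks <- unique(vapply(strsplit(names(ds$chip), ":"), `[`, "", 1))
  scores <- list()
  for (mk in marks) {
    sel <- grep(paste0("^", mk, ":"), names(ds$chip), value = TRUE)
    scores[[mk]] <- score_matrix(ds$chip[sel], ann, params$window,
                                 params$step, params$flank, params$floor_c,
                                 params$scale)
    colnames(scores[[mk]]) <- sub(paste0("^", mk, ":"), "", sel)
  }
  res$scores <- scores

  # KS comparisons and box-plot values of cumulative TSS signal,
  # Cd73PG vs Cd73NG per mark / fraction / stage
  pg <- genes[groups %in% c("A", "B", "C", "D")]
  ng <- unique(unlist(lapply(celltype, function(x) x$retained)))
  if (!length(ng)) ng <- genes[spec$P2 == "N" & spec$P5 == "N"]
  ks_rows <- list()
  box_groups <- list()
  for (mk in marks) {
    for (cn in colnames(scores[[mk]])) {
      a <- scores[[mk]][pg, cn]
      b <- scores[[mk]][ng, cn]
      if (sum(!is.na(a)) && sum(!is.na(b))) {
        ks <- ks_two_sample(a[!is.na(a)], b[!is.na(b)])
        ks_rows[[paste(mk, cn)]] <- data.frame(
          mark = mk, sample = cn, D = ks$statistic, p_value = ks$p_value,
          n_PG = ks$n_a, n_NG = ks$n_b, stringsAsFactors = FALSE)
        box_groups[[paste(mk, cn, "PG", sep = ":")]] <- a[!is.na(a)]
        box_groups[[paste(mk, cn, "NG", sep = ":")]] <- b[!is.na(b)]
      }
    }
  }
  res$ks_pg_vs_ng <- do.call(rbind, c(ks_rows, list(make.row.names = FALSE)))
  res$signal_boxplots <- boxplot_summary(box_groups)

  # --- clustering ----------------------------------------------------------
  expr_mat <- log2(fpkm[expressed$expressed, , drop = FALSE] + 1)
  if (nrow(expr_mat) >= params$k) {
    res$kmeans <- kmeans_profiles(expr_mat, params$k, seed = params$seed)
  }
  a_ids <- subtypes$Cd73P_A
  hist_mat <- do.call(cbind, lapply(marks, function(mk) {
    m <- scores[[mk]][a_ids, , drop = FALSE]
    colnames(m) <- paste(mk, colnames(m), sep = ":")
    m
  }))
  hist_mat <- hist_mat[stats::complete.cases(hist_mat), , drop = FALSE]
  if (nrow(hist_mat) >= params$n_subclusters) {
    res$subclusters <- hierarchical_subcluster(hist_mat,
                                               params$n_subclusters)
  }

  # --- TF peaks ------------------------------------------------------------
  domains <- build_regulatory_domains(ann, params$basal_up,
                                      params$basal_down, params$max_ext)
  res$domains <- domains
  occupancy <- lapply(ds$tf_peaks, tss_window_occupancy, annotation = ann,
                      flank = params$flank)
  res$assignments <- lapply(ds$tf_peaks, assign_peaks, domains = domains)
  if (!is.null(res$subclusters)) {
    subcl <- res$subclusters$labels
    occ_rows <- list()
    for (tf in names(occupancy)) {
      for (ci in sort(unique(subcl))) {
        ids <- names(subcl)[subcl == ci]
        occ_rows[[paste(tf, ci)]] <- data.frame(
          tf = tf, subcluster = ci, n_genes = length(ids),
          occupancy_pct = peak_occupancy_fraction(ids, occupancy[[tf]]),
          stringsAsFactors = FALSE)
      }
    }
    res$subcluster_occupancy <- do.call(rbind, occ_rows)
  }
  res$occupancy <- occupancy

  # bound vs unbound group-A genes: expression and H3K4me3 comparisons
  if (length(a_ids) >= 4 && "Nrl" %in% names(occupancy)) {
    bound <- a_ids[occupancy$Nrl[a_ids]]
    unbound <- setdiff(a_ids, bound)
    if (length(bound) >= 2 && length(unbound) >= 2) {
      p8 <- log2(fpkm[, sample_id("P8", "P")] + 1)
      res$nrl_expression_test <- t_test_with_r(p8[match(bound, genes)],
                                               p8[match(unbound, genes)])
      k4 <- scores$H3K4me3[, grep(":P8$", colnames(scores$H3K4me3),
                                  value = TRUE)[1]]
      res$nrl_h3k4me3_test <- t_test_with_r(
        k4[bound][!is.na(k4[bound])], k4[unbound][!is.na(k4[unbound])])
    }
  }

  # --- H3K27me3 heatmap matrix over 10 kb around TSS -----------------------
  if ("H3K27me3" %in% marks) {
    key <- grep("^H3K27me3:P:", names(ds$chip), value = TRUE)[1]
    pr <- ds$chip[[key]]
    wt <- log2_transform(
      normalize_and_subtract(count_windows(pr$test, params$window,
                                           params$step),
                             count_windows(pr$input, params$window,
                                           params$step),
                             scale = params$scale),
      params$floor_c)
    heat_genes <- if (length(ng)) ng else ann$gene_id
    res$h3k27me3_heatmap <- tss_profile_matrix(wt, ann, heat_genes)
    res$h3k27me3_track <- wt
  }

  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$grouping[order(res$grouping$gene_id), ], "grouping.tsv")
  wt(res$regulation_summary, "regulation_summary.tsv")
  for (mk in names(res$scores)) {
    m <- res$scores[[mk]]
    wt(data.frame(gene_id = rownames(m), m, check.names = FALSE),
       paste0("scores_", mk, ".tsv"))
  }
  wt(res$ks_pg_vs_ng, "ks_pg_vs_ng.tsv")
  wt(res$signal_boxplots, "signal_boxplots.tsv")
  if (!is.null(res$kmeans)) {
    wt(data.frame(gene_id = names(res$kmeans$labels),
                  cluster = unname(res$kmeans$labels)), "kmeans_clusters.tsv")
  }
  if (!is.null(res$subclusters)) {
    wt(data.frame(gene_id = names(res$subclusters$labels),
                  subcluster = unname(res$subclusters$labels)),
       "subclusters.tsv")
  }
  if (!is.null(res$subcluster_occupancy)) {
    wt(res$subcluster_occupancy, "subcluster_occupancy.tsv")
  }
  for (tf in names(res$assignments)) {
    wt(res$assignments[[tf]], paste0("peak_assignments_", tf, ".tsv"))
  }
  if (!is.null(res$h3k27me3_heatmap)) {
    m <- res$h3k27me3_heatmap
    wt(data.frame(gene_id = rownames(m), m, check.names = FALSE),
       "h3k27me3_tss_heatmap.tsv")
    export_bedgraph(res$h3k27me3_track,
                    file.path(out_dir, "h3k27me3_P_log2.bedgraph"))
  }
  writeLines(res$validation_candidates,
             file.path(out_dir, "validation_candidates.txt"))
  invisible(out_dir)
}
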
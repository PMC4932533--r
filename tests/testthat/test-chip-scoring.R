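# The histone-score chain: window counting, scaling/subtraction, log2,
# TSS averaging, quantile normalization, profiles, and bedGraph round trips.

test_that("window counting matches the half-open window definition", {
  sizes <- c(chr1 = 5000)
  none <- count_windows(tag_track(list(), sizes))
  expect_equal(length(none$values$chr1), floor((5000 - 1050) / 50) + 1)
  expect_true(all(none$values$chr1 == 0))

  # a single tag at 1049 falls in the 21 windows starting 0..1000
  one <- count_windows(tag_track(list(chr1 = 1049), sizes))
  expect_equal(which(one$values$chr1 == 1), 1:21)
  expect_equal(sum(one$values$chr1), 21)

  # chromosome shorter than one window yields zero windows
  short <- count_windows(tag_track(list(), c(chr1 = 800)))
  expect_length(short$values$chr1, 0)
})

test_that("window counts equal a brute-force double loop", {
  set.seed(10)
  pos <- sort(sample(0:9999, 200, replace = TRUE))
  wt <- count_windows(tag_track(list(chr1 = pos), c(chr1 = 10000)))
  expect_equal(wt$values$chr1, brute_count_windows(pos, 10000, 1050, 50))

  # and for a non-default geometry where window is not a step multiple
  wt2 <- count_windows(tag_track(list(chr1 = pos), c(chr1 = 10000)),
                       window = 330, step = 70)
  expect_equal(wt2$values$chr1, brute_count_windows(pos, 10000, 330, 70))
})

test_that("library scaling and input subtraction behave per million", {
  sizes <- c(chr1 = 5000)
  pos <- c(0:9)  # 10 tags in the first window
  test <- count_windows(tag_track(list(chr1 = pos), sizes))
  empty <- count_windows(tag_track(list(), sizes))

  # identical test and input with equal totals cancel to 0 everywhere
  zero <- normalize_and_subtract(test, test)
  expect_true(all(unlist(zero$values) == 0))

  # 10 tags of a 1e6-tag library against an empty input -> 10.0
  sub <- normalize_and_subtract(test, empty, test_total = 1e6,
                                input_total = 1e6)
  expect_equal(sub$values$chr1[1], 10)

  # scale invariance: inflating counts and totals together changes nothing
  sub_k <- normalize_and_subtract(test, empty, test_total = 2e6,
                                  input_total = 2e6)
  test2 <- test
  test2$values$chr1 <- test$values$chr1 * 2
  sub2 <- normalize_and_subtract(test2, empty, test_total = 2e6,
                                 input_total = 1e6)
  expect_equal(sub2$values$chr1, 2 * sub_k$values$chr1 * 1)
  expect_equal(sub2$values$chr1, sub$values$chr1)

  short <- count_windows(tag_track(list(), c(chr1 = 4000)))
  expect_error(normalize_and_subtract(test, short), "grids differ")
})

test_that("log2 conversion floors negatives and offsets by floor_c", {
  sizes <- c(chr1 = 5000)
  seven <- count_windows(tag_track(list(chr1 = 0:6), sizes))
  empty <- count_windows(tag_track(list(), sizes))
  sub <- normalize_and_subtract(seven, empty, test_total = 1e6,
                                input_total = 1e6)
  lg <- log2_transform(sub, floor_c = 1)
  expect_equal(lg$values$chr1[1], 3)              # log2(7 + 1)
  expect_equal(lg$values$chr1[50], 0)             # log2(0 + 1)

  neg <- normalize_and_subtract(empty, seven, test_total = 1e6,
                                input_total = 1e6)
  expect_true(all(log2_transform(neg, 1)$values$chr1 == 0))
  expect_error(log2_transform(sub, floor_c = 0))
})

test_that("TSS averaging selects windows by midpoint and truncates at edges", {
  sizes <- c(chr1 = 60000)
  ann <- mk_ann(c("mid", "edge"), "chr1", "+", c(30000, 1000), sizes)
  empty <- count_windows(tag_track(list(), sizes))
  constant <- log2_transform(normalize_and_subtract(empty, empty,
                                                    test_total = 1,
                                                    input_total = 1), 2)
  sc <- tss_average(constant, ann)
  expect_equal(unname(sc), c(1, 1))  # log2(0 + 2) everywhere

  set.seed(11)
  pos <- sort(sample(0:59999, 800, replace = TRUE))
  lg <- log2_transform(normalize_and_subtract(
    count_windows(tag_track(list(chr1 = pos), sizes)), empty,
    input_total = 800), 1)
  sc <- tss_average(lg, ann, flank = 5000)
  v <- lg$values$chr1
  mids <- (seq_along(v) - 1) * 50 + 525
  for (g in 1:2) {
    keep <- mids >= ann$tss[g] - 5000 & mids < ann$tss[g] + 5000
    expect_equal(unname(sc[g]), mean(v[keep]))
  }
  # the edge gene's flank is truncated: fewer windows than the interior gene
  expect_lt(sum(mids >= ann$tss[2] - 5000 & mids < ann$tss[2] + 5000),
            sum(mids >= ann$tss[1] - 5000 & mids < ann$tss[1] + 5000))

  # a gene on a window-less chromosome is NA and reported
  ann2 <- mk_ann("off", "chr2", "+", 100, c(chr1 = 60000, chr2 = 500))
  trk <- count_windows(tag_track(list(), c(chr1 = 60000, chr2 = 500)))
  expect_message(sc2 <- tss_average(trk, ann2), "no covered window")
  expect_true(is.na(sc2["off"]))
})

test_that("quantile normalization equalizes column multisets", {
  # worked three-column example, checked against the rank-and-average oracle
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 8, 5))
  qn <- quantile_normalize(m)
  expect_equal(qn, brute_quantile_normalize(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  ref <- c(mean(c(1, 4, 2)), mean(c(2, 5, 5)), mean(c(3, 6, 8)))
  expect_equal(unname(qn[, "c"]), ref[c(1, 3, 2)])

  # single column and identical columns are unchanged
  expect_equal(quantile_normalize(m[, 1, drop = FALSE]),
               m[, 1, drop = FALSE])
  same <- cbind(m[, 1], m[, 1])
  expect_equal(quantile_normalize(same), same)

  # random matrices: all columns share one sorted multiset, exactly
  set.seed(12)
  r <- matrix(rnorm(500 * 8), 500, 8)
  qr <- quantile_normalize(r)
  for (j in 2:8) expect_identical(sort(qr[, j]), sort(qr[, 1]))
  # order within each column is preserved
  for (j in 1:8) expect_identical(order(qr[, j]), order(r[, j]))

  # independent implementation agrees on tie-free data
  expect_equal(unname(qr), unname(limma::normalizeQuantiles(r)),
               tolerance = 1e-9)

  # NA values are excluded from ranking and stay NA
  rna <- r[1:50, 1:3]
  rna[c(3, 20), 2] <- NA
  qna <- quantile_normalize(rna)
  expect_true(all(is.na(qna[c(3, 20), 2])))
  expect_false(anyNA(qna[, 1]))
})

test_that("TSS profile matrices sample the track 5' to 3'", {
  sizes <- c(chr1 = 60000)
  empty <- count_windows(tag_track(list(), sizes))
  constant <- log2_transform(normalize_and_subtract(empty, empty,
                                                    test_total = 1,
                                                    input_total = 1), 2)
  ann <- mk_ann(c("plus", "minus"), "chr1", c("+", "-"), c(20000, 40000),
                sizes)
  pm <- tss_profile_matrix(constant, ann)
  expect_equal(dim(pm), c(2, 200))
  expect_true(all(pm == 1))

  # identical planted asymmetric peaks give identical oriented rows:
  # tags downstream of each TSS (strand-aware)
  # downstream blocks, exact integer mirrors: position p maps to 2*tss-1-p
  pos <- c(20100:20299, 39700:39899)
  lg <- log2_transform(normalize_and_subtract(
    count_windows(tag_track(list(chr1 = pos), sizes)), empty,
    input_total = 400), 1)
  pm2 <- tss_profile_matrix(lg, ann)
  expect_equal(pm2["plus", ], pm2["minus", ], ignore_attr = TRUE)
  expect_gt(max(pm2["plus", 101:110]), max(pm2["plus", 1:50]))

  # brute-force bin lookup oracle, including the minus-strand reversal
  v <- lg$values$chr1
  brute_row <- function(tss, strand) {
    centers <- tss - 5000 + (0:199) * 50 + 25
    idx <- pmin(pmax(round((centers - 525) / 50), 0), length(v) - 1)
    vals <- v[idx + 1]
    if (strand == "-") rev(vals) else vals
  }
  expect_equal(unname(pm2["plus", ]), brute_row(20000, "+"))
  expect_equal(unname(pm2["minus", ]), brute_row(40000, "-"))
})

test_that("bedGraph export round-trips the window track", {
  sizes <- c(chr1 = 8000)
  set.seed(13)
  pos <- sort(sample(0:7999, 300, replace = TRUE))
  lg <- log2_transform(normalize_and_subtract(
    count_windows(tag_track(list(chr1 = pos), sizes)),
    count_windows(tag_track(list(chr1 = sample(0:7999, 250)), sizes))), 1)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  export_bedgraph(lg, path)
  back <- read_bedgraph_track(path, sizes)
  expect_equal(back$values$chr1, lg$values$chr1, tolerance = 1e-6)

  # per-step reduction: each step carries the value of its centred window
  gr <- rtracklayer::import(path, format = "bedGraph")
  s0 <- GenomicRanges::start(gr)[1] - 1
  step_val <- gr$score[1]
  wi <- min(max(round((s0 + 25 - 525) / 50), 0), length(lg$values$chr1) - 1)
  expect_equal(step_val, lg$values$chr1[wi + 1], tolerance = 1e-6)

  # empty track -> header-only file
  empty_path <- withr::local_tempfile(fileext = ".bedgraph")
  export_bedgraph(count_windows(tag_track(list(), c(chr1 = 500))),
                  empty_path)
  expect_true(file.exists(empty_path))
  back0 <- read_bedgraph_track(empty_path, c(chr1 = 500))
  expect_length(back0$values$chr1, 0)
})

test_that("full chain equals a from-scratch brute-force recomputation", {
  cfg <- sim_config(seed = 14, n_chroms = 1, chrom_length = 1e5,
                    n_genes = 11, gene_length = 1000, gene_spacing = 7000,
                    group_sizes = c(A = 4L), silent_fraction = 0,
                    background_rate = 0.002, enrichment_fold = 6,
                    n_tags_test = 300, n_tags_input = 250)
  ann <- generate_annotation(cfg)
  pair <- simulate_chip_tags(cfg, ann, ann$gene_id[1:4])
  got <- histone_score(pair$test, pair$input, ann)
  want <- brute_histone_score(pair$test$positions$chr1,
                              pair$input$positions$chr1, 1e5, ann)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("adding TSS tags never lowers the gene's score at fixed totals", {
  sizes <- c(chr1 = 60000)
  ann <- mk_ann("g", "chr1", "+", 30000, sizes)
  set.seed(15)
  base_pos <- sort(sample(0:59999, 500, replace = TRUE))
  input <- count_windows(tag_track(list(chr1 = sample(0:59999, 500)), sizes))
  score_with <- function(extra) {
    test <- count_windows(tag_track(list(chr1 = sort(c(base_pos, extra))),
                                    sizes))
    sub <- normalize_and_subtract(test, input, test_total = 1000,
                                  input_total = 500)
    tss_average(log2_transform(sub, 1), ann)
  }
  prev <- score_with(integer())
  for (k in c(5, 20, 80)) {
    cur <- score_with(rep(30000, k))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("depth-mode window counting agrees with tag counts for unit depth", {
  set.seed(16)
  pos <- sort(sample(0:9999, 150))
  sizes <- c(chr1 = 10000)
  tagged <- count_windows(tag_track(list(chr1 = pos), sizes))
  depth <- data.frame(chrom = "chr1", start = pos, end = pos + 1, value = 1)
  from_depth <- count_windows_depth(depth, sizes)
  expect_equal(from_depth$values$chr1, tagged$values$chr1)
  expect_equal(from_depth$total_tags, 150)
})
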
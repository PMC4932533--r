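# Fold-change classification, temporal groups, knockout calls, Venn
# partitions, summaries, and the associated filters.

test_that("fraction specificity follows the strict pseudocounted ratio rule", {
  m <- mk_expr(c("a", "b", "c", "d"),
               "P2:P:control" = c(30, 5, 15, 0),
               "P2:N:control" = c(10, 5, 10, 0))
  lab <- classify_fraction_specific(m, "P2", fold = 1.5, pseudocount = 0)
  expect_equal(unname(lab[c("a", "b")]), c("P", "none"))
  # ratio exactly 1.5 stays 'none' under the strict inequality
  expect_equal(unname(lab["c"]), "none")

  # pseudocount keeps zero-FPKM genes finite and neutral
  lab1 <- classify_fraction_specific(m, "P2", pseudocount = 1)
  expect_equal(unname(lab1["d"]), "none")

  expect_error(classify_fraction_specific(m, "P5"), "missing sample column")
})

test_that("specificity labels match a brute-force loop on a large matrix", {
  set.seed(1)
  n <- 1000
  p <- rlnorm(n, 1, 1.5)
  q <- rlnorm(n, 1, 1.5)
  m <- mk_expr(sprintf("g%04d", 1:n), "P5:P:control" = p, "P5:N:control" = q)
  lab <- classify_fraction_specific(m, "P5", fold = 1.5, pseudocount = 1)
  oracle <- character(n)
  for (i in 1:n) {
    rp <- (p[i] + 1) / (q[i] + 1)
    oracle[i] <- if (rp > 1.5) "P" else if (1 / rp > 1.5) "N" else "none"
  }
  expect_equal(unname(lab), oracle)
  expect_true(all(table(lab) > 0))
})

test_that("swapping fractions swaps P and N labels exactly", {
  set.seed(2)
  m <- mk_expr(sprintf("g%03d", 1:300),
               "P8:P:control" = rlnorm(300, 1, 1),
               "P8:N:control" = rlnorm(300, 1, 1))
  swapped <- m[, c(2, 1)]
  colnames(swapped) <- colnames(m)
  lab <- classify_fraction_specific(m, "P8")
  lab_sw <- classify_fraction_specific(swapped, "P8")
  expect_equal(lab_sw == "P", lab == "N")
  expect_equal(lab_sw == "none", lab == "none")
})

test_that("raising the fold threshold never grows a specific set", {
  set.seed(3)
  m <- mk_expr(sprintf("g%03d", 1:400),
               "P2:P:control" = rlnorm(400, 1, 1),
               "P2:N:control" = rlnorm(400, 1, 1))
  lab15 <- classify_fraction_specific(m, "P2", fold = 1.5)
  lab20 <- classify_fraction_specific(m, "P2", fold = 2.0)
  expect_true(all(names(lab20)[lab20 == "P"] %in% names(lab15)[lab15 == "P"]))
  expect_true(all(names(lab20)[lab20 == "N"] %in% names(lab15)[lab15 == "N"]))
})

test_that("temporal groups are the four exclusive specificity patterns", {
  pat <- rbind(c("P", "P", "P"), c("none", "P", "P"), c("none", "none", "P"),
               c("P", "none", "none"), c("P", "P", "none"),
               c("N", "P", "P"), c("none", "none", "none"))
  g <- assign_temporal_group(pat[, 1], pat[, 2], pat[, 3])
  expect_equal(unname(g), c("A", "B", "C", "D", "unassigned", "B",
                            "unassigned"))

  # groups partition: every P-containing pattern gets exactly one label and
  # the A-D definitions recompute from the pattern
  set.seed(4)
  sp <- matrix(sample(c("P", "N", "none"), 3000, replace = TRUE), ncol = 3)
  g <- assign_temporal_group(sp[, 1], sp[, 2], sp[, 3])
  p <- sp == "P"
  expect_equal(g == "A", p[, 1] & p[, 2] & p[, 3])
  expect_equal(g == "B", !p[, 1] & p[, 2] & p[, 3])
  expect_equal(g == "C", !p[, 1] & !p[, 2] & p[, 3])
  expect_equal(g == "D", p[, 1] & !p[, 2] & !p[, 3])
  expect_true(all(g %in% c("A", "B", "C", "D", "unassigned")))
})

test_that("knockout calls follow the same strict ratio rule", {
  m <- mk_expr(c("a", "b"),
               "P12:P:control" = c(10, 7),
               "P12:P:CKO" = c(20, 7))
  calls <- classify_cko_regulation(m, "P", pseudocount = 0)
  expect_equal(unname(calls), c("up", "unchanged"))
  expect_error(classify_cko_regulation(m, "N"), "missing sample column")
})

test_that("venn partition equals direct set algebra", {
  v <- venn_partition(c("a", "b"), c("b", "c"))
  expect_equal(v, list(N_specific = "c", common = "b", P_specific = "a"))
  expect_equal(venn_partition("a", "b")$common, character())

  set.seed(5)
  universe <- sprintf("g%04d", 1:2000)
  p <- sample(universe, 500)
  n <- sample(universe, 500)
  v <- venn_partition(p, n)
  expect_setequal(v$common, intersect(p, n))
  expect_setequal(v$P_specific, setdiff(p, n))
  expect_setequal(v$N_specific, setdiff(n, p))
  expect_length(intersect(v$P_specific, v$N_specific), 0)
  expect_setequal(c(v$N_specific, v$common, v$P_specific), union(p, n))
})

test_that("regulation summary percentages recompute from their own counts", {
  set.seed(6)
  universe <- sprintf("g%04d", 1:800)
  up <- venn_partition(sample(universe, 120), sample(universe, 200))
  down <- venn_partition(sample(universe, 80), sample(universe, 60))
  subtypes <- list(s1 = sample(universe, 261), s2 = sample(universe, 27),
                   empty = character())
  summ <- build_regulation_summary(subtypes, up, down)
  for (col in grep("_n$", names(summ), value = TRUE)) {
    pct_col <- sub("_n$", "_pct", col)
    expect_equal(summ[[pct_col]],
                 ifelse(summ$gene_number == 0, 0,
                        round_half_away(100 * summ[[col]] /
                                          summ$gene_number)))
    expect_true(all(summ[[col]] <= summ$gene_number))
  }
  expect_equal(summ$gene_number[summ$subtype == "empty"], 0)
})

test_that("cell-type clustering keeps N-specific clusters only", {
  genes <- sprintf("g%02d", 1:20)
  pvals <- c(rep(10, 10), rep(40, 10))
  nvals <- c(rep(40, 10), rep(10, 10))  # first 10 N-specific (ratio 4)
  m <- mk_expr(genes,
               "P2:P:control" = pvals, "P2:N:control" = nvals,
               "P5:P:control" = pvals, "P5:N:control" = nvals,
               "P8:P:control" = pvals, "P8:N:control" = nvals)
  res <- celltype_relative_expression(m, genes, n_clusters = 2)
  expect_setequal(res$retained, genes[1:10])
  expect_equal(unname(res$profile["g01", "P2"]), 41 / 11)

  # genes absent from the matrix are reported and skipped
  expect_message(
    res2 <- celltype_relative_expression(m, c(genes, "missing"),
                                         n_clusters = 2),
    "skipping 1")
  expect_setequal(res2$missing, "missing")
  expect_equal(celltype_relative_expression(m, character())$retained,
               character())
})

test_that("validation candidates are low-fold group-A genes at >=2 stages", {
  m <- mk_expr(c("a", "b"),
               "P2:P:control" = c(18, 25), "P2:N:control" = c(10, 10),
               "P5:P:control" = c(17, 25), "P5:N:control" = c(10, 10),
               "P8:P:control" = c(30, 18), "P8:N:control" = c(10, 10))
  # ratios a: (1.8, 1.7, 3.0) -> selected; b: (2.5, 2.5, 1.8) -> not
  sel <- select_validation_candidates(m, c("a", "b"), fold = 2,
                                      pseudocount = 0)
  expect_equal(sel, "a")

  set.seed(7)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  cols <- list()
  for (st in c("P2", "P5", "P8")) {
    cols[[sample_id(st, "P")]] <- rlnorm(n, 2, 1)
    cols[[sample_id(st, "N")]] <- rlnorm(n, 2, 1)
  }
  m2 <- do.call(mk_expr, c(list(genes), cols))
  sel2 <- select_validation_candidates(m2, genes, fold = 2, pseudocount = 1)
  oracle <- character()
  for (g in genes) {
    low <- 0
    for (st in c("P2", "P5", "P8")) {
      r <- (m2[g, sample_id(st, "P")] + 1) / (m2[g, sample_id(st, "N")] + 1)
      if (r < 2) low <- low + 1
    }
    if (low >= 2) oracle <- c(oracle, g)
  }
  expect_equal(sel2, oracle)
})

test_that("not-expressed filter flags genes below threshold everywhere", {
  m <- mk_expr(c("zero", "low", "one_high"),
               "P2:P:control" = c(0, 0.5, 0.2),
               "P2:N:control" = c(0, 0.9, 3))
  f <- nonexpressed_filter(m, threshold = 1)
  expect_setequal(f$not_expressed, c("zero", "low"))
  expect_setequal(f$expressed, "one_high")

  set.seed(8)
  m2 <- matrix(rlnorm(2000, 0, 2), 500,
               dimnames = list(sprintf("g%03d", 1:500), NULL))
  colnames(m2) <- c("P2:P:control", "P2:N:control", "P5:P:control",
                    "P5:N:control")
  f2 <- nonexpressed_filter(m2, threshold = 1)
  oracle <- rownames(m2)[apply(m2, 1, max) < 1]
  expect_setequal(f2$not_expressed, oracle)
})
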
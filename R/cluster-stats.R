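# Clustering of expression / histone-score profiles and the statistical
# comparisons used across the analysis (two-sample Kolmogorov-Smirnov,
# Welch t with point-biserial r, box-plot summaries).

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  idx <- sample.int(n, 1)
  centers[1, ] <- m[idx, ]
  if (k > 1) {
    d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- m[idx, ]
      d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' K-means clustering of profiles with k-means++ seeding
#'
#' Lloyd's algorithm from a k-means++ initialization, deterministic given
#' the seed. Expression profiles are conventionally clustered on
#' log2(FPKM + 1); histone profiles on quantile-normalized scores.
#'
#' @param m Numeric item x feature matrix (finite values).
#' @param k Number of clusters; default 15.
#' @param seed Required integer seed.
#' @param max_iter Maximum Lloyd iterations.
#' @param n_retry Re-seeding attempts if an empty cluster arises.
#' @return List with `labels` (named by rownames), `centers`, `k`,
#'   `withinss`, and `tot_withinss`.
#' @export
kmeans_profiles <- function(m, k = 15, seed, max_iter = 100, n_retry = 5) {
  stopifnot(is.matrix(m), all(is.finite(m)))
  if (missing(seed)) stop("kmeans_profiles: 'seed' is required")
  if (k > nrow(m)) stop("kmeans_profiles: k exceeds the number of items")
  for (attempt in seq_len(n_retry)) {
    km <- withr::with_seed(as.integer(seed) + attempt - 1L, {
      centers <- kmeanspp_centers(m, k)
      tryCatch(
        suppressWarnings(stats::kmeans(m, centers = centers,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
    })
    if (!is.null(km) && all(km$size > 0)) break
  }
  if (is.null(km)) stop("kmeans_profiles: clustering failed")
  list(labels = stats::setNames(km$cluster, rownames(m)),
       centers = km$centers, k = k, withinss = km$withinss,
       tot_withinss = km$tot.withinss)
}

#' Hierarchical subclustering
#'
#' Agglomerative clustering with Euclidean distance and average linkage,
#' cut to `n_clusters` groups — used e.g. to split the photoreceptor
#' group-A genes into subclusters on their H3K4me3/H3K27me3 scores.
#'
#' @param m Numeric item x feature matrix.
#' @param n_clusters Number of clusters to cut to.
#' @param method Linkage; default `"average"`.
#' @return List with `labels` (named by rownames), `tree` (the `hclust`
#'   object), and `n_clusters`.
#' @export
hierarchical_subcluster <- function(m, n_clusters, method = "average") {
  stopifnot(is.matrix(m))
  if (n_clusters > nrow(m)) {
    stop("hierarchical_subcluster: fewer items than clusters")
  }
  tree <- stats::hclust(stats::dist(m), method = method)
  labels <- stats::cutree(tree, k = n_clusters)
  list(labels = stats::setNames(labels, rownames(m)), tree = tree,
       n_clusters = n_clusters)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the two-sided
#' p-value uses the asymptotic Kolmogorov distribution at effective sample
#' size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("ks_two_sample: empty input")
  pooled <- sort(unique(c(a, b)))
  d <- max(abs(vapply(pooled, function(x) mean(a <= x) - mean(b <= x),
                      numeric(1))))
  neff <- length(a) * length(b) / (length(a) + length(b))
  t_stat <- sqrt(neff) * d
  p <- if (d == 0) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t_stat^2))))
  }
  list(statistic = d, p_value = p, n_a = length(a), n_b = length(b))
}

#' Welch t test with point-biserial effect size
#'
#' Two-sample unequal-variance t test plus the point-biserial correlation
#' r between the group indicator (1 for `group1`) and the pooled values, as
#' the effect size. Two degenerate constant groups with equal means return
#' t = 0, p = 1, r = 0.
#'
#' @param group1,group2 Numeric samples with >= 2 values each.
#' @return List with `statistic` (t), `df`, `p_value`, `r`, `n1`, `n2`.
#' @export
t_test_with_r <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  tt <- tryCatch(stats::t.test(group1, group2, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both groups constant; equal means -> no effect
    return(list(statistic = 0, df = length(group1) + length(group2) - 2,
                p_value = 1, r = 0,
                n1 = length(group1), n2 = length(group2)))
  }
  ind <- c(rep(1, length(group1)), rep(0, length(group2)))
  vals <- c(group1, group2)
  r <- if (stats::sd(vals) == 0) 0 else stats::cor(ind, vals)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, r = r,
       n1 = length(group1), n2 = length(group2))
}

#' Five-number box-plot summaries per group
#'
#' Min, lower quartile, median, upper quartile, max per group, with
#' linear-interpolation quantiles (type 7).
#'
#' @param values_by_group Named list of non-empty numeric vectors.
#' @return Data frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
boxplot_summary <- function(values_by_group) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  rows <- lapply(names(values_by_group), function(nm) {
    x <- values_by_group[[nm]]
    x <- x[!is.na(x)]
    stopifnot(length(x) >= 1)
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    data.frame(group = nm, n = length(x), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
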
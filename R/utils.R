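# Small shared numerical helpers.

#' Round half away from zero
#'
#' Integer rounding used for all printed percentages: halves round away from
#' zero (so 29.5 -> 30), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Integer percentage of a count
#'
#' @param count Numerator count(s).
#' @param total Denominator; a total of 0 yields 0.
#' @return Integer percentage(s), rounded half away from zero.
#' @export
percentage_of <- function(count, total) {
  if (length(total) == 1L && total == 0) {
    return(rep(0, length(count)))
  }
  round_half_away(100 * count / total)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score for separating positives from
#' negatives. Equals 1 when every positive scores strictly above every
#' negative.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param positive Logical vector, same length as `scores`.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  keep <- !is.na(scores) & !is.na(positive)
  scores <- scores[keep]
  positive <- positive[keep]
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc() needs at least one positive and one negative score")
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Zero-mean normal draw truncated to [-bound, bound]; sd = 0 collapses to 0.
rnorm_trunc <- function(n, sd, bound) {
  stopifnot(bound > 0)
  if (sd <= 0) {
    return(numeric(n))
  }
  lo <- stats::pnorm(-bound, sd = sd)
  hi <- stats::pnorm(bound, sd = sd)
  stats::qnorm(stats::runif(n, lo, hi), sd = sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
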
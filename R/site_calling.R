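#' Uniform site calling
#'
#' Every technique is called the same way: a one-sided exact binomial test of
#' the per-site m6A count against the sample-wide background rate
#' `p0 = sum(m6a) / sum(total)`, followed by Benjamini-Hochberg correction
#' over the sites that are testable (`total > 0`) in that column.
#'
#' @name site_calling
NULL

#' Sample-wide background methylation rate
#'
#' `p0 = sum(m6a_count) / sum(total_count)` over all sites of one sample
#' (or of one aggregated column). When IVT calibration has been applied the
#' masked cells are zero in both layers and so drop out of both sums.
#'
#' @param m6a,total integer vectors, or a `SummarizedExperiment` plus
#'   `sample` id.
#' @param se methylation `SummarizedExperiment`.
#' @param sample column id within `se`.
#' @return the scalar background proportion.
#' @export
estimate_background_rate <- function(m6a, total) {
  assert_that(length(m6a) == length(total), "layer lengths differ")
  tt <- sum(as.numeric(total))
  assert_that(tt > 0, "zero total coverage: background rate undefined")
  sum(as.numeric(m6a)) / tt
}

#' @rdname estimate_background_rate
#' @export
background_rate_sample <- function(se, sample) {
  estimate_background_rate(
    SummarizedExperiment::assay(se, "m6a_count")[, sample],
    SummarizedExperiment::assay(se, "total_count")[, sample])
}

#' One-sided exact binomial tail test
#'
#' `p = P(X >= k)` for `X ~ Binomial(n, p0)` (alternative "greater"); the
#' exact tail is used for every `n` (`pbinom` evaluates the survival
#' function directly, so no normal approximation is ever needed). `n = 0`
#' gives `p = 1`.
#'
#' @param k,n observed m6A count and total coverage (vectors recycle).
#' @param p0 background success probability.
#' @return vector of upper-tail p-values.
#' @export
binomial_test_site <- function(k, n, p0) {
  assert_that(all(k <= n), "k must be <= n")
  assert_that(all(k >= 0) && all(n >= 0), "counts must be >= 0")
  assert_that(all(p0 >= 0) && all(p0 <= 1), "p0 must lie in [0,1]")
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min(1, min_{j >= i} p_(j) * m / j)`, returned in input order.
#' Implemented directly from the step-up definition.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Binomial site calling over a methylation matrix
#'
#' Per column: p-values at every site with `total > 0`, BH correction over
#' exactly those sites, call = `bh_p < alpha`. Sites with `total = 0` get
#' `p = 1`, `bh_p = 1`, no call, and are excluded from the BH family so they
#' do not dilute the correction.
#'
#' @param se methylation `SummarizedExperiment` (calibrated if applicable).
#' @param alpha BH-adjusted significance threshold.
#' @param samples which columns to call; default all.
#' @return `se` with added assays `p_value`, `bh_p` and logical `call`.
#' @export
call_sites_binomial <- function(se, alpha = 0.05, samples = NULL) {
  m6a <- SummarizedExperiment::assay(se, "m6a_count")
  tot <- SummarizedExperiment::assay(se, "total_count")
  samples <- samples %||% colnames(se)
  pv <- bh <- matrix(1, nrow(se), ncol(se),
                     dimnames = dimnames(m6a))
  cl <- matrix(FALSE, nrow(se), ncol(se), dimnames = dimnames(m6a))
  for (s in samples) {
    res <- call_sites_vector(m6a[, s], tot[, s], alpha = alpha)
    pv[, s] <- res$p_value; bh[, s] <- res$bh_p; cl[, s] <- res$call
  }
  SummarizedExperiment::assay(se, "p_value") <- pv
  SummarizedExperiment::assay(se, "bh_p") <- bh
  SummarizedExperiment::assay(se, "call") <- cl
  se
}

#' @rdname call_sites_binomial
#' @param m6a,total count vectors for one column (e.g. an aggregate).
#' @export
call_sites_vector <- function(m6a, total, alpha = 0.05) {
  testable <- total > 0
  p <- rep(1, length(m6a))
  bh <- rep(1, length(m6a))
  if (any(testable)) {
    p0 <- estimate_background_rate(m6a, total)
    p[testable] <- binomial_test_site(m6a[testable], total[testable], p0)
    bh[testable] <- bh_adjust(p[testable])
  }
  list(p_value = p, bh_p = bh, call = bh < alpha & testable,
       p0 = if (any(testable)) p0 else NA_real_)
}
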
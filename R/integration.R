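#' Orthogonal validation of m6A sites across technique pairs
#'
#' Counts are aggregated within each technique (baseline samples, or samples
#' of one condition), converted to beta values `beta = m6A / (m6A + A)` with
#' multiplicative tie-breaking jitter, restricted to sites with aggregated
#' coverage >= 20 in both techniques, and fed to the copula-mixture IDR
#' model. A site is orthogonally validated when all three criteria hold:
#' global IDR < 0.05, and a BH-adjusted binomial p-value < 0.05 in each
#' technique (computed on the same aggregated, filtered site set).
#'
#' @name integration
NULL

#' Technical orthogonality of two assay categories
#'
#' Categories (`antibody`, `enzyme`, `chemical`, `direct`) are orthogonal
#' when they differ, with one exception: direct RNA sequencing and antibody
#' assays are non-orthogonal in either order, because the base-caller models
#' used by direct sequencing are trained on antibody-derived data.
#'
#' @param category1,category2 category labels.
#' @param technique1,technique2 optional technique names (informational).
#' @return logical.
#' @export
is_orthogonal <- function(category1, category2,
                          technique1 = NULL, technique2 = NULL) {
  cats <- c("antibody", "enzyme", "chemical", "direct")
  assert_that(category1 %in% cats && category2 %in% cats,
              "unknown assay category")
  if (category1 == category2) return(FALSE)
  pair <- sort(c(category1, category2))
  !(identical(pair, c("antibody", "direct")))
}

#' Aggregate count layers over selected samples
#'
#' Elementwise sums of `m6a_count` and `total_count` over the selected
#' columns: all baseline samples by default, a named condition, or an
#' explicit sample vector.
#'
#' @param se methylation `SummarizedExperiment`.
#' @param filter `"baseline"` or a condition label matched against
#'   `colData$condition` (ignored when `samples` given).
#' @param samples explicit sample ids.
#' @param cell_or_tissue optional additional stratum filter.
#' @return list with numeric vectors `m6a`, `total` and the `samples` used.
#' @export
aggregate_counts <- function(se, filter = "baseline", samples = NULL,
                             cell_or_tissue = NULL) {
  cd <- SummarizedExperiment::colData(se)
  if (is.null(samples)) {
    keep <- if (identical(filter, "baseline")) cd$baseline %in% TRUE
            else cd$condition == filter
    keep <- keep & !(cd$is_ivt %in% TRUE)
    if (!is.null(cell_or_tissue)) keep <- keep & cd$cell_or_tissue == cell_or_tissue
    samples <- rownames(cd)[keep]
  }
  assert_that(length(samples) >= 1, "sample selection is empty")
  m6a <- SummarizedExperiment::assay(se, "m6a_count")[, samples, drop = FALSE]
  tot <- SummarizedExperiment::assay(se, "total_count")[, samples, drop = FALSE]
  list(m6a = rowSums(m6a), total = rowSums(tot), samples = samples)
}

#' Beta values with tie-breaking jitter
#'
#' `beta = m6A / (m6A + A)` per site, `NA` where total coverage is zero.
#' A multiplicative uniform jitter on `(1 - f, 1 + f)` with
#' `f = jitter_factor` breaks ties deterministically given `seed`; zero
#' betas are jittered additively on `(0, f)` so ties at zero also resolve.
#'
#' @param m6a,total aggregated counts.
#' @param jitter_factor relative jitter magnitude (0 disables).
#' @param seed RNG seed recorded with the result.
#' @return list `beta` (jittered), `beta_raw`, `jittered`, `seed`.
#' @export
compute_beta <- function(m6a, total, jitter_factor = 1e-4, seed = NULL) {
  assert_that(all(m6a >= 0) && all(total >= 0), "negative counts")
  assert_that(all(m6a <= total), "m6a must be <= total")
  beta <- ifelse(total > 0, m6a / total, NA_real_)
  out <- beta
  if (jitter_factor > 0) {
    out <- with_seed_if(seed, {
      ok <- !is.na(beta)
      j <- beta
      j[ok] <- beta[ok] * stats::runif(sum(ok), 1 - jitter_factor,
                                       1 + jitter_factor)
      zero <- ok & beta == 0
      j[zero] <- stats::runif(sum(zero), 0, jitter_factor)
      j
    })
  }
  list(beta = out, beta_raw = beta, jittered = jitter_factor > 0, seed = seed)
}

#' Pairwise aggregated-coverage filter
#'
#' @param total1,total2 aggregated total coverage per technique.
#' @param min_cov both totals must be `>= min_cov`.
#' @return integer indices passing the filter.
#' @export
pairwise_coverage_filter <- function(total1, total2, min_cov = 20) {
  assert_that(length(total1) == length(total2), "length mismatch")
  which(total1 >= min_cov & total2 >= min_cov)
}

#' Three-criterion orthogonal validation decision
#'
#' @param idr_fit an [fit_idr] result on the filtered site pair.
#' @param calls1,calls2 logical binomial calls (BH p < 0.05) per technique,
#'   aligned with the fit's site index.
#' @param idr_alpha threshold on the global IDR.
#' @return data.frame with `idr_local`, `idr_global`, `call_tech1`,
#'   `call_tech2`, `validated`.
#' @export
validate_sites <- function(idr_fit, calls1, calls2, idr_alpha = 0.05) {
  assert_that(inherits(idr_fit, "idr_fit"), "idr_fit required")
  assert_that(length(calls1) == idr_fit$n && length(calls2) == idr_fit$n,
              "call vectors must align with the IDR fit index")
  data.frame(
    idr_local = idr_fit$idr_local,
    idr_global = idr_fit$idr_global,
    call_tech1 = as.logical(calls1),
    call_tech2 = as.logical(calls2),
    validated = idr_fit$idr_global < idr_alpha & calls1 & calls2
  )
}

#' End-to-end orthogonal validation of a technique pair
#'
#' Runs the full chain on two calibrated matrices sharing one site set:
#' aggregation, binomial calling on the aggregates, beta + jitter, coverage
#' filter, IDR fit, three-criterion decision.
#'
#' @param se1,se2 methylation `SummarizedExperiment`s (same row space).
#' @param condition `"baseline"` or a condition label.
#' @param min_cov aggregated-coverage threshold.
#' @param idr_alpha,call_alpha thresholds for IDR and binomial calls.
#' @param jitter_factor,seed see [compute_beta].
#' @param check_orthogonality error if the two categories are not orthogonal.
#' @return list: `result` (validation data.frame with site ids and betas),
#'   `fit`, `index` (row indices that passed the filter), `pair`.
#' @export
validate_pair <- function(se1, se2, condition = "baseline", min_cov = 20,
                          idr_alpha = 0.05, call_alpha = 0.05,
                          jitter_factor = 1e-4, seed = 1L,
                          check_orthogonality = TRUE) {
  assert_that(nrow(se1) == nrow(se2) &&
                all(rownames(se1) == rownames(se2)),
              "matrices must share one reference site set")
  cat1 <- unique(SummarizedExperiment::colData(se1)$category)[1]
  cat2 <- unique(SummarizedExperiment::colData(se2)$category)[1]
  if (check_orthogonality && !is_orthogonal(cat1, cat2)) {
    stop2(sprintf("categories %s/%s are not technically orthogonal", cat1, cat2))
  }
  agg1 <- aggregate_counts(se1, filter = condition)
  agg2 <- aggregate_counts(se2, filter = condition)
  idx <- pairwise_coverage_filter(agg1$total, agg2$total, min_cov)
  assert_that(length(idx) >= 100,
              "fewer than 100 sites pass the pairwise coverage filter")
  b1 <- compute_beta(agg1$m6a[idx], agg1$total[idx],
                     jitter_factor = jitter_factor, seed = seed)
  b2 <- compute_beta(agg2$m6a[idx], agg2$total[idx],
                     jitter_factor = jitter_factor,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  fit <- fit_idr(b1$beta, b2$beta)
  c1 <- call_sites_vector(agg1$m6a[idx], agg1$total[idx],
                          alpha = call_alpha)$call
  c2 <- call_sites_vector(agg2$m6a[idx], agg2$total[idx],
                          alpha = call_alpha)$call
  res <- validate_sites(fit, c1, c2, idr_alpha = idr_alpha)
  res <- cbind(data.frame(site_id = rownames(se1)[idx],
                          beta_tech1 = b1$beta_raw, beta_tech2 = b2$beta_raw),
               res)
  list(result = res, fit = fit, index = idx,
       pair = paste(cat1, cat2, sep = "x"), condition = condition)
}

#' Orthogonal validation of differential methylation
#'
#' The IDR input is the per-technique difference in beta values between
#' treated and control aggregates, restricted to sites with coverage
#' >= `min_cov` in all four aggregates. A validated differentially
#' methylated (DM) site has global IDR < `idr_alpha`.
#'
#' @param m6a_t1,tot_t1 treated counts, technique 1 (and so on for
#'   `_c1`, `_t2`, `_c2`).
#' @param min_cov coverage threshold applied to all four totals.
#' @param idr_alpha IDR threshold.
#' @param jitter_factor,seed see [compute_beta].
#' @return list: `fit`, `index`, `delta1`, `delta2`, `validated` (logical
#'   over `index`), `degenerate`.
#' @export
differential_idr <- function(m6a_t1, tot_t1, m6a_c1, tot_c1,
                             m6a_t2, tot_t2, m6a_c2, tot_c2,
                             min_cov = 20, idr_alpha = 0.05,
                             jitter_factor = 1e-4, seed = 1L) {
  lens <- lengths(list(m6a_t1, tot_t1, m6a_c1, tot_c1,
                       m6a_t2, tot_t2, m6a_c2, tot_c2))
  assert_that(length(unique(lens)) == 1L, "count vectors must align")
  idx <- which(tot_t1 >= min_cov & tot_c1 >= min_cov &
                 tot_t2 >= min_cov & tot_c2 >= min_cov)
  assert_that(length(idx) >= 100,
              "fewer than 100 sites pass the coverage filter")
  beta <- function(k, n) ifelse(n > 0, k / n, NA_real_)
  d1 <- beta(m6a_t1[idx], tot_t1[idx]) - beta(m6a_c1[idx], tot_c1[idx])
  d2 <- beta(m6a_t2[idx], tot_t2[idx]) - beta(m6a_c2[idx], tot_c2[idx])
  degenerate <- (length(unique(d1)) == 1L) || (length(unique(d2)) == 1L)
  if (degenerate) {
    warning("beta differences are constant (all ties) before jitter; fit flagged degenerate")
  }
  jd1 <- jitter_values(d1, jitter_factor, seed)
  jd2 <- jitter_values(d2, jitter_factor,
                       if (is.null(seed)) NULL else seed + 1L)
  fit <- fit_idr(jd1, jd2)
  list(fit = fit, index = idx, delta1 = d1, delta2 = d2,
       validated = fit$idr_global < idr_alpha, degenerate = degenerate)
}

# multiplicative jitter for signed values (beta differences): relative where
# nonzero, additive on (-f, f) at exact zeros
jitter_values <- function(x, jitter_factor = 1e-4, seed = NULL) {
  if (jitter_factor <= 0) return(x)
  with_seed_if(seed, {
    out <- x * stats::runif(length(x), 1 - jitter_factor, 1 + jitter_factor)
    zero <- !is.na(x) & x == 0
    out[zero] <- stats::runif(sum(zero), -jitter_factor, jitter_factor)
    out
  })
}

#' Export validated sites as BED6 + CSV
#'
#' @param validation result of [validate_pair].
#' @param sites the full [site_set] matching the matrices.
#' @param prefix output prefix (`<prefix>.bed`, `<prefix>.csv`).
#' @export
write_validation <- function(validation, sites, prefix) {
  res <- validation$result
  keep <- sites[validation$index, , drop = FALSE][res$validated, ,
                                                  drop = FALSE]
  write_sites_bed(validate_site_set(keep), paste0(prefix, ".bed"))
  utils::write.table(res, paste0(prefix, ".csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
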
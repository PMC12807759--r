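#' IVT negative-control calibration
#'
#' In-vitro-transcribed (IVT) samples are modification-free, so any site the
#' binomial caller flags in them is a technique-specific false positive. The
#' mask zeroes both count layers at those sites for every sample of the
#' technique, which removes them self-consistently from the background rate
#' and every downstream aggregation.
#'
#' @name calibration
NULL

#' Flag false-positive sites from IVT controls
#'
#' Counts are summed across the named IVT samples, binomial site calling is
#' run on the aggregate, and called sites become the mask.
#'
#' @param se methylation `SummarizedExperiment`.
#' @param ivt_sample_ids columns with `is_ivt = TRUE`.
#' @param alpha BH threshold for the IVT call.
#' @return object of class `fp_mask`: logical vector over sites plus
#'   provenance (`ivt_samples`, `alpha`, `technique`).
#' @export
flag_ivt_false_positives <- function(se, ivt_sample_ids = NULL, alpha = 0.05) {
  cd <- SummarizedExperiment::colData(se)
  if (is.null(ivt_sample_ids)) {
    ivt_sample_ids <- rownames(cd)[cd$is_ivt %in% TRUE]
  }
  assert_that(length(ivt_sample_ids) > 0, "no IVT samples available")
  assert_that(all(cd[ivt_sample_ids, "is_ivt"] %in% TRUE),
              "named samples must have is_ivt = TRUE")
  agg <- aggregate_counts(se, samples = ivt_sample_ids)
  if (all(agg$total == 0)) {
    warning("IVT samples have no coverage anywhere; empty mask")
    mask <- rep(FALSE, nrow(se))
  } else {
    mask <- call_sites_vector(agg$m6a, agg$total, alpha = alpha)$call
  }
  structure(list(mask = mask, ivt_samples = ivt_sample_ids, alpha = alpha,
                 technique = unique(cd[ivt_sample_ids, "technique"])),
            class = "fp_mask")
}

#' Zero count layers at masked sites
#'
#' `m6a_count` and `total_count` are set to 0 at masked rows for every
#' column; other cells and layers are untouched. Idempotent.
#'
#' @param se methylation `SummarizedExperiment`.
#' @param mask an `fp_mask` or logical vector of length `nrow(se)`.
#' @return the masked `SummarizedExperiment` (metadata records the mask).
#' @export
mask_sites <- function(se, mask) {
  if (inherits(mask, "fp_mask")) mask <- mask$mask
  assert_that(length(mask) == nrow(se), "mask length must equal site count")
  m6a <- SummarizedExperiment::assay(se, "m6a_count")
  tot <- SummarizedExperiment::assay(se, "total_count")
  m6a[mask, ] <- 0L
  tot[mask, ] <- 0L
  SummarizedExperiment::assay(se, "m6a_count") <- m6a
  SummarizedExperiment::assay(se, "total_count") <- tot
  S4Vectors::metadata(se)$fp_mask <- mask
  se
}

#' @export
print.fp_mask <- function(x, ...) {
  cat(sprintf("IVT false-positive mask: %d/%d sites (alpha=%.3g, IVT: %s)\n",
              sum(x$mask), length(x$mask), x$alpha,
              paste(x$ivt_samples, collapse = ",")))
  invisible(x)
}

#' Write a false-positive mask to BED6 + TSV
#'
#' @param mask an `fp_mask`.
#' @param sites the matching [site_set].
#' @param prefix output path prefix (writes `<prefix>.bed`, `<prefix>.tsv`).
#' @export
write_mask <- function(mask, sites, prefix) {
  flagged <- validate_site_set(sites[mask$mask, , drop = FALSE])
  write_sites_bed(flagged, paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(site_id = sites$site_id, masked = mask$mask),
    paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
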
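#' Methylation count matrices
#'
#' The central container is a `SummarizedExperiment` whose rows are a
#' reference [site_set] (carried as `rowData` plus `rowRanges`) and whose
#' columns are samples described by [sample_record] metadata. Two integer
#' assays are mandatory and complete (zeros, never gaps): `m6a_count` and
#' `total_count` with `0 <= m6a_count <= total_count` elementwise. Derived
#' real-valued layers (`p_value`, `bh_p`, `posterior_m6a`, ...) may be added
#' by the calling functions.
#'
#' @name methylation_matrix
NULL

#' Sample metadata records
#'
#' Builds the per-sample metadata table used as `colData`. `category` must be
#' one of `antibody`, `enzyme`, `chemical`, `direct`; antibody samples used
#' for site calling need a resolvable `paired_input_id`.
#'
#' @param sample_id unique sample identifiers.
#' @param technique assay name (e.g. `"MeRIP-seq"`, `"GLORI"`).
#' @param category biochemical principle class.
#' @param condition condition label; `baseline` flags non-perturbation samples.
#' @param is_ivt logical, in-vitro-transcribed negative control.
#' @param cell_or_tissue label.
#' @param paired_input_id for antibody assays, the matching input sample.
#' @param baseline logical baseline flag.
#' @return a `data.frame` of sample records.
#' @export
sample_record <- function(sample_id, technique = "unknown",
                          category = c("antibody", "enzyme", "chemical",
                                       "direct"),
                          condition = "baseline", baseline = NULL,
                          is_ivt = FALSE, cell_or_tissue = "unknown",
                          paired_input_id = NA_character_) {
  n <- length(sample_id)
  category <- as.character(category)
  if (length(category) > 1L && length(category) != n) category <- category[1]
  assert_that(all(category %in% c("antibody", "enzyme", "chemical", "direct")),
              "category must be antibody/enzyme/chemical/direct")
  assert_that(!anyDuplicated(sample_id), "duplicate sample_id")
  if (is.null(baseline)) baseline <- rep_len(condition, n) == "baseline"
  data.frame(
    sample_id = as.character(sample_id),
    technique = rep_len(technique, n),
    category = rep_len(category, n),
    condition = rep_len(condition, n),
    baseline = rep_len(baseline, n),
    is_ivt = rep_len(is_ivt, n),
    cell_or_tissue = rep_len(cell_or_tissue, n),
    paired_input_id = rep_len(paired_input_id, n),
    stringsAsFactors = FALSE
  )
}

#' Assemble a methylation matrix from per-sample count vectors
#'
#' Column-binds per-sample `(m6a, total)` vectors over a common site set and
#' validates the container invariants.
#'
#' @param m6a,total matrices (sites x samples) or lists of per-sample vectors,
#'   each of length `nrow(sites)`.
#' @param sites a [site_set].
#' @param samples a [sample_record] data.frame, one row per column.
#' @return a `SummarizedExperiment` with assays `m6a_count`, `total_count`.
#' @export
assemble_matrix <- function(m6a, total, sites, samples) {
  sites <- validate_site_set(sites)
  if (is.list(m6a) && !is.matrix(m6a)) m6a <- do.call(cbind, m6a)
  if (is.list(total) && !is.matrix(total)) total <- do.call(cbind, total)
  m6a <- as.matrix(m6a); total <- as.matrix(total)
  assert_that(nrow(m6a) == nrow(sites) && nrow(total) == nrow(sites),
              "count vectors must have one entry per site")
  assert_that(all(dim(m6a) == dim(total)), "layer dimensions differ")
  assert_that(ncol(m6a) == nrow(samples),
              "one metadata row per sample column required")
  assert_that(!anyDuplicated(samples$sample_id), "duplicate sample_id")
  assert_that(!anyNA(m6a) && !anyNA(total),
              "count layers must be complete (zeros, not gaps)")
  assert_that(all(m6a >= 0) && all(total >= 0), "counts must be >= 0")
  assert_that(all(m6a <= total), "m6a_count must be <= total_count")
  storage.mode(m6a) <- "integer"; storage.mode(total) <- "integer"
  dimnames(m6a) <- dimnames(total) <- list(sites$site_id, samples$sample_id)
  rr <- site_granges(sites)
  names(rr) <- sites$site_id
  S4Vectors::mcols(rr)$motif <- sites$motif
  S4Vectors::mcols(rr)$provenance <- sites$provenance
  SummarizedExperiment::SummarizedExperiment(
    assays = list(m6a_count = m6a, total_count = total),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  )
}

#' @rdname methylation_matrix
#' @param se a methylation `SummarizedExperiment`.
#' @return `matrix_sites` reconstructs the [site_set] from `rowRanges`.
#' @export
matrix_sites <- function(se) {
  rr <- SummarizedExperiment::rowRanges(se)
  site_set(as.character(GenomicRanges::seqnames(rr)),
           BiocGenerics::start(rr),
           as.character(BiocGenerics::strand(rr)),
           motif = S4Vectors::mcols(rr)$motif %||% NA_character_,
           site_id = names(rr),
           provenance = S4Vectors::mcols(rr)$provenance %||% "unknown")
}

#' Serialize count layers to TSV and back
#'
#' One TSV per layer: `site_id` column followed by one column per sample.
#' `read_matrix_tsv` re-assembles the full container given the layer files,
#' sites and sample metadata.
#'
#' @param se methylation `SummarizedExperiment`.
#' @param dir output directory (created if missing).
#' @param layers which assays to write; default all.
#' @export
write_matrix_tsv <- function(se, dir, layers = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layers <- layers %||% SummarizedExperiment::assayNames(se)
  for (ly in layers) {
    m <- SummarizedExperiment::assay(se, ly)
    dt <- data.table::data.table(site_id = rownames(m))
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, file.path(dir, paste0(ly, ".tsv")), sep = "\t")
  }
  data.table::fwrite(
    as.data.frame(SummarizedExperiment::colData(se)),
    file.path(dir, "samples.tsv"), sep = "\t")
  write_sites_bed(matrix_sites(se), file.path(dir, "sites.bed"))
  invisible(dir)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(dir) {
  sites <- read_sites_bed(file.path(dir, "sites.bed"))
  samples <- as.data.frame(data.table::fread(file.path(dir, "samples.tsv")))
  rd <- function(ly) {
    dt <- data.table::fread(file.path(dir, paste0(ly, ".tsv")))
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt$site_id
    m[sites$site_id, samples$sample_id, drop = FALSE]
  }
  se <- assemble_matrix(rd("m6a_count"), rd("total_count"), sites, samples)
  extra <- setdiff(sub("\\.tsv$", "", list.files(dir, "\\.tsv$")),
                   c("m6a_count", "total_count", "samples"))
  for (ly in extra) SummarizedExperiment::assay(se, ly) <- rd(ly)
  se
}
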
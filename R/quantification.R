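#' Alignment-based quantification against reference sites
#'
#' Two counting contracts produce the `(m6a_count, total_count)` layers:
#' overlap counting for antibody enrichment assays (IP fragments over the
#' single-base site; total = IP + paired input) and per-base pileup counting
#' for base-conversion chemistries (reads showing the unconverted A are
#' methylated evidence). No post-alignment MAPQ or duplicate filtering is
#' applied here; upstream filtering is the caller's responsibility.
#'
#' @name quantification
NULL

# Accept SAM or BAM; return an indexed BamFile. SAM (and BAM without an
# index) are converted/indexed into tempdir so repository fixtures can stay
# plain text.
ensure_bam <- function(path) {
  assert_that(file.exists(path), paste("alignment file not found:", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    sorted <- tempfile(fileext = ".bam")
    path <- Rsamtools::sortBam(path, sub("\\.bam$", "", sorted))
    Rsamtools::indexBam(path)
  }
  Rsamtools::BamFile(path)
}

# Fragment-level ranges: properly paired mates unified by template span,
# everything else (single-end) one range per read.
read_fragments <- function(bam) {
  galp <- suppressWarnings(GenomicAlignments::readGAlignmentPairs(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE))))
  frags <- GenomicRanges::granges(galp)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = FALSE)))
  c(frags, GenomicRanges::granges(gal))
}

check_site_chroms <- function(sites, bam) {
  hdr <- Rsamtools::scanBamHeader(bam$path)[[1]]$targets
  missing <- setdiff(unique(sites$chrom), names(hdr))
  if (length(missing)) {
    warning(sprintf("site chromosomes absent from alignment header (%s); counted as 0",
                    paste(missing, collapse = ",")))
  }
  missing
}

#' Count IP/input fragment overlaps at single-base sites
#'
#' `m6a` = number of IP fragments whose aligned span overlaps the site (a
#' properly paired mate pair counts once, via its template span); `total` =
#' `m6a` + the analogous count in the paired input sample.
#'
#' @param ip_alignments,input_alignments SAM/BAM paths.
#' @param sites a [site_set].
#' @param stranded if `TRUE`, only fragments on the site's strand count;
#'   the default for IP overlap counting is strand-agnostic.
#' @return list with integer vectors `m6a` and `total` (length = sites).
#' @export
count_ip_input <- function(ip_alignments, input_alignments, sites,
                           stranded = FALSE) {
  sites <- validate_site_set(sites)
  ip <- count_fragment_overlaps(ip_alignments, sites, stranded)
  inp <- count_fragment_overlaps(input_alignments, sites, stranded)
  list(m6a = ip, total = ip + inp)
}

count_fragment_overlaps <- function(path, sites, stranded = FALSE) {
  bam <- ensure_bam(path)
  check_site_chroms(sites, bam)
  frags <- read_fragments(bam)
  gr <- site_granges(sites)
  shared <- intersect(GenomeInfoDb::seqlevels(gr),
                      GenomeInfoDb::seqlevels(frags))
  n <- integer(nrow(sites))
  on_shared <- sites$chrom %in% shared
  if (any(on_shared)) {
    gr2 <- GenomeInfoDb::keepSeqlevels(gr[on_shared], shared,
                                       pruning.mode = "coarse")
    frags <- GenomeInfoDb::keepSeqlevels(frags, shared,
                                         pruning.mode = "coarse")
    n[on_shared] <- GenomicRanges::countOverlaps(gr2, frags,
                                                 ignore.strand = !stranded)
  }
  n
}

#' Count conversion-chemistry pileups at single-base sites
#'
#' For A-to-G style conversion chemistries the methylated (protected) base
#' remains A on the sense strand while unmethylated A reads as G. The rule
#' names which sense-strand read bases count as methylated evidence and which
#' enter the denominator; reads with deletions or bases outside
#' `total_bases` at the site are excluded from both counts. Minus-strand
#' sites are read complement-aware.
#'
#' @param alignments SAM/BAM path.
#' @param sites a [site_set].
#' @param rule list with character vectors `m6a_bases` (default `"A"`) and
#'   `total_bases` (default `c("A","G")`), on the site's sense strand.
#' @return list with integer vectors `m6a` and `total`.
#' @export
count_conversion_pileup <- function(alignments, sites,
                                    rule = list(m6a_bases = "A",
                                                total_bases = c("A", "G"))) {
  sites <- validate_site_set(sites)
  assert_that(length(rule$m6a_bases) > 0 && length(rule$total_bases) > 0,
              "rule must name m6a_bases and total_bases")
  bam <- ensure_bam(alignments)
  check_site_chroms(sites, bam)
  gr <- site_granges(sites)
  hdr <- Rsamtools::scanBamHeader(bam$path)[[1]]$targets
  ok <- sites$chrom %in% names(hdr)
  m6a <- total <- integer(nrow(sites))
  if (any(ok)) {
    which_gr <- GenomeInfoDb::keepSeqlevels(gr[ok], unique(sites$chrom[ok]),
                                            pruning.mode = "coarse")
    pp <- Rsamtools::PileupParam(
      max_depth = 1e6L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE, include_deletions = FALSE,
      include_insertions = FALSE)
    res <- Rsamtools::pileup(bam,
                             scanBamParam = Rsamtools::ScanBamParam(which = which_gr),
                             pileupParam = pp)
    if (nrow(res)) {
      key <- paste(res$seqnames, res$pos)
      idx <- match(key, paste(sites$chrom, sites$pos))
      keep <- !is.na(idx)
      res <- res[keep, , drop = FALSE]; idx <- idx[keep]
      base <- as.character(res$nucleotide)
      minus <- sites$strand[idx] == "-"
      base[minus] <- chartr("ACGTN", "TGCAN", base[minus])
      in_tot <- base %in% rule$total_bases
      in_m6a <- base %in% rule$m6a_bases
      total <- total + as.integer(
        tabulate_weighted(idx[in_tot], res$count[in_tot], nrow(sites)))
      m6a <- m6a + as.integer(
        tabulate_weighted(idx[in_m6a], res$count[in_m6a], nrow(sites)))
    }
  }
  list(m6a = m6a, total = total)
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  if (length(idx)) {
    agg <- rowsum(as.numeric(w), group = idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((length/1000) * (library_size/1e6))`.
#'
#' @param gene_counts raw read counts per gene.
#' @param gene_lengths_bp feature lengths in bp (> 0).
#' @param library_size total mapped reads (> 0).
#' @return numeric vector of RPKM values.
#' @export
compute_rpkm <- function(gene_counts, gene_lengths_bp, library_size) {
  assert_that(all(gene_lengths_bp > 0), "gene lengths must be > 0")
  assert_that(length(library_size) == 1L && library_size > 0,
              "library size must be a single positive number")
  as.numeric(gene_counts) /
    ((gene_lengths_bp / 1e3) * (library_size / 1e6))
}
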
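#' Reference adenosine site sets
#'
#' A `site_set` is a plain `data.frame` with one row per single-base
#' adenosine locus and columns `chrom`, `pos` (1-based position of the A on
#' the chromosome), `strand` (`"+"`/`"-"`), `motif` (sense-strand 5-mer
#' centred on the A), `site_id` and `provenance`. Sites are unique by
#' `(chrom, pos, strand)` and sorted by that key; this ordered set is the row
#' space of every downstream matrix.
#'
#' @param chrom,pos,strand,motif,site_id,provenance vectors of equal length.
#' @return a validated `site_set` data.frame.
#' @export
site_set <- function(chrom, pos, strand, motif = NA_character_,
                     site_id = NULL, provenance = "unknown") {
  n <- length(chrom)
  if (is.null(site_id)) {
    site_id <- sprintf("%s:%d:%s", chrom, as.integer(pos), strand)
  }
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand),
    motif = rep_len(as.character(motif), n),
    site_id = as.character(site_id),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  validate_site_set(sort_site_set(df))
}

sort_site_set <- function(df) {
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_site_set <- function(df) {
  req <- c("chrom", "pos", "strand", "motif", "site_id", "provenance")
  assert_that(all(req %in% names(df)), "site_set is missing required columns")
  if (nrow(df) == 0) {
    class(df) <- c("site_set", "data.frame")
    return(df)
  }
  assert_that(all(df$pos >= 1L), "site positions must be >= 1")
  assert_that(all(df$strand %in% c("+", "-")),
              "strand must be '+' or '-'")
  key <- paste(df$chrom, df$pos, df$strand)
  assert_that(!anyDuplicated(key),
              "sites must be unique by (chrom, pos, strand)")
  assert_that(!anyDuplicated(df$site_id), "site_id values must be unique")
  with_motif <- !is.na(df$motif)
  if (any(with_motif)) {
    ok <- nchar(df$motif[with_motif]) == 5L &
      substr(df$motif[with_motif], 3L, 3L) == "A"
    assert_that(all(ok), "motifs must be 5-mers with A at the centre")
  }
  class(df) <- unique(c("site_set", class(df)))
  df
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set with %d sites\n", nrow(x)))
  NextMethod()
}

drach_regex <- "[AGT][AG]AC[ACT]"

# Brute-force DRACH scan of one sense-strand sequence; returns 1-based
# offsets of the central A within the sequence. Used both by the synthetic
# genome generator (as recorded truth) and as an internal fallback.
scan_drach_string <- function(seq) {
  n <- nchar(seq)
  if (n < 5L) return(integer(0))
  starts <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(drach_regex, substr(seq, from, n))
    if (m < 0) break
    s <- from + as.integer(m) - 1L
    starts <- c(starts, s)
    from <- s + 1L           # overlapping matches
    if (from > n - 4L) break
  }
  starts + 2L
}

read_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  assert_that(methods::is(genome, "DNAStringSet"),
              "genome must be a FASTA path or DNAStringSet")
  genome
}

# Normalize annotation input to a GRanges of exons carrying transcript_id,
# gene_id and a logical `canonical` column. Accepts a GTF path, a GRanges,
# or a data.frame with chrom/start/end/strand columns.
read_exon_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    gr <- rtracklayer::import(annotation, format = "gtf")
    gr <- gr[gr$type == "exon"]
  } else if (methods::is(annotation, "GRanges")) {
    gr <- annotation
    if ("type" %in% names(S4Vectors::mcols(gr))) gr <- gr[gr$type == "exon"]
  } else if (is.data.frame(annotation)) {
    gr <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(annotation$start, annotation$end),
      strand = annotation$strand
    )
    for (cn in setdiff(names(annotation), c("chrom", "start", "end", "strand")))
      S4Vectors::mcols(gr)[[cn]] <- annotation[[cn]]
  } else {
    stop2("annotation must be a GTF path, GRanges or data.frame")
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) mc$transcript_id <- "tx1"
  if (is.null(mc$gene_id)) mc$gene_id <- mc$transcript_id
  if (is.null(mc$canonical)) {
    # Ensembl-style GTFs mark canonical transcripts with a `tag` attribute.
    if (!is.null(mc$tag)) {
      tag <- mc$tag
      if (methods::is(tag, "List") || is.list(tag)) {
        mc$canonical <- vapply(tag, function(t) any(grepl("canonical", t)),
                               logical(1))
      } else {
        mc$canonical <- grepl("canonical", as.character(tag))
      }
    } else {
      mc$canonical <- NA
    }
  }
  mc$canonical <- as.logical(mc$canonical)
  S4Vectors::mcols(gr) <- mc
  gr
}

# When no transcript is flagged canonical for a gene, fall back to the
# longest transcript (summed exon width) of that gene.
select_canonical <- function(exons) {
  mc <- S4Vectors::mcols(exons)
  if (any(mc$canonical %in% TRUE)) {
    keep_tx <- unique(mc$transcript_id[mc$canonical %in% TRUE])
    return(exons[mc$transcript_id %in% keep_tx])
  }
  w <- tapply(BiocGenerics::width(exons), mc$transcript_id, sum)
  gene_of <- tapply(as.character(mc$gene_id), mc$transcript_id,
                    function(g) g[[1]])
  keep_tx <- vapply(split(names(w), gene_of[names(w)]), function(txs) {
    txs[which.max(w[txs])]
  }, character(1))
  exons[mc$transcript_id %in% keep_tx]
}

#' Scan canonical exons for DRACH adenosines
#'
#' Finds every exonic position whose sense-strand 5-mer matches the DRACH
#' consensus (D=\[AGT\], R=\[AG\], A, C, H=\[ACT\]). Minus-strand exons are
#' scanned on the reverse complement and the site is reported at the genomic
#' coordinate of the central A. The 5-mer window must lie entirely inside the
#' exon, so positions within 2 bp of an exon end are never reported.
#' Duplicate sites from overlapping transcripts collapse to one record.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param annotation GTF path, exon `GRanges`, or data.frame with columns
#'   `chrom,start,end,strand` and optionally `transcript_id,gene_id,canonical`.
#'   When no transcript carries `canonical = TRUE`, the longest transcript of
#'   each gene is used.
#' @return a [site_set] with provenance `"DRACH-exonic"`.
#' @export
scan_drach <- function(genome, annotation) {
  genome <- read_genome(genome)
  exons <- select_canonical(read_exon_annotation(annotation))
  if (length(exons) == 0) return(empty_site_set())

  chrom <- as.character(GenomicRanges::seqnames(exons))
  bad <- !(chrom %in% names(genome))
  assert_that(!any(bad), "exon chromosome absent from genome")
  st <- BiocGenerics::start(exons); en <- BiocGenerics::end(exons)
  too_big <- en > BiocGenerics::width(genome)[match(chrom, names(genome))] |
    st < 1L
  assert_that(!any(too_big), "exon interval outside sequence bounds")

  res <- vector("list", length(exons))
  for (i in seq_along(exons)) {
    seq <- Biostrings::subseq(genome[[chrom[i]]], st[i], en[i])
    strand_i <- as.character(BiocGenerics::strand(exons[i]))
    if (strand_i == "*") strand_i <- "+"
    sense <- if (strand_i == "-") Biostrings::reverseComplement(seq) else seq
    sense_chr <- as.character(sense)
    if (grepl("[^ACGT]", sense_chr)) {
      warning("non-ACGT characters in exon sequence; those windows skipped")
    }
    hits <- Biostrings::matchPattern("DRACH", sense, fixed = FALSE)
    centre_off <- BiocGenerics::start(hits) + 2L   # offset of A in sense seq
    if (length(centre_off) == 0) next
    if (strand_i == "+") {
      gpos <- st[i] + centre_off - 1L
    } else {
      gpos <- en[i] - centre_off + 1L
    }
    res[[i]] <- data.frame(
      chrom = chrom[i], pos = gpos, strand = strand_i,
      motif = as.character(Biostrings::extractAt(
        sense, IRanges::IRanges(centre_off - 2L, centre_off + 2L))),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) return(empty_site_set())
  out <- out[!duplicated(paste(out$chrom, out$pos, out$strand)), , drop = FALSE]
  site_set(out$chrom, out$pos, out$strand, out$motif,
           provenance = "DRACH-exonic")
}

empty_site_set <- function() {
  site_set(character(0), integer(0), character(0), character(0),
           site_id = character(0), provenance = character(0))
}

#' Merge two reference site sets
#'
#' Set union keyed by `(chrom, pos, strand)`. Provenance labels are
#' concatenated (`;`-separated) for sites present in both inputs. On a motif
#' conflict at an identical key, `a`'s motif wins with a warning.
#'
#' @param a,b [site_set] objects.
#' @return the merged, sorted [site_set].
#' @export
merge_site_sets <- function(a, b) {
  a <- validate_site_set(a); b <- validate_site_set(b)
  if (nrow(b) == 0) return(a)
  if (nrow(a) == 0) return(b)
  ka <- paste(a$chrom, a$pos, a$strand)
  kb <- paste(b$chrom, b$pos, b$strand)
  shared <- match(kb, ka)
  dup <- !is.na(shared)
  if (any(dup)) {
    ia <- shared[dup]
    conflict <- !is.na(a$motif[ia]) & !is.na(b$motif[dup]) &
      a$motif[ia] != b$motif[dup]
    if (any(conflict)) {
      warning(sprintf("%d conflicting motifs at shared sites; keeping first set's",
                      sum(conflict)))
    }
    add_prov <- b$provenance[dup]
    differs <- a$provenance[ia] != add_prov
    a$provenance[ia[differs]] <-
      paste(a$provenance[ia[differs]], add_prov[differs], sep = ";")
    # fill motifs missing in a from b
    fill <- is.na(a$motif[ia]) & !is.na(b$motif[dup])
    a$motif[ia[fill]] <- b$motif[dup][fill]
  }
  out <- rbind(as.data.frame(a), as.data.frame(b[!dup, , drop = FALSE]))
  out <- sort_site_set(out)
  out$site_id <- make.unique(out$site_id)
  validate_site_set(out)
}

#' Read / write reference sites as BED6
#'
#' BED6 with 0-based half-open single-base intervals (`start = pos - 1`,
#' `end = pos`), `name = site_id`, `score = 0` and the strand column. The
#' round trip is lossless for `(chrom, pos, strand, site_id)`; the motif is
#' not representable in BED6 and is set to `NA` on read.
#'
#' @param path BED file path.
#' @param sites a [site_set].
#' @param provenance provenance label assigned to sites read from `path`.
#' @return `read_sites_bed` returns a [site_set]; `write_sites_bed` returns
#'   `path` invisibly.
#' @export
read_sites_bed <- function(path, provenance = "external") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  assert_that(ncol(bed) >= 6, "BED6 required: six columns including strand")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  assert_that(all(bed$end - bed$start == 1L),
              "single-base BED intervals required (width 1)")
  assert_that(all(bed$strand %in% c("+", "-")),
              "BED strand column must be '+' or '-'")
  site_set(bed$chrom, bed$start + 1L, bed$strand,
           site_id = bed$name, provenance = provenance)
}

#' @rdname read_sites_bed
#' @export
write_sites_bed <- function(sites, path) {
  sites <- validate_site_set(sites)
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos,
                    sites$site_id, 0L, sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

site_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos, sites$pos),
                         strand = sites$strand,
                         site_id = sites$site_id)
}
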
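#' Synthetic data with planted truth
#'
#' Every generator is deterministic given `(parameters, seed)` and returns
#' (or writes alongside its outputs) a truth record sufficient to regenerate
#' and to score downstream calls: per-site methylation states and theta,
#' shared/independent flags for technique pairs, causal variant maps for the
#' QTL stage.
#'
#' @name synthetic_data
NULL

#' Serialize a simulation truth sidecar
#'
#' @param truth a list of generator parameters and planted truth.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Generate a toy genome and annotation
#'
#' Random chromosomes with genes of 1-5 exons on both strands, one
#' transcript per gene tagged canonical. The truth records every exonic
#' DRACH site, found by a plain-R brute-force scan of each exon's sense
#' sequence (independent of the production scanner).
#'
#' @param n_chrom,chrom_length,n_genes layout parameters.
#' @param seed RNG seed.
#' @param dir if non-NULL, writes `genome.fa`, `annotation.gtf`,
#'   `truth.json` there.
#' @return list: `genome` (DNAStringSet), `exons` (data.frame), `truth`
#'   (incl. `drach_sites`), and file paths when `dir` given.
#' @export
make_toy_genome <- function(n_chrom = 2L, chrom_length = 50000L,
                            n_genes = 20L, seed = 1L, dir = NULL) {
  with_seed_if(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    seqs <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms

    exons <- NULL
    if (n_genes > 0) {
      per_chrom <- rep(n_genes %/% n_chrom, n_chrom)
      per_chrom[seq_len(n_genes %% n_chrom)] <-
        per_chrom[seq_len(n_genes %% n_chrom)] + 1L
      gi <- 0L
      ex_list <- list()
      for (ci in seq_len(n_chrom)) {
        ng <- per_chrom[ci]
        if (ng == 0) next
        slot_w <- chrom_length %/% ng
        for (g in seq_len(ng)) {
          gi <- gi + 1L
          lo <- (g - 1L) * slot_w + 1L
          span <- sort(sample(lo:(lo + slot_w - 1L), 2L))
          if (span[2] - span[1] < 200L) span[2] <- min(span[1] + 200L,
                                                       lo + slot_w - 1L)
          n_ex <- sample.int(5L, 1L)
          bounds <- sort(sample(span[1]:span[2], 2L * n_ex))
          strand <- sample(c("+", "-"), 1L)
          for (e in seq_len(n_ex)) {
            ex_list[[length(ex_list) + 1L]] <- data.frame(
              chrom = chroms[ci],
              start = bounds[2L * e - 1L], end = bounds[2L * e],
              strand = strand,
              gene_id = sprintf("g%03d", gi),
              transcript_id = sprintf("g%03d.t1", gi),
              canonical = TRUE, stringsAsFactors = FALSE)
          }
        }
      }
      exons <- do.call(rbind, ex_list)
    }

    truth_sites <- brute_force_drach(genome, exons)
    truth <- list(
      parameters = list(n_chrom = n_chrom, chrom_length = chrom_length,
                        n_genes = n_genes, seed = seed),
      n_drach_sites = nrow(truth_sites),
      drach_sites = truth_sites
    )
    out <- list(genome = genome, exons = exons, truth = truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      out$fasta <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, out$fasta)
      out$gtf <- file.path(dir, "annotation.gtf")
      write_toy_gtf(exons, out$gtf)
      write_truth(truth, file.path(dir, "truth.json"))
    }
    out
  })
}

# Brute-force oracle: regex-scan the sense sequence of every exon window
# that lies fully inside the exon; reverse-complement minus-strand exons.
brute_force_drach <- function(genome, exons) {
  if (is.null(exons) || nrow(exons) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), motif = character(0)))
  }
  rc <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                                   collapse = ""))
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    ex <- exons[i, ]
    seq <- substr(as.character(genome[[ex$chrom]]), ex$start, ex$end)
    sense <- if (ex$strand == "-") rc(seq) else seq
    centres <- scan_drach_string(sense)
    for (off in centres) {
      gpos <- if (ex$strand == "+") ex$start + off - 1L else ex$end - off + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ex$chrom, pos = gpos, strand = ex$strand,
        motif = substr(sense, off - 2L, off + 2L), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0),
               strand = character(0), motif = character(0))
  out <- out[!duplicated(paste(out$chrom, out$pos, out$strand)), ,
             drop = FALSE]
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

write_toy_gtf <- function(exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  if (is.null(exons) || nrow(exons) == 0) return(invisible(path))
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; tag "canonical";',
      ex$gene_id[1], tx)
    writeLines(sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       ex$chrom[1], min(ex$start), max(ex$end),
                       ex$strand[1], attr_str), con)
    for (i in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                         ex$chrom[i], ex$start[i], ex$end[i],
                         ex$strand[i], attr_str), con)
    }
  }
  invisible(path)
}

#' Simulate a methylome count matrix with planted truth
#'
#' Each site is foreground with probability `pi` (theta ~ `Beta(6, 4)`) or
#' background (theta ~ `Beta(1, 50)`); theta is a per-site property shared
#' by all samples. Depth is negative binomial (`mu = depth_mean`,
#' dispersion `depth_disp`, so `size = 1/depth_disp`) per cell and
#' `k ~ Binomial(n, theta)`.
#'
#' @param sites a [site_set], or an integer number of anonymous sites.
#' @param pi foreground mixing proportion.
#' @param n_samples number of columns.
#' @param depth_mean,depth_disp negative-binomial depth parameters.
#' @param fg_shape,bg_shape Beta shape pairs for foreground/background theta.
#' @param bg_theta if non-NULL, a constant background theta replacing the
#'   `bg_shape` draw — the exact global null (`theta = p0` everywhere) that
#'   calibration checks of the binomial caller assume.
#' @param seed RNG seed.
#' @param samples optional [sample_record] table.
#' @return list: `se` (methylation SummarizedExperiment), `truth`
#'   (`state`, `theta`, parameters).
#' @export
simulate_methylome <- function(sites = 2000L, pi = 0.2, n_samples = 1L,
                               depth_mean = 50, depth_disp = 0.3,
                               fg_shape = c(6, 4), bg_shape = c(1, 50),
                               bg_theta = NULL, seed = 1L, samples = NULL) {
  if (is.numeric(sites) && length(sites) == 1L) {
    sites <- site_set(rep("chr1", sites), seq_len(sites) * 10L, "+",
                      provenance = "simulated")
  }
  ns <- nrow(sites)
  with_seed_if(seed, {
    state <- stats::rbinom(ns, 1L, pi) == 1L
    theta_bg <- if (is.null(bg_theta)) {
      stats::rbeta(ns, bg_shape[1], bg_shape[2])
    } else rep(bg_theta, ns)
    theta <- ifelse(state, stats::rbeta(ns, fg_shape[1], fg_shape[2]),
                    theta_bg)
    n <- matrix(stats::rnbinom(ns * n_samples, mu = depth_mean,
                               size = 1 / depth_disp), ns, n_samples)
    k <- matrix(stats::rbinom(ns * n_samples, as.vector(n),
                              rep(theta, n_samples)), ns, n_samples)
    if (is.null(samples)) {
      samples <- sample_record(sprintf("S%02d", seq_len(n_samples)),
                               technique = "simulated", category = "chemical")
    }
    se <- assemble_matrix(k, n, sites, samples)
    truth <- list(state = state, theta = theta,
                  parameters = list(pi = pi, n_samples = n_samples,
                                    depth_mean = depth_mean,
                                    depth_disp = depth_disp,
                                    fg_shape = fg_shape, bg_shape = bg_shape,
                                    bg_theta = bg_theta, seed = seed))
    list(se = se, truth = truth)
  })
}

#' Greedily thin a site set to a minimum genomic gap
#'
#' Reads simulated for one site also pile up on any other site within a
#' read length — exactly as in real data. For exact round-trip checks,
#' thin the site set so no two retained sites on a chromosome are closer
#' than `min_gap` (use `min_gap >= read_len`).
#'
#' @param sites a [site_set].
#' @param min_gap minimum distance between retained sites.
#' @return the thinned [site_set].
#' @export
thin_sites <- function(sites, min_gap = 60L) {
  sites <- validate_site_set(sites)
  keep <- logical(nrow(sites))
  last_chrom <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(sites))) {
    if (sites$chrom[i] != last_chrom ||
        sites$pos[i] - last_pos >= min_gap) {
      keep[i] <- TRUE
      last_chrom <- sites$chrom[i]
      last_pos <- sites$pos[i]
    }
  }
  validate_site_set(sites[keep, , drop = FALSE])
}

#' Simulate SAM reads realizing given (k, n) cells
#'
#' For `mode = "conversion"` one SAM is written: at each site, `k` reads
#' keep the reference A (methylated evidence) and `n - k` carry the
#' converted base at the site position (G on the sense strand, i.e. C on
#' the reference for minus-strand sites). For `mode = "ip"` two SAMs are
#' written: `k` IP reads and `n - k` input reads of plain reference
#' sequence. Reads are `read_len` long, placed uniformly among the starts
#' that cover the site, CIGAR all-match.
#'
#' @param sites a [site_set] (reference bases at `+` sites must be A, at
#'   `-` sites T, as produced by [scan_drach] / [make_toy_genome]).
#' @param k,n per-site methylated and total read counts.
#' @param genome `DNAStringSet` or FASTA path.
#' @param path output SAM path (conversion), or prefix (`<path>_ip.sam`,
#'   `<path>_input.sam`) for IP mode.
#' @param mode `"conversion"` or `"ip"`.
#' @param read_len read length.
#' @param seed RNG seed.
#' @return path(s) to the SAM file(s), invisibly a list with `truth`.
#' @export
simulate_reads <- function(sites, k, n, genome, path,
                           mode = c("conversion", "ip"), read_len = 50L,
                           seed = 1L) {
  mode <- match.arg(mode)
  genome <- read_genome(genome)
  sites <- validate_site_set(sites)
  assert_that(length(k) == nrow(sites) && length(n) == nrow(sites),
              "k and n must align with sites")
  assert_that(all(k <= n), "k must be <= n")
  with_seed_if(seed, {
    recs_main <- character(0)   # conversion reads / IP reads
    recs_input <- character(0)
    rid <- 0L
    for (i in seq_len(nrow(sites))) {
      if (n[i] == 0) next
      ch <- sites$chrom[i]; pos <- sites$pos[i]
      clen <- BiocGenerics::width(genome)[match(ch, names(genome))]
      len <- min(read_len, clen)
      lo <- max(1L, pos - len + 1L)
      hi <- min(pos, clen - len + 1L)
      starts <- lo + sample.int(hi - lo + 1L, n[i], replace = TRUE) - 1L
      methylated <- c(rep(TRUE, k[i]), rep(FALSE, n[i] - k[i]))
      for (r in seq_len(n[i])) {
        rid <- rid + 1L
        st <- starts[r]
        seq <- substr(as.character(genome[[ch]]), st, st + len - 1L)
        if (mode == "conversion" && !methylated[r]) {
          off <- pos - st + 1L
          conv <- if (sites$strand[i] == "+") "G" else "C"
          substr(seq, off, off) <- conv
        }
        rec <- sprintf("read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       rid, ch, st, len, seq,
                       strrep("I", len))
        if (mode == "ip" && !methylated[r]) {
          recs_input <- c(recs_input, rec)
        } else {
          recs_main <- c(recs_main, rec)
        }
      }
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        BiocGenerics::width(genome)))
    if (mode == "conversion") {
      writeLines(c(header, recs_main), path)
      invisible(list(sam = path, truth = list(k = k, n = n, seed = seed)))
    } else {
      ip_path <- paste0(path, "_ip.sam")
      input_path <- paste0(path, "_input.sam")
      writeLines(c(header, recs_main), ip_path)
      writeLines(c(header, recs_input), input_path)
      invisible(list(ip = ip_path, input = input_path,
                     truth = list(k = k, n = n, seed = seed)))
    }
  })
}

#' Simulate a correlated two-technique count pair
#'
#' A fraction of sites is reproducible: both techniques observe the same
#' underlying theta ~ `Beta(6, 4)`, perturbed per technique by Gaussian
#' noise of `noise_sd` on the logit scale. The rest draw independent
#' background thetas ~ `Beta(1, 50)` per technique. Counts are binomial at
#' negative-binomial depths around `depth1` / `depth2`.
#'
#' @param n_sites number of sites.
#' @param reproducible_fraction fraction with shared signal.
#' @param depth1,depth2 mean aggregated depth per technique.
#' @param noise_sd logit-scale technique noise on shared thetas.
#' @param depth_disp negative-binomial dispersion.
#' @param seed RNG seed.
#' @return list: `m6a1`, `total1`, `m6a2`, `total2`, `truth` (`shared`,
#'   `theta1`, `theta2`, parameters).
#' @export
simulate_technique_pair <- function(n_sites = 5000L,
                                    reproducible_fraction = 0.5,
                                    depth1 = 60, depth2 = 60,
                                    noise_sd = 0.3, depth_disp = 0.3,
                                    seed = 1L) {
  with_seed_if(seed, {
    shared <- stats::runif(n_sites) < reproducible_fraction
    base <- stats::rbeta(n_sites, 6, 4)
    jit <- function(th) stats::plogis(stats::qlogis(.clamp(th, 1e-6, 1 - 1e-6)) +
                                        stats::rnorm(n_sites, 0, noise_sd))
    th1 <- ifelse(shared, jit(base), stats::rbeta(n_sites, 1, 50))
    th2 <- ifelse(shared, jit(base), stats::rbeta(n_sites, 1, 50))
    n1 <- stats::rnbinom(n_sites, mu = depth1, size = 1 / depth_disp)
    n2 <- stats::rnbinom(n_sites, mu = depth2, size = 1 / depth_disp)
    list(m6a1 = stats::rbinom(n_sites, n1, th1), total1 = n1,
         m6a2 = stats::rbinom(n_sites, n2, th2), total2 = n2,
         truth = list(shared = shared, theta1 = th1, theta2 = th2,
                      parameters = list(
                        n_sites = n_sites,
                        reproducible_fraction = reproducible_fraction,
                        depth1 = depth1, depth2 = depth2,
                        noise_sd = noise_sd, depth_disp = depth_disp,
                        seed = seed)))
  })
}

#' Simulate an IVT negative-control sample
#'
#' Coverage matches the supplied expression profile; methylated counts are
#' pure error: `k ~ Binomial(n, error_rate)`.
#'
#' @param total_profile per-site total coverage (the expression match).
#' @param error_rate false-methylation rate.
#' @param seed RNG seed.
#' @return list `m6a`, `total`, `truth`.
#' @export
simulate_ivt <- function(total_profile, error_rate = 0.01, seed = 1L) {
  with_seed_if(seed, {
    k <- stats::rbinom(length(total_profile), total_profile, error_rate)
    list(m6a = k, total = as.integer(total_profile),
         truth = list(error_rate = error_rate, seed = seed))
  })
}

#' Simulate a QTL cohort with planted cis effects
#'
#' Hardy-Weinberg dosages at `n_variants` variants per site window (windows
#' disjoint across sites), two known covariates with real effects, and
#' phenotype `y = covariates + dosage * effect + N(0, 1)` where `effect`
#' (in phenotype-sd units) applies to one causal variant for each of the
#' first `n_causal` sites.
#'
#' @param n_samples,n_sites,n_variants cohort dimensions.
#' @param maf_range minor-allele-frequency range (uniform).
#' @param effect causal effect size in noise-sd units.
#' @param n_causal number of causal sites (0 = global null).
#' @param seed RNG seed.
#' @return list: `pheno` (sites x samples), `dosage` (variants x samples),
#'   `cis` (site -> variant ids), `covariates`, `truth` (causal map).
#' @export
simulate_qtl_cohort <- function(n_samples = 100L, n_sites = 50L,
                                n_variants = 30L,
                                maf_range = c(0.05, 0.5),
                                effect = 0, n_causal = 0L, seed = 1L) {
  with_seed_if(seed, {
    site_ids <- sprintf("site%03d", seq_len(n_sites))
    nv_tot <- n_sites * n_variants
    maf <- stats::runif(nv_tot, maf_range[1], maf_range[2])
    dosage <- matrix(stats::rbinom(nv_tot * n_samples, 2L,
                                   rep(maf, n_samples)),
                     nv_tot, n_samples)
    rownames(dosage) <- sprintf("var%05d", seq_len(nv_tot))
    colnames(dosage) <- sprintf("ind%03d", seq_len(n_samples))
    cis <- split(rownames(dosage),
                 rep(site_ids, each = n_variants))[site_ids]
    covariates <- cbind(age = stats::rnorm(n_samples),
                        batch = stats::rbinom(n_samples, 1L, 0.5))
    rownames(covariates) <- colnames(dosage)
    causal <- rep(NA_character_, n_sites)
    pheno <- matrix(NA_real_, n_sites, n_samples,
                    dimnames = list(site_ids, colnames(dosage)))
    for (i in seq_len(n_sites)) {
      y <- 0.5 * covariates[, "age"] - 0.3 * covariates[, "batch"] +
        stats::rnorm(n_samples)
      if (i <= n_causal && effect != 0) {
        cv <- sample(cis[[i]], 1L)
        causal[i] <- cv
        y <- y + effect * dosage[cv, ]
      }
      pheno[i, ] <- y
    }
    list(pheno = pheno, dosage = dosage, cis = cis,
         covariates = covariates,
         truth = list(causal_variant = stats::setNames(causal, site_ids),
                      effect = effect, n_causal = n_causal,
                      parameters = list(n_samples = n_samples,
                                        n_sites = n_sites,
                                        n_variants = n_variants,
                                        maf_range = maf_range, seed = seed)))
  })
}
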
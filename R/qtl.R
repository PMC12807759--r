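#' m6A quantitative trait locus stage
#'
#' Methylation for QTL mapping is expressed as depth-normalized log-odds
#' M-levels, `M = log[(IP / sum(IP)) / (Input / sum(Input))]`, filtered for
#' missingness (rows then columns), corrected for IP-efficiency trends
#' against a pseudo-reference (MA regression), corrected for GC trends with
#' natural cubic splines, then row z-scored and column quantile-normalized.
#' Cis associations are tested by OLS on genotype dosage with covariates and
#' latent factors, with permutation-based empirical p-values and a
#' beta-distribution tail approximation.
#'
#' @name qtl
NULL

#' Log-odds methylation levels (M-levels)
#'
#' `M = log[(IP_ij / sum_i IP_ij) / (Input_ij / sum_i Input_ij)]` (natural
#' log). A cell is missing when `IP + Input = 0`; when coverage exists but
#' one side is zero, a pseudocount of 0.5 is added to both sides of that
#' cell to keep M finite. Column sums use the raw counts.
#'
#' @param ip_counts,input_counts matrices (sites x samples), columns paired.
#' @return numeric matrix of M-levels with `NA` at missing cells.
#' @export
compute_m_levels <- function(ip_counts, input_counts) {
  ip <- as.matrix(ip_counts); inp <- as.matrix(input_counts)
  assert_that(all(dim(ip) == dim(inp)), "IP and input dimensions differ")
  sip <- colSums(ip); sin_ <- colSums(inp)
  assert_that(all(sip > 0) && all(sin_ > 0),
              "every sample needs positive IP and input column sums")
  covered <- (ip + inp) > 0
  needs_pc <- covered & (ip == 0 | inp == 0)
  ipa <- ip + 0.5 * needs_pc
  ina <- inp + 0.5 * needs_pc
  m <- log(sweep(ipa, 2, sip, "/")) - log(sweep(ina, 2, sin_, "/"))
  m[!covered] <- NA_real_
  dimnames(m) <- dimnames(ip)
  m
}

#' Missingness filtering, rows then columns
#'
#' Sites (rows) with missing fraction strictly greater than `row_max` are
#' removed first; then samples (columns) with missing fraction strictly
#' greater than `col_max`, evaluated on the row-filtered matrix. The order
#' is fixed and matters.
#'
#' @param m matrix with `NA` missing cells.
#' @param row_max,col_max strict missing-fraction thresholds.
#' @return the filtered matrix.
#' @export
filter_missingness <- function(m, row_max = 0.20, col_max = 0.80) {
  rmiss <- rowMeans(is.na(m))
  m <- m[rmiss <= row_max, , drop = FALSE]
  assert_that(nrow(m) > 0, "all rows removed by missingness filter")
  cmiss <- colMeans(is.na(m))
  m[, cmiss <= col_max, drop = FALSE]
}

#' MA normalization against a pseudo-reference
#'
#' The pseudo-reference `r` is the row-wise mean across samples. Per sample
#' `x`: `M' = x - r`, `A' = (x + r) / 2`; an OLS fit of `M'` on `A'`
#' (missing cells excluded) is subtracted from the profile, removing
#' intensity-dependent IP-efficiency bias. A constant `A'` degenerates to
#' subtracting `mean(M')`.
#'
#' @param m M-level matrix (sites x samples), `NA` allowed.
#' @return corrected matrix of the same shape.
#' @export
ma_normalize <- function(m) {
  m <- as.matrix(m)
  assert_that(ncol(m) >= 2, "MA normalization needs >= 2 samples")
  r <- rowMeans(m, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x) & !is.na(r)
    mm <- x[ok] - r[ok]
    aa <- (x[ok] + r[ok]) / 2
    if (length(unique(aa)) < 2L) {
      warning("constant A values; subtracting mean M only")
      out[ok, j] <- x[ok] - mean(mm)
    } else {
      fit <- stats::lm.fit(cbind(1, aa), mm)
      out[ok, j] <- x[ok] - (fit$coefficients[1] + fit$coefficients[2] * aa)
    }
  }
  out
}

#' GC-content spline correction
#'
#' Per sample, M-levels are regressed on a natural cubic spline basis of
#' per-site GC content (`df` degrees of freedom); the fitted curve is
#' subtracted and the sample re-centred to mean zero.
#'
#' @param m M-level matrix (sites x samples).
#' @param gc per-site GC fraction in `[0, 1]`.
#' @param df spline degrees of freedom.
#' @return corrected, per-sample mean-centred matrix.
#' @export
gc_correct <- function(m, gc, df = 4) {
  m <- as.matrix(m)
  assert_that(length(gc) == nrow(m), "gc must be defined on all sites")
  assert_that(all(gc >= 0 & gc <= 1), "gc must lie in [0,1]")
  assert_that(length(unique(gc)) > df,
              "spline df must be below the number of distinct GC values")
  basis <- splines::ns(gc, df = df)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    fit <- stats::lm.fit(cbind(1, basis[ok, , drop = FALSE]), x[ok])
    resid <- fit$residuals
    out[ok, j] <- resid - mean(resid)
  }
  out
}

#' Row z-scoring followed by column quantile normalization
#'
#' Rows are scaled to mean 0, sample standard deviation 1 (missing cells
#' ignored; zero-variance rows dropped with a warning). Columns are then
#' quantile-normalized to the mean of the per-column sorted values, with
#' average-rank tie handling; a column's missing cells stay missing and its
#' non-missing ranks are scaled onto the reference grid.
#'
#' @param m matrix, `NA` allowed.
#' @return normalized matrix (possibly fewer rows).
#' @export
zscore_rows_then_quantile_columns <- function(m) {
  quantile_normalize_columns(zscore_rows(m))
}

#' @rdname zscore_rows_then_quantile_columns
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  nn <- rowSums(!is.na(m))
  assert_that(all(nn >= 2), "each row needs >= 2 non-missing values")
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  keep <- s > 0
  if (!all(keep)) warning(sprintf("%d zero-variance rows dropped", sum(!keep)))
  (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
}

#' @rdname zscore_rows_then_quantile_columns
#' @export
quantile_normalize_columns <- function(m) {
  m <- as.matrix(m)
  nr <- nrow(m)
  sorted <- vapply(seq_len(ncol(m)), function(j) {
    x <- sort(m[!is.na(m[, j]), j])
    if (length(x) == nr) x else
      stats::approx(seq(0, 1, length.out = length(x)), x,
                    xout = seq(0, 1, length.out = nr))$y
  }, numeric(nr))
  ref <- rowMeans(matrix(sorted, nrow = nr))
  out <- m
  if (nr == 1L) {
    out[1, !is.na(m[1, ])] <- ref
    return(out)
  }
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    k <- sum(ok)
    rk <- rank(x[ok], ties.method = "average")
    # map ranks 1..k onto the reference grid 1..nr
    pos <- if (k == nr) rk
           else if (k == 1L) (nr + 1) / 2
           else (rk - 1) / (k - 1) * (nr - 1) + 1
    out[ok, j] <- stats::approx(seq_len(nr), ref, xout = pos)$y
  }
  out
}

#' Estimate the number of latent factors by permutation
#'
#' The matrix (rows residualized on known covariates, missing cells
#' mean-imputed) is decomposed by SVD; the number of factors `k` is the
#' length of the leading run of singular-value variance proportions that
#' exceed the `(1 - alpha)` quantile of their row-permutation null
#' distribution (`B` permutations of each row independently).
#'
#' @param m normalized matrix (sites x samples).
#' @param known_covariates optional samples x q matrix.
#' @param B number of permutation nulls.
#' @param alpha per-component significance level.
#' @param seed RNG seed.
#' @return samples x k matrix of right singular vectors (k may be 0).
#' @export
estimate_latent_factors <- function(m, known_covariates = NULL, B = 20L,
                                    alpha = 0.10, seed = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) {
    rmu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- rmu[idx[, 1]]
  }
  if (!is.null(known_covariates)) {
    C <- cbind(1, as.matrix(known_covariates))
    hat <- C %*% solve(crossprod(C)) %*% t(C)
    m <- m - m %*% hat
  } else {
    m <- m - rowMeans(m)
  }
  props <- function(x) {
    d <- svd(x, nu = 0, nv = 0)$d
    d^2 / sum(d^2)
  }
  obs <- props(m)
  nulls <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      perm <- t(apply(m, 1, sample))
      props(perm)
    }, numeric(length(obs)))
  })
  thresh <- apply(nulls, 1, stats::quantile, probs = 1 - alpha)
  sig <- obs > thresh
  k <- if (!sig[1]) 0L else which.min(c(sig, FALSE)) - 1L
  if (k == 0L) {
    return(matrix(numeric(0), nrow = ncol(m), ncol = 0))
  }
  sv <- svd(m, nu = 0, nv = k)
  factors <- sv$v[, seq_len(k), drop = FALSE]
  rownames(factors) <- colnames(m)
  colnames(factors) <- paste0("LF", seq_len(k))
  factors
}

#' Strand-aware cis window around a host gene
#'
#' Union of the gene body span (exons and introns) and the promoter
#' interval, `[TSS - 2000, TSS + 200]` on the transcription strand
#' (reflected for minus-strand genes), clamped to `[1, chrom_length]`.
#'
#' @param gene_start,gene_end body span (1-based, inclusive).
#' @param strand `"+"` or `"-"`.
#' @param chrom_length optional clamp bound.
#' @param upstream,downstream promoter extent around the TSS.
#' @return c(start, end) of the cis window.
#' @export
define_cis_window <- function(gene_start, gene_end, strand,
                              chrom_length = NULL,
                              upstream = 2000L, downstream = 200L) {
  assert_that(strand %in% c("+", "-"), "strand must be '+' or '-'")
  assert_that(gene_end >= gene_start, "gene_end must be >= gene_start")
  if (strand == "+") {
    tss <- gene_start
    prom <- c(tss - upstream, tss + downstream)
  } else {
    tss <- gene_end
    prom <- c(tss - downstream, tss + upstream)
  }
  win <- c(min(gene_start, prom[1]), max(gene_end, prom[2]))
  win[1] <- max(1L, win[1])
  if (!is.null(chrom_length)) win[2] <- min(win[2], chrom_length)
  as.integer(win)
}

# Beta MLE on permutation best-p values; moments start, optim on log scale.
fit_beta_mle <- function(x) {
  x <- .clamp(x, 1e-12, 1 - 1e-12)
  mx <- mean(x); vx <- stats::var(x)
  if (!is.finite(vx) || vx <= 0) return(c(a = NA_real_, b = NA_real_))
  common <- mx * (1 - mx) / vx - 1
  start <- log(pmax(c(mx * common, (1 - mx) * common), 1e-3))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b)) return(1e12)
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(stats::optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) list(par = start))
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Map cis m6A QTLs with permutation empirical p-values
#'
#' Per site: the phenotype (normalized M-levels) and all cis dosages are
#' residualized on the covariates (known + latent factors, plus an
#' intercept); the best nominal OLS p across cis variants is recorded; the
#' residualized phenotype is permuted `n_perm` times and the per-permutation
#' best p tracked. Direct empirical p =
#' `(1 + #\{perm best <= observed best\}) / (1 + n_perm)`; the
#' beta-approximated empirical p is the fitted `Beta(a, b)` CDF at the
#' observed best p, with `(a, b)` estimated from the permutation best-p
#' values by maximum likelihood (requires >= 2 cis variants, otherwise the
#' direct value is reported alone). Per-site nominal thresholds at the
#' `low`/`high` target levels are the corresponding beta quantiles.
#'
#' @param pheno sites x samples matrix of normalized M-levels.
#' @param geno variants x samples dosage matrix in `{0, 1, 2}` (missing
#'   dosages mean-imputed per variant; monomorphic variants excluded).
#' @param cis named list: `site_id` -> character vector of cis variant ids.
#' @param covariates optional samples x q matrix (known covariates and
#'   latent factors combined).
#' @param n_perm number of phenotype permutations per site.
#' @param seed RNG seed.
#' @param low,high empirical-p stringency tiers reported as logical columns.
#' @return data.frame, one row per site: best `variant_id`, `slope`,
#'   `nominal_p`, `emp_p_direct`, `emp_p_beta`, `beta_a`, `beta_b`,
#'   `nominal_threshold_low`, `nominal_threshold_high`, `n_variants`,
#'   `sig_low`, `sig_high`.
#' @export
map_cis_qtl <- function(pheno, geno, cis, covariates = NULL,
                        n_perm = 1000L, seed = NULL,
                        low = 0.1, high = 0.05) {
  pheno <- as.matrix(pheno); geno <- as.matrix(geno)
  assert_that(ncol(pheno) == ncol(geno),
              "phenotype and genotype sample counts differ")
  ns <- ncol(pheno)
  # mean-impute missing dosages per variant
  if (anyNA(geno)) {
    vmu <- rowMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- vmu[idx[, 1]]
  }
  C <- if (is.null(covariates)) matrix(1, ns, 1) else
    cbind(1, as.matrix(covariates))
  q <- ncol(C) - 1L
  hat <- C %*% solve(crossprod(C)) %*% t(C)
  resid_of <- function(v) v - hat %*% v
  dof <- ns - 2L - q
  assert_that(dof >= 1, "not enough samples for the covariate model")

  gres <- t(geno) - hat %*% t(geno)          # samples x variants
  keep_var <- apply(gres, 2, stats::sd) > 1e-12
  gnorm <- sweep(gres, 2, sqrt(colSums(gres^2)), "/")

  r_to_p <- function(r) {
    r <- .clamp(r, -1 + 1e-15, 1 - 1e-15)
    tt <- abs(r) * sqrt(dof / (1 - r^2))
    2 * stats::pt(tt, dof, lower.tail = FALSE)
  }

  with_seed_if(seed, {
    rows <- lapply(names(cis), function(sid) {
      vids <- intersect(cis[[sid]], rownames(geno))
      vids <- vids[keep_var[vids]]
      nv <- length(vids)
      if (nv == 0L || !(sid %in% rownames(pheno))) {
        warning(sprintf("site %s skipped: no usable cis variants", sid))
        return(NULL)
      }
      y <- resid_of(pheno[sid, ])
      ynorm2 <- sum(y^2)
      if (ynorm2 < 1e-12) return(NULL)
      G <- gnorm[, vids, drop = FALSE]
      r_obs <- drop(crossprod(G, y)) / sqrt(ynorm2)
      p_obs <- r_to_p(r_obs)
      best <- which.min(p_obs)
      g_best <- gres[, vids[best]]
      slope <- sum(g_best * y) / sum(g_best^2)

      perm_idx <- replicate(n_perm, sample.int(ns))
      Yp <- matrix(y[perm_idx], ns, n_perm)
      Rp <- crossprod(G, Yp) / sqrt(ynorm2)
      best_r_perm <- apply(abs(Rp), 2, max)
      best_p_perm <- r_to_p(best_r_perm)
      p_min <- min(p_obs)
      emp_direct <- (1 + sum(best_p_perm <= p_min)) / (1 + n_perm)

      if (nv >= 2L) {
        ab <- fit_beta_mle(best_p_perm)
        emp_beta <- stats::pbeta(p_min, ab["a"], ab["b"])
        thr_low <- stats::qbeta(low, ab["a"], ab["b"])
        thr_high <- stats::qbeta(high, ab["a"], ab["b"])
      } else {
        ab <- c(a = NA_real_, b = NA_real_)
        emp_beta <- NA_real_
        thr_low <- thr_high <- NA_real_
      }
      emp_use <- if (is.finite(emp_beta)) emp_beta else emp_direct
      data.frame(site_id = sid, variant_id = vids[best], slope = slope,
                 nominal_p = p_min, emp_p_direct = emp_direct,
                 emp_p_beta = unname(emp_beta),
                 beta_a = unname(ab["a"]), beta_b = unname(ab["b"]),
                 nominal_threshold_low = unname(thr_low),
                 nominal_threshold_high = unname(thr_high),
                 n_variants = nv,
                 sig_low = emp_use < low, sig_high = emp_use < high,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(out) <- NULL
    out
  })
}

#' Read genotype dosages
#'
#' Either a dosage TSV (`variant_id`, `chrom`, `pos`, then one column per
#' sample) or a VCF, whose `GT` field is converted to ALT-allele dosage.
#'
#' @param path file path (`.vcf`/`.vcf.gz` or TSV).
#' @return list: `dosage` (variants x samples), `variants` data.frame
#'   (`variant_id`, `chrom`, `pos`).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    assert_that(requireNamespace("VariantAnnotation", quietly = TRUE),
                "VariantAnnotation required for VCF input")
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean == "0/0"] <- 0
    dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean == "1/1"] <- 2
    rr <- SummarizedExperiment::rowRanges(vcf)
    variants <- data.frame(
      variant_id = rownames(gt),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = BiocGenerics::start(rr), stringsAsFactors = FALSE)
  } else {
    dt <- as.data.frame(data.table::fread(path))
    meta <- c("variant_id", "chrom", "pos")
    assert_that(all(meta %in% names(dt)),
                "dosage TSV needs variant_id, chrom, pos columns")
    dos <- as.matrix(dt[, setdiff(names(dt), meta), drop = FALSE])
    rownames(dos) <- dt$variant_id
    variants <- dt[, meta]
  }
  list(dosage = dos, variants = variants)
}

#' Assign cis variants to sites
#'
#' @param site_pos data.frame `site_id`, `chrom`, `pos`.
#' @param windows data.frame `site_id`, `chrom`, `start`, `end` (from
#'   [define_cis_window] applied to each site's host gene).
#' @param variants data.frame `variant_id`, `chrom`, `pos`.
#' @return named list `site_id` -> cis variant ids.
#' @export
assign_cis_variants <- function(windows, variants) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    variants$variant_id[variants$chrom == w$chrom &
                          variants$pos >= w$start & variants$pos <= w$end]
  })
  names(out) <- windows$site_id
  out
}
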
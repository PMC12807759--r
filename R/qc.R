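#' Per-sample quality control metrics
#'
#' Pure, deterministic summaries mirroring a per-sample QC report: coverage
#' summaries, the beta-value density (with a bimodality coefficient), the
#' GC-vs-beta correlation, motif association (ANOVA R-squared across DRACH
#' 5-mers), accuracy against a validated truth set (Matthews correlation)
#' and p-value calibration data for QQ plots.
#'
#' @name qc
NULL

#' ANOVA R-squared of beta values across 5-mer motifs
#'
#' `R2 = SS_between / SS_total` grouping beta by motif identity. Requires at
#' least two motif groups with two or more observations each.
#'
#' @param beta numeric vector.
#' @param motifs 5-mer labels aligned with `beta`.
#' @return scalar R-squared in `[0, 1]`.
#' @export
motif_anova_r2 <- function(beta, motifs) {
  ok <- !is.na(beta) & !is.na(motifs)
  beta <- beta[ok]; motifs <- as.character(motifs[ok])
  tab <- table(motifs)
  assert_that(sum(tab >= 2) >= 2,
              "need >= 2 motif groups with >= 2 observations")
  keep <- motifs %in% names(tab)[tab >= 2]
  beta <- beta[keep]; motifs <- motifs[keep]
  gm <- mean(beta)
  mu_g <- tapply(beta, motifs, mean)
  n_g <- tapply(beta, motifs, length)
  ssb <- sum(n_g * (mu_g - gm)^2)
  sst <- sum((beta - gm)^2)
  assert_that(sst > 0, "zero total variance: R2 undefined")
  ssb / sst
}

#' Matthews correlation coefficient
#'
#' Standard MCC of the 2x2 confusion table; returns 0 (flagged by a
#' warning) when any marginal is zero.
#'
#' @param calls,truth aligned logical vectors.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(calls, truth) {
  assert_that(length(calls) == length(truth), "length mismatch")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- as.numeric(sum(calls & truth)); tn <- as.numeric(sum(!calls & !truth))
  fp <- as.numeric(sum(calls & !truth)); fn <- as.numeric(sum(!calls & truth))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warning("a confusion-table marginal is zero; MCC reported as 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Expected-vs-observed quantile pairs for QQ plots
#'
#' `expected = (i - 0.5) / m` uniform quantiles against the sorted observed
#' p-values, both returned on the -log10 scale (raw values included).
#'
#' @param p_values p-values in `[0, 1]`.
#' @return data.frame `expected`, `observed` (raw) and `neglog10_*` columns.
#' @export
qq_data <- function(p_values) {
  assert_that(length(p_values) > 0, "empty p-value vector")
  assert_that(all(p_values >= 0 & p_values <= 1), "p-values must be in [0,1]")
  m <- length(p_values)
  obs <- sort(p_values)
  expd <- (seq_len(m) - 0.5) / m
  data.frame(expected = expd, observed = obs,
             neglog10_expected = -log10(expd),
             neglog10_observed = -log10(pmax(obs, .Machine$double.xmin)))
}

#' Sarle's bimodality coefficient
#'
#' `(skewness^2 + 1) / (kurtosis + 3 (n-1)^2 / ((n-2)(n-3)))`; values above
#' ~0.555 (the uniform's coefficient) suggest bimodality of the beta-value
#' density.
#'
#' @param x numeric vector (n > 3).
#' @return scalar coefficient.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  assert_that(n > 3, "need more than 3 observations")
  m <- mean(x); s <- stats::sd(x)
  assert_that(s > 0, "zero variance")
  z <- (x - m) / s
  g1 <- mean(z^3) * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (mean(z^4) - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Assemble a per-sample QC report
#'
#' @param m6a,total count vectors for the sample.
#' @param motifs optional per-site 5-mers (enables the motif ANOVA panel).
#' @param gc optional per-site GC content (enables the GC panel).
#' @param truth optional logical validated-site truth (enables MCC).
#' @param calls optional logical calls to score against `truth`; defaults
#'   to the binomial calls computed here.
#' @param sample_id label.
#' @param n_bins histogram bins for the beta density.
#' @return a `qc_report` list; serialize with [write_qc_report].
#' @export
qc_report <- function(m6a, total, motifs = NULL, gc = NULL, truth = NULL,
                      calls = NULL, sample_id = "sample", n_bins = 20L) {
  covered <- total > 0
  beta <- ifelse(covered, m6a / pmax(total, 1L), NA_real_)
  called <- call_sites_vector(m6a, total)
  if (is.null(calls)) calls <- called$call
  h <- graphics::hist(beta[covered], breaks = seq(0, 1, length.out = n_bins + 1),
                      plot = FALSE)
  rep <- list(
    sample_id = sample_id,
    n_sites = length(m6a),
    sites_covered = sum(covered),
    median_total_coverage = stats::median(total[covered]),
    background_rate = called$p0,
    beta_histogram = list(breaks = h$breaks, density = h$density),
    bimodality = if (sum(covered) > 3 &&
                     stats::sd(beta[covered]) > 0)
      bimodality_coefficient(beta[covered]) else NA_real_,
    gc_beta_pearson = if (!is.null(gc))
      stats::cor(gc[covered], beta[covered], use = "complete.obs")
      else NA_real_,
    motif_r2 = if (!is.null(motifs) &&
                   length(unique(motifs[covered & !is.na(motifs)])) >= 2)
      motif_anova_r2(beta[covered], motifs[covered]) else NA_real_,
    mcc_vs_truth = if (!is.null(truth)) mcc(calls, truth) else NA_real_,
    qq = qq_data(called$p_value[covered])
  )
  class(rep) <- "qc_report"
  rep
}

#' @rdname qc_report
#' @param report a `qc_report`.
#' @param path output JSON path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "columns")
  invisible(path)
}

#' Generic feature-table association hook
#'
#' Fits a user-supplied feature table against either a binary site label
#' (logistic regression) or a methylation level (linear regression) and
#' returns the fit summary. The feature annotation itself is the caller's
#' responsibility.
#'
#' @param response logical (classification) or numeric (level) vector.
#' @param features data.frame of per-site features.
#' @return `summary.glm` / `summary.lm` object.
#' @export
feature_association <- function(response, features) {
  assert_that(nrow(features) == length(response),
              "feature rows must align with the response")
  df <- data.frame(.y = response, features)
  if (is.logical(response)) {
    summary(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  } else {
    summary(stats::lm(.y ~ ., data = df))
  }
}
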
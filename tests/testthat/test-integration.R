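test_that("orthogonality follows the category rules", {
  expect_true(is_orthogonal("chemical", "enzyme"))
  expect_true(is_orthogonal("antibody", "chemical"))   # MeRIP x GLORI
  expect_true(is_orthogonal("direct", "enzyme"))
  expect_true(is_orthogonal("direct", "chemical"))
  expect_false(is_orthogonal("direct", "antibody"))    # ONT-DRS x m6ACE-seq
  expect_false(is_orthogonal("antibody", "direct"))    # either order
  expect_false(is_orthogonal("antibody", "antibody"))  # same category
  expect_error(is_orthogonal("antibody", "nanopore"), "unknown")
})

test_that("aggregate_counts sums selected columns like a naive loop", {
  sites <- site_set("chr1", c(10L, 20L, 30L), "+")
  samples <- sample_record(
    c("b1", "b2", "t1", "ivt1"), category = "chemical",
    condition = c("baseline", "baseline", "treated", "baseline"),
    is_ivt = c(FALSE, FALSE, FALSE, TRUE))
  m6a <- matrix(c(3L, 1L, 0L,  5L, 2L, 1L,  9L, 9L, 9L,  1L, 1L, 1L), 3, 4)
  tot <- matrix(c(10L, 4L, 2L, 20L, 5L, 3L, 30L, 9L, 9L, 2L, 2L, 2L), 3, 4)
  se <- assemble_matrix(m6a, tot, sites, samples)
  agg <- aggregate_counts(se)                    # baseline, IVT excluded
  expect_equal(agg$samples, c("b1", "b2"))
  expect_equal(agg$m6a, setNames(c(8, 3, 1), sites$site_id))
  expect_equal(agg$total, setNames(c(30, 9, 5), sites$site_id))
  one <- aggregate_counts(se, filter = "treated")    # single sample identity
  expect_equal(unname(one$m6a), c(9, 9, 9))
  expect_error(aggregate_counts(se, filter = "nonexistent"), "empty")
  # random matrix vs naive double loop
  sim <- simulate_methylome(sites = 100L, n_samples = 4L, seed = 80)
  agg2 <- aggregate_counts(sim$se)
  m <- SummarizedExperiment::assay(sim$se, "m6a_count")
  naive <- numeric(100)
  for (i in 1:100) for (j in 1:4) naive[i] <- naive[i] + m[i, j]
  expect_equal(unname(agg2$m6a), naive)
})

test_that("compute_beta follows the ratio definition and jitter contract", {
  b <- compute_beta(3, 4, jitter_factor = 0)
  expect_equal(b$beta, 0.75)                       # m6A=3, unmethylated A=1
  expect_true(is.na(compute_beta(0, 0, jitter_factor = 0)$beta))
  expect_error(compute_beta(-1, 3), "negative")
  expect_error(compute_beta(5, 3), "<=")
  # 100 tied values become distinct but stay within 1e-4 relative distance
  m6a <- rep(30L, 100); tot <- rep(60L, 100)
  bj <- compute_beta(m6a, tot, seed = 81)
  expect_equal(length(unique(bj$beta)), 100L)
  expect_true(all(abs(bj$beta - 0.5) / 0.5 <= 1e-4))
  # deterministic given the seed
  bj2 <- compute_beta(m6a, tot, seed = 81)
  expect_identical(bj$beta, bj2$beta)
  # ties at zero also resolve
  b0 <- compute_beta(rep(0L, 50), rep(30L, 50), seed = 82)
  expect_equal(length(unique(b0$beta)), 50L)
  expect_true(all(b0$beta >= 0 & b0$beta <= 1e-4))
})

test_that("pairwise coverage filter is a strict >= on both margins", {
  expect_equal(pairwise_coverage_filter(c(19, 20, 25), c(25, 20, 19)), 2L)
  t1 <- withr::with_seed(83, rpois(200, 25))
  t2 <- withr::with_seed(84, rpois(200, 25))
  oracle <- which(vapply(seq_len(200),
                         function(i) t1[i] >= 20 && t2[i] >= 20, logical(1)))
  expect_equal(pairwise_coverage_filter(t1, t2), oracle)
})

test_that("fit_idr is rank-invariant, bounded, and monotone in its outputs", {
  sim <- simulate_technique_pair(n_sites = 800, reproducible_fraction = 0.5,
                                 seed = 85)
  x <- compute_beta(sim$m6a1, pmax(sim$total1, 1), seed = 86)$beta
  y <- compute_beta(sim$m6a2, pmax(sim$total2, 1), seed = 87)$beta
  fit <- suppressWarnings(fit_idr(x, y))
  expect_true(all(fit$idr_local >= 0 & fit$idr_local <= 1))
  o <- order(fit$idr_local)
  expect_true(all(diff(fit$idr_global[o]) >= -1e-12))
  expect_true(fit$p > 0 && fit$p < 1)
  expect_true(fit$rho > 0 && fit$rho < 1)
  expect_gt(fit$sigma, 0)
  # strictly monotone transform of a margin changes nothing
  fit2 <- suppressWarnings(fit_idr(exp(x), y))
  expect_equal(fit$idr_local, fit2$idr_local)
  expect_equal(fit$p, fit2$p)
  # permuting the joint order permutes the idr values identically
  perm <- withr::with_seed(88, sample.int(length(x)))
  fit3 <- suppressWarnings(fit_idr(x[perm], y[perm]))
  expect_equal(fit3$idr_local, fit$idr_local[perm])
  expect_error(fit_idr(x[1:50], y[1:50]), ">= 100")
})

test_that("each EM step improves the fixed-pseudo-value likelihood", {
  sim <- simulate_technique_pair(n_sites = 600, reproducible_fraction = 0.6,
                                 seed = 89)
  x <- compute_beta(sim$m6a1, pmax(sim$total1, 1), seed = 90)$beta
  y <- compute_beta(sim$m6a2, pmax(sim$total2, 1), seed = 91)$beta
  fit <- suppressWarnings(fit_idr(x, y))
  # em_gain is the likelihood change of each M-step at fixed pseudo-values:
  # non-negative by EM theory (pseudo-value refreshes may still move the
  # overall trace either way)
  expect_true(all(fit$em_gain >= -1e-6))
})

test_that("validate_sites is the three-criterion conjunction", {
  fit <- structure(list(idr_local = c(0.01, 0.01, 0.8),
                        idr_global = c(0.01, 0.01, 0.5),
                        n = 3L), class = "idr_fit")
  res <- validate_sites(fit, c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  expect_equal(res$validated, c(TRUE, FALSE, FALSE))
  expect_error(validate_sites(fit, TRUE, c(TRUE, TRUE, TRUE)), "align")
})

test_that("validate_pair recovers planted concordant sites end to end", {
  px <- make_planted_pair(n = 1000L, n_planted = 100L, seed = 92)
  v <- suppressWarnings(validate_pair(px$se1, px$se2, seed = 93))
  val_ids <- v$result$site_id[v$result$validated]
  recall <- mean(px$planted %in% val_ids)
  fp <- if (length(val_ids)) mean(!(val_ids %in% px$planted)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fp, 0.1)
  # non-orthogonal pairs are refused
  se_ab <- px$se1
  SummarizedExperiment::colData(se_ab)$category <- "antibody"
  se_dr <- px$se2
  SummarizedExperiment::colData(se_dr)$category <- "direct"
  expect_error(validate_pair(se_ab, se_dr, seed = 94), "not technically")
})

test_that("differential IDR flags degenerate zero-difference input", {
  n <- 300L
  tot <- rep(50L, n); m <- rep(10L, n)
  w <- capture_warnings(
    d <- differential_idr(m, tot, m, tot, m, tot, m, tot, seed = 95))
  expect_true(any(grepl("degenerate", w)))
  expect_true(d$degenerate)
  expect_true(all(d$delta1 == 0))
})

test_that("differential IDR recovers planted concordant beta drops", {
  withr::with_seed(96, {
    n <- 1000L
    planted <- 1:100
    tot <- function() rnbinom(n, mu = 60, size = 5) + 20L
    t_t1 <- tot(); t_c1 <- tot(); t_t2 <- tot(); t_c2 <- tot()
    th_c <- rbeta(n, 2, 8)                     # control methylation
    th_t <- th_c + rnorm(n, 0, 0.01)           # treated ~ control (null)
    th_c[planted] <- rbeta(100, 6, 2)          # high control level
    th_t[planted] <- pmax(th_c[planted] - 0.5, 0.01)   # drop of ~0.5
    th_t <- pmin(pmax(th_t, 0), 1)
    m_t1 <- rbinom(n, t_t1, th_t); m_c1 <- rbinom(n, t_c1, th_c)
    m_t2 <- rbinom(n, t_t2, th_t); m_c2 <- rbinom(n, t_c2, th_c)
    d <- suppressWarnings(differential_idr(m_t1, t_t1, m_c1, t_c1,
                                           m_t2, t_t2, m_c2, t_c2,
                                           seed = 97))
    hit <- d$index %in% planted
    expect_gte(mean(d$validated[hit]), 0.9)
    # validated DM sites show larger |delta beta| than non-validated
    mean_abs <- function(sel) mean(abs(d$delta1[sel]) + abs(d$delta2[sel])) / 2
    expect_gt(mean_abs(d$validated), mean_abs(!d$validated))
  })
})
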
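#' Irreproducible discovery rate via a Gaussian copula mixture
#'
#' Paired scores from two techniques are reduced to ranks, mapped to
#' pseudo-values through the inverse of the fitted marginal mixture CDF, and
#' modelled as a two-component bivariate normal mixture: a reproducible
#' component `N((mu, mu), sigma^2, rho)` and an independent standard-normal
#' noise component. The local idr of a site is its posterior probability of
#' belonging to the noise component; the global IDR of a site is the mean
#' local idr over all sites ranked at or above it, the quantity thresholded
#' (IDR < 0.05) in ENCODE-style analyses.
#'
#' @name idr
NULL

# log bivariate normal density with common mean/sd and correlation rho
ldbvn <- function(z1, z2, mu, sigma, rho) {
  a <- (z1 - mu) / sigma
  b <- (z2 - mu) / sigma
  -log(2 * pi) - 2 * log(sigma) - 0.5 * log1p(-rho^2) -
    (a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))
}

# marginal mixture CDF G(z) = p*Phi((z-mu)/sigma) + (1-p)*Phi(z)
marginal_cdf <- function(z, p, mu, sigma) {
  p * stats::pnorm((z - mu) / sigma) + (1 - p) * stats::pnorm(z)
}

# vectorized numerical inverse of the marginal mixture CDF on a monotone grid
marginal_quantile <- function(u, p, mu, sigma) {
  lo <- min(-9, mu - 9 * sigma)
  hi <- max(9, mu + 9 * sigma)
  grid <- seq(lo, hi, length.out = 4096L)
  cdf <- marginal_cdf(grid, p, mu, sigma)
  # strictly increasing in exact arithmetic; enforce for approx()
  cdf <- cummax(cdf + seq_along(cdf) * 1e-15)
  stats::approx(cdf, grid, xout = u, rule = 2)$y
}

#' Fit the copula mixture IDR model
#'
#' Margins are rank-transformed as `u = rank/(n+1)` (keeping pseudo-values
#' finite), pseudo-values `z = G^{-1}(u)` are refreshed from the current
#' marginal mixture each outer iteration, and an EM pass updates
#' `(p, mu, sigma, rho)` in between, until the pseudo-likelihood change
#' drops below `tol`. Parameters are clamped to
#' `rho in [1e-4, 0.999]`, `sigma >= 1e-3`, `p in [1e-4, 1 - 1e-4]`.
#'
#' @param x,y paired score vectors (>= 100 sites, ties broken upstream).
#' @param init named list of starting values `mu, sigma, rho, p`.
#' @param tol convergence tolerance on the pseudo log-likelihood change
#'   between successive refresh+EM iterations.
#' @param max_iter cap on total iterations (one EM step per pseudo-value
#'   refresh). Diffuse data (e.g. pure noise) may exhaust it; the fit is
#'   then flagged `converged = FALSE` but remains usable.
#' @return an `idr_fit` with `p, mu, sigma, rho`, per-site `idr_local` and
#'   `idr_global`, `loglik`, `trace` (pseudo-log-likelihood per iteration),
#'   `em_gain` (fixed-pseudo-value likelihood change of each M-step,
#'   non-negative by EM theory), `converged`, `n_iter`.
#' @export
fit_idr <- function(x, y,
                    init = list(mu = 0.1, sigma = 1, rho = 0.2, p = 0.5),
                    tol = 1e-6, max_iter = 2000L) {
  assert_that(length(x) == length(y), "x and y lengths differ")
  n <- length(x)
  assert_that(n >= 100, "need >= 100 paired sites to fit the IDR model")
  assert_that(!anyNA(x) && !anyNA(y), "missing values not allowed; filter first")
  if (anyDuplicated(x) || anyDuplicated(y)) {
    warning("tied scores detected; ranks use average ties (apply jitter upstream)")
  }
  u <- rank(x, ties.method = "average") / (n + 1)
  v <- rank(y, ties.method = "average") / (n + 1)

  mu <- init$mu %||% 0.1
  sigma <- init$sigma %||% 1
  rho <- init$rho %||% 0.2
  p <- init$p %||% 0.5

  trace <- numeric(0)
  em_gain <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  e1 <- NULL
  posterior <- function(z1, z2) {
    l1 <- ldbvn(z1, z2, mu, sigma, rho) + log(p)
    l0 <- ldbvn(z1, z2, 0, 1, 0) + log1p(-p)   # independent standard normal
    mx <- pmax(l1, l0)
    den <- exp(l1 - mx) + exp(l0 - mx)
    list(e1 = exp(l1 - mx) / den, ll = sum(mx + log(den)))
  }
  # one EM step per pseudo-value refresh, the reference scheme; at fixed
  # pseudo-values each M-step cannot decrease the likelihood (em_gain >= 0)
  while (it < max_iter) {
    it <- it + 1L
    z1 <- marginal_quantile(u, p, mu, sigma)
    z2 <- marginal_quantile(v, p, mu, sigma)
    es <- posterior(z1, z2)
    e1 <- es$e1
    trace <- c(trace, es$ll)
    if (is.finite(ll_old) && abs(es$ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$ll
    sw <- sum(e1)
    p <- .clamp(sw / n, 1e-4, 1 - 1e-4)
    if (sw > 1e-10) {
      mu <- sum(e1 * (z1 + z2)) / (2 * sw)
      s2 <- sum(e1 * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sw)
      sigma <- sqrt(max(s2, 1e-6))
      rho <- sum(e1 * (z1 - mu) * (z2 - mu)) / (sw * sigma^2)
    }
    sigma <- max(sigma, 1e-3)
    rho <- .clamp(rho, 1e-4, 0.999)
    em_gain <- c(em_gain, posterior(z1, z2)$ll - es$ll)
  }
  if (!converged) warning("IDR EM did not converge within max_iter")

  idr_local <- 1 - e1
  o <- order(idr_local)
  idr_global <- numeric(n)
  idr_global[o] <- cumsum(idr_local[o]) / seq_len(n)
  structure(list(p = p, mu = mu, sigma = sigma, rho = rho,
                 idr_local = idr_local, idr_global = idr_global,
                 loglik = utils::tail(trace, 1), trace = trace,
                 em_gain = em_gain,
                 converged = converged, n_iter = it, n = n),
            class = "idr_fit")
}

#' @export
print.idr_fit <- function(x, ...) {
  cat(sprintf(
    "IDR fit (n=%d): p=%.3f mu=%.3f sigma=%.3f rho=%.3f; %d sites at IDR<0.05\n",
    x$n, x$p, x$mu, x$sigma, x$rho, sum(x$idr_global < 0.05)))
  invisible(x)
}
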
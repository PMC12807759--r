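#' Two-component beta-binomial mixture (BBmix) site classifier
#'
#' Models the per-site counts `k ~ BetaBin(n, mu, phi)` as a mixture of a
#' low-methylation background and a high-methylation foreground, in the
#' (mean, concentration) parameterization `a = mu * phi`,
#' `b = (1 - mu) * phi`. Fitted by EM; the M-step maximizes each component's
#' weighted log-likelihood numerically from the current parameters
#' (generalized EM), so the observed-data log-likelihood never decreases.
#' The posterior probability of foreground membership classifies sites at a
#' 0.5 threshold.
#'
#' @name bbmix
NULL

# log BetaBin(k; n, a, b) density, vectorized
ldbetabinom <- function(k, n, a, b) {
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

.mu_phi_to_ab <- function(mu, phi) c(a = mu * phi, b = (1 - mu) * phi)

# component log-density at (mu, phi)
comp_logdens <- function(k, n, mu, phi) {
  ldbetabinom(k, n, unname(mu) * unname(phi), (1 - unname(mu)) * unname(phi))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# weighted ML update of one component on the logit(mu)/log(phi) scale,
# started at the current parameters so the Q-function cannot decrease
mstep_component <- function(k, n, w, mu, phi, maxit = 25L) {
  if (sum(w) < 1e-8) return(c(mu = mu, phi = phi))
  nll <- function(par) {
    m <- stats::plogis(par[1]); f <- exp(par[2])
    if (!is.finite(f) || f > 1e8) return(1e12)
    -sum(w * comp_logdens(k, n, .clamp(m, 1e-8, 1 - 1e-8), f))
  }
  start <- c(stats::qlogis(.clamp(mu, 1e-6, 1 - 1e-6)), log(phi))
  fit <- tryCatch(
    stats::optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = maxit)),
    error = function(e) list(par = start, value = nll(start)))
  if (!is.finite(fit$value) || fit$value > nll(start)) fit$par <- start
  c(mu = .clamp(stats::plogis(fit$par[1]), 1e-8, 1 - 1e-8),
    phi = .clamp(exp(fit$par[2]), 1e-4, 1e8))
}

bbmix_loglik <- function(k, n, pi, mu_bg, phi_bg, mu_fg, phi_fg) {
  lf <- comp_logdens(k, n, mu_fg, phi_fg) + log(pi)
  lb <- comp_logdens(k, n, mu_bg, phi_bg) + log1p(-pi)
  mx <- pmax(lf, lb)
  sum(mx + log(exp(lf - mx) + exp(lb - mx)))
}

bbmix_em_once <- function(k, n, init, tol, max_iter) {
  pi <- init$pi; mu_bg <- init$mu_bg; mu_fg <- init$mu_fg
  phi_bg <- init$phi_bg; phi_fg <- init$phi_fg
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lf <- comp_logdens(k, n, mu_fg, phi_fg) + log(pi)
    lb <- comp_logdens(k, n, mu_bg, phi_bg) + log1p(-pi)
    mx <- pmax(lf, lb)
    den <- exp(lf - mx) + exp(lb - mx)
    r_fg <- exp(lf - mx) / den
    ll <- sum(mx + log(den))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi <- .clamp(mean(r_fg), 1e-6, 1 - 1e-6)
    up_fg <- mstep_component(k, n, r_fg, mu_fg, phi_fg)
    up_bg <- mstep_component(k, n, 1 - r_fg, mu_bg, phi_bg)
    mu_fg <- up_fg[["mu"]]; phi_fg <- up_fg[["phi"]]
    mu_bg <- up_bg[["mu"]]; phi_bg <- up_bg[["phi"]]
  }
  list(pi = pi, mu_bg = mu_bg, phi_bg = phi_bg, mu_fg = mu_fg,
       phi_fg = phi_fg, loglik = utils::tail(trace, 1), trace = trace,
       converged = converged, n_iter = it)
}

#' Fit the BBmix model
#'
#' @param k,n m6A counts and total coverages; at least 50 sites with `n > 0`.
#' @param init optional named list `pi, mu_bg, mu_fg, phi_bg, phi_fg`; by
#'   default the component means start at the 10th/90th percentile of `k/n`
#'   with concentration 10 and `pi = 0.5`.
#' @param tol EM convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per restart.
#' @param restarts number of randomly perturbed restarts (best kept).
#' @param seed RNG seed keying the restarts.
#' @return an object of class `bbmix_fit` with elements `pi`, `mu_bg`,
#'   `mu_fg`, `phi_bg`, `phi_fg`, `loglik`, `trace`, `converged`, `n_iter`,
#'   `degenerate`.
#' @export
fit_bbmix <- function(k, n, init = NULL, tol = 1e-6, max_iter = 1000L,
                      restarts = 5L, seed = NULL) {
  assert_that(length(k) == length(n), "k and n lengths differ")
  assert_that(all(k <= n), "k must be <= n")
  use <- n > 0
  assert_that(sum(use) >= 50, "need >= 50 sites with n > 0")
  k <- k[use]; n <- n[use]
  degenerate <- all(k == 0)

  rates <- k / n
  q <- stats::quantile(rates, c(0.1, 0.9), names = FALSE)
  base <- list(pi = 0.5,
               mu_bg = .clamp(q[1], 1e-3, 1 - 1e-3),
               mu_fg = .clamp(max(q[2], q[1] + 0.01), 2e-3, 1 - 1e-3),
               phi_bg = 10, phi_fg = 10)
  if (!is.null(init)) base[names(init)] <- init

  fits <- with_seed_if(seed, {
    lapply(seq_len(max(1L, restarts)), function(r) {
      ini <- base
      if (r > 1L) {
        ini$pi <- stats::runif(1, 0.05, 0.6)
        ini$mu_bg <- .clamp(base$mu_bg * exp(stats::rnorm(1, 0, 0.5)),
                            1e-4, 0.5)
        ini$mu_fg <- .clamp(base$mu_fg + stats::runif(1, -0.15, 0.15),
                            ini$mu_bg + 0.01, 1 - 1e-3)
        ini$phi_bg <- exp(stats::rnorm(1, log(10), 0.5))
        ini$phi_fg <- exp(stats::rnorm(1, log(10), 0.5))
      }
      bbmix_em_once(k, n, ini, tol, max_iter)
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  # relabel so the foreground is the high-mean component
  if (best$mu_fg < best$mu_bg) {
    best[c("mu_bg", "mu_fg")] <- best[c("mu_fg", "mu_bg")]
    best[c("phi_bg", "phi_fg")] <- best[c("phi_fg", "phi_bg")]
    best$pi <- 1 - best$pi
  }
  if (!best$converged) warning("BBmix EM did not converge; fit flagged")
  if (degenerate) {
    best$pi <- 1e-6   # no foreground evidence at all: prior to the boundary
    warning("all k = 0: degenerate fit, pi forced to boundary")
  }
  structure(c(best, list(degenerate = degenerate)), class = "bbmix_fit")
}

#' @export
print.bbmix_fit <- function(x, ...) {
  cat(sprintf(
    "BBmix fit: pi=%.3f mu_bg=%.4f (phi=%.2f) mu_fg=%.4f (phi=%.2f)\n",
    x$pi, x$mu_bg, x$phi_bg, x$mu_fg, x$phi_fg))
  cat(sprintf("loglik=%.3f, %d iterations, converged=%s\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Posterior probability of foreground membership
#'
#' `posterior = pi * BB_fg(k; n) / (pi * BB_fg + (1 - pi) * BB_bg)`.
#' Sites with `n = 0` carry no information and return the prior `pi`.
#'
#' @param fit a `bbmix_fit`.
#' @param k,n counts.
#' @return posterior foreground probabilities in `[0, 1]`.
#' @export
bbmix_posterior <- function(fit, k, n) {
  assert_that(inherits(fit, "bbmix_fit"), "fit must be a bbmix_fit")
  assert_that(all(k <= n), "k must be <= n")
  lf <- comp_logdens(k, n, fit$mu_fg, fit$phi_fg) + log(fit$pi)
  lb <- comp_logdens(k, n, fit$mu_bg, fit$phi_bg) + log1p(-fit$pi)
  mx <- pmax(lf, lb)
  post <- exp(lf - mx) / (exp(lf - mx) + exp(lb - mx))
  post[n == 0] <- fit$pi
  post
}

#' @rdname bbmix_posterior
#' @param threshold classification threshold on the posterior.
#' @export
bbmix_classify <- function(fit, k, n, threshold = 0.5) {
  bbmix_posterior(fit, k, n) > threshold
}
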
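#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimizer following the standard
#' (mu/mu_w, lambda) strategy with cumulative step-size adaptation and
#' rank-one plus rank-mu covariance updates.  Box constraints are handled
#' by projecting sampled candidates onto the bounds before evaluation (the
#' projected candidate is what is evaluated and reported).  Suitable for
#' noisy objectives such as simulation-based costs.
#'
#' Randomness is drawn from R's generator: seed with `set.seed()` for
#' reproducible runs.
#'
#' @param fn objective function of a numeric vector, returning a scalar.
#' @param x0 initial mean.
#' @param sigma0 initial global step size.
#' @param lower,upper bounds (recycled to `length(x0)`).
#' @param budget maximum number of function evaluations.
#' @param lambda population size per generation (default
#'   `4 + floor(3 log n)`).
#' @return List with `par` (best candidate found), `value`, `n_evals`,
#'   `trace` (best-so-far value after each generation, non-increasing) and
#'   `converged` (`TRUE` when the incumbent stopped improving before the
#'   final third of the generations, i.e. the search stabilized within the
#'   budget).
#' @references Hansen, N. The CMA evolution strategy: a tutorial.
#' @export
cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   budget = 1000L, lambda = NULL) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  weights <- log(mu + 0.5) - log(seq_len(mu))
  weights <- weights / sum(weights)
  mueff <- 1 / sum(weights^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); Ddiag <- rep(1, n)
  C <- diag(n); invsqrtC <- diag(n)
  eigen_stale <- 0

  best_x <- xmean; best_f <- Inf
  n_evals <- 0L
  trace <- numeric(0)
  last_improvement <- 0L
  gen <- 0L

  while (n_evals < budget) {
    gen <- gen + 1L
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (Ddiag * arz)
    arx <- xmean + sigma * ary
    arx <- pmin(pmax(arx, lower), upper)       # project onto the box
    fit <- apply(arx, 2, fn)
    n_evals <- n_evals + lambda
    ord <- order(fit)
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]; best_x <- arx[, ord[1]]
      last_improvement <- gen
    }
    trace <- c(trace, best_f)

    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- drop(arx[, sel, drop = FALSE] %*% weights)
    ydiff <- (xmean - xold) / sigma

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% ydiff)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * n_evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ydiff

    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (weights * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eigen_stale <- eigen_stale + lambda
    if (eigen_stale > lambda / (c1 + cmu) / n / 10) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      Ddiag <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
      invsqrtC <- B %*% (t(B) / Ddiag)
    }
    if (!is.finite(sigma) || sigma > 1e6 * sigma0) sigma <- sigma0
  }

  list(par = best_x, value = best_f, n_evals = n_evals, trace = trace,
       converged = last_improvement <= floor(2 * gen / 3))
}
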
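## Minimal (mu/mu_w, lambda) covariance-matrix-adaptation evolution
## strategy, following the standard tutorial formulation.  Sufficient for
## the low-dimensional, noisy objectives arising in population fitting;
## no restarts, no box handling (the hyperparameter space is unbounded).

#' CMA-ES minimizer
#'
#' @param fn objective to minimize (takes a numeric vector).
#' @param x0 start point.
#' @param sigma0 initial step size.
#' @param lambda population size (default `4 + floor(3 log n)`).
#' @param max_evals evaluation budget.
#' @param on_generation optional callback `function(gen, xbest, fbest,
#'   fvals)` run after each generation (used for noise handling).
#' @return A list with `par` (distribution mean at termination),
#'   `par_avg` (mean averaged over the last 40 percent of generations, a
#'   noise-robust estimate for stochastic objectives), `best_par`,
#'   `best_value`, `evals`, and a `trace` tibble (generation, best value,
#'   step size).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.5, lambda = NULL, max_evals = 1000L,
                   on_generation = NULL) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- x0
  sigma <- sigma0
  C <- diag(n)
  ps <- pc <- numeric(n)
  B <- diag(n); D <- rep(1, n)
  evals <- 0L
  gen <- 0L
  best_val <- Inf
  best_par <- x0
  trace <- list()
  m_hist <- list()

  while (evals + lambda <= max_evals) {
    gen <- gen + 1L
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- m + sigma * Y
    fvals <- apply(X, 2L, fn)
    fvals[!is.finite(fvals)] <- .Machine$double.xmax # reject, keep ranking
    evals <- evals + lambda
    ord <- order(fvals)
    if (fvals[ord[1L]] < best_val) {
      best_val <- fvals[ord[1L]]
      best_par <- X[, ord[1L]]
    }
    yw <- Y[, ord[seq_len(mu)], drop = FALSE] %*% w
    m <- m + sigma * as.vector(yw)
    Cinvsqrt_yw <- B %*% ((t(B) %*% yw) / D)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.vector(Cinvsqrt_yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * as.vector(yw)
    Ymu <- Y[, ord[seq_len(mu)], drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (Ymu %*% (w * t(Ymu)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    m_hist[[gen]] <- m
    trace[[gen]] <- list(generation = gen, best = fvals[ord[1L]],
                         sigma = sigma)
    if (!is.null(on_generation)) {
      on_generation(gen, X[, ord[1L]], fvals[ord[1L]], fvals)
    }
  }
  tail_gens <- max(1L, floor(gen * 0.6)):gen
  par_avg <- Reduce(`+`, m_hist[tail_gens]) / length(tail_gens)
  list(par = m, par_avg = par_avg, best_par = best_par,
       best_value = best_val, evals = evals,
       trace = dplyr::bind_rows(trace))
}
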
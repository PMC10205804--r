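## Likelihood-free inference over populations of birds: bounded
## softplus-beta densities per parameter, the mixed Euclidean /
## quantized-p-value distance between summary datasets, k-nearest-neighbor
## log-likelihood estimates and reproducibility scoring.

## f(x) = log(exp(x) + 1) - 1; f(x) + 1 = softplus(x) > 0, so the beta
## shape parameters f(.) + 1 are always positive
softplus1 <- function(x) log1p(exp(x)) - 1

beta_shapes <- function(s, d) {
  if (d < 0) {
    c(a = softplus1(s) + 1, b = softplus1(s + d) + 1)
  } else {
    c(a = softplus1(s - d) + 1, b = softplus1(s) + 1)
  }
}

## split "v_eat.mealworm" into base name and food id
parse_param_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) list(base = name, food = NULL)
  else list(base = parts[1L], food = parts[2L])
}

param_bounds <- function(name) {
  base <- parse_param_name(name)$base
  rng <- parameter_ranges()
  row <- rng[rng$name == base, ]
  if (!nrow(row)) stop("unknown parameter '", base, "'", call. = FALSE)
  c(l = row$min, u = row$max)
}

set_param <- function(params, name, value) {
  p <- parse_param_name(name)
  if (is.null(p$food)) {
    params[[p$base]] <- value
  } else {
    params[[p$base]][food_type_id(p$food)] <- value
  }
  params
}

#' Population hyperparameters
#'
#' Per fitted parameter: a location `s` and an asymmetry `d` of the
#' softplus-beta density on the parameter's allowed interval.
#'
#' @param s,d named numeric vectors (same names; names are parameter names,
#'   per-food parameters as `"v_eat.mealworm"`).
#' @return A `hyperparameters` list.
#' @export
hyperparameters <- function(s, d = setNames(rep(0, length(s)), names(s))) {
  stopifnot(setequal(names(s), names(d)))
  structure(list(s = s, d = d[names(s)]), class = "hyperparameters")
}

#' Sample a bird parameter vector from the population density
#'
#' Each fitted parameter is drawn from a beta density with exponents
#' `f(s)` and `f(s + d)` (for `d < 0`; mirrored for `d >= 0`), where
#' `f(x) = log(exp(x) + 1) - 1`, rescaled to the parameter's interval.
#' `d = 0` gives a symmetric density; positive `d` shifts mass toward the
#' lower bound.
#'
#' @param hyper a [hyperparameters()] object.
#' @param template a [bird_parameters()] list supplying all parameters not
#'   covered by `hyper`.
#' @return A `bird_parameters` list.
#' @export
sample_parameters <- function(hyper, template = default_bird_parameters()) {
  params <- template
  for (nm in names(hyper$s)) {
    sh <- beta_shapes(hyper$s[[nm]], hyper$d[[nm]])
    z <- rbeta(1L, sh["a"], sh["b"])
    b <- param_bounds(nm)
    params <- set_param(params, nm, b["l"] + (b["u"] - b["l"]) * z)
  }
  params
}

#' Population density and moments of a fitted parameter
#'
#' @param hyper a [hyperparameters()] object.
#' @return `population_means()`: named vector of population means on the
#'   natural parameter scale; `population_density()`: a function of
#'   (name, theta) evaluating the density.
#' @export
population_means <- function(hyper) {
  vapply(names(hyper$s), function(nm) {
    sh <- beta_shapes(hyper$s[[nm]], hyper$d[[nm]])
    b <- param_bounds(nm)
    unname(b["l"] + (b["u"] - b["l"]) * sh["a"] / (sh["a"] + sh["b"]))
  }, 0)
}

#' @rdname population_means
#' @export
population_density <- function(hyper) {
  function(name, theta) {
    sh <- beta_shapes(hyper$s[[name]], hyper$d[[name]])
    b <- param_bounds(name)
    z <- (theta - b["l"]) / (b["u"] - b["l"])
    stats::dbeta(z, sh["a"], sh["b"]) / (b["u"] - b["l"])
  }
}

#' Five-level quantization of p-values
#'
#' Maps p-values to scores 1..5 with half-open bands split at 0.001, 0.01,
#' 0.05 and 0.1; highly significant p-values collapse onto one level,
#' which reduces variance during fitting.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Integer scores in 1..5.
#' @examples
#' quantize_p(c(1e-11, 1e-5, 0.03, 0.05, 0.5)) # 1 1 3 4 5
#' @export
quantize_p <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  findInterval(p, c(0, 0.001, 0.01, 0.05, 0.1))
}

#' Distance between two summary datasets
#'
#' Euclidean combination of raw differences on ordinary quantities and
#' quantized differences on p-values.
#'
#' @param d1,d2 [summary_dataset()] objects sharing index sets.
#' @return Non-negative distance.
#' @export
dataset_distance <- function(d1, d2) {
  if (!setequal(names(d1$values), names(d2$values))) {
    stop("summary datasets do not share their index sets", call. = FALSE)
  }
  v2 <- d2$values[names(d1$values)]
  ip <- d1$is_pvalue
  dd <- numeric(length(v2))
  dd[!ip] <- d1$values[!ip] - v2[!ip]
  dd[ip] <- quantize_p(d1$values[ip]) - quantize_p(v2[ip])
  sqrt(sum(dd^2))
}

log_unit_ball_volume <- function(d) {
  (d / 2) * log(pi) - lgamma(d / 2 + 1)
}

#' k-nearest-neighbor log-likelihood estimate
#'
#' Approximates the log-likelihood of one experiment's observed summary
#' dataset under the simulator: `-d_E * log(Delta^(n)) + c(d_E)` where
#' `Delta^(n)` is the distance to the n-th nearest simulated dataset and
#' the constant is the standard (Kozachenko-Leonenko) k-NN density
#' normalization `digamma(n) - digamma(K) - log V_d` (unit-ball volume),
#' which removes the finite-n bias of the naive `log(n/K)` constant and
#' keeps values comparable across `K`.
#'
#' @param observed a [summary_dataset()] (or list of them, one per
#'   experiment; the result is then summed).
#' @param simulated list of `K` simulated summary datasets (or list of
#'   such lists).
#' @param n neighbor index (1 <= n <= K).
#' @param tie_floor distances of exactly zero are floored at this value
#'   (with a warning) to keep the logarithm finite.
#' @return Approximate log-likelihood (scalar).
#' @export
knn_loglik <- function(observed, simulated, n = 5L, tie_floor = 1e-12) {
  if (inherits(observed, "summary_dataset")) {
    observed <- list(observed); simulated <- list(simulated)
  }
  total <- 0
  for (e in seq_along(observed)) {
    K <- length(simulated[[e]])
    if (K < n) stop("need K >= n simulated datasets", call. = FALSE)
    dists <- vapply(simulated[[e]], dataset_distance, 0, d2 = observed[[e]])
    dn <- sort(dists, partial = n)[n]
    if (dn <= 0) {
      warning("tied (zero) neighbor distance floored at ", tie_floor)
      dn <- tie_floor
    }
    dE <- length(observed[[e]]$values)
    total <- total - dE * log(dn) + digamma(n) - digamma(K) -
      log_unit_ball_volume(dE)
  }
  total
}

#' Reproducibility of statistical tests
#'
#' A simulated experiment repetition reproduces the observed result when
#' every one of its key tests falls on the same side of p = 0.05 as the
#' experimental test.  Returns the fraction of repetitions reproducing all
#' tests simultaneously.
#'
#' @param p_sim matrix of simulated p-values (repetitions x tests) or a
#'   vector for a single test.
#' @param p_exp numeric vector of experimental p-values (one per test).
#' @return Fraction in `[0, 1]`.
#' @examples
#' reproducibility(c(0.01, 0.2), 0.03) # 0.5
#' @export
reproducibility <- function(p_sim, p_exp) {
  p_sim <- as.matrix(p_sim)
  stopifnot(ncol(p_sim) == length(p_exp))
  side_exp <- p_exp < 0.05
  ok <- sweep(p_sim < 0.05, 2L, side_exp, `==`)
  mean(apply(ok, 1L, all))
}

#' One-sided p-value for a difference of reproducibility rates
#'
#' Treats a plotted average reproducibility as the empirical rate of
#' `trials` Bernoulli trials and tests, with a normal approximation, for
#' an excess of `rate_difference` over the least-favorable baseline rate
#' (0.5 maximises the variance, hence the p-value).
#'
#' @param rate_difference observed excess rate in `[0, 1]`.
#' @param trials number of Bernoulli trials (simulated repetitions).
#' @param baseline baseline rate; 0.5 is the least favorable.
#' @return One-sided p-value.
#' @examples
#' rate_difference_pvalue(0.03, 1000) # about 0.029
#' @export
rate_difference_pvalue <- function(rate_difference, trials, baseline = 0.5) {
  stopifnot(trials >= 1, rate_difference >= 0, rate_difference <= 1)
  se <- sqrt(baseline * (1 - baseline) / trials)
  1 - pnorm(rate_difference / se)
}
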
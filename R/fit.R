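## Population fitting: CMA-ES over the (d, s) hyperparameters with the
## k-NN log-likelihood objective and a simple adaptive-K noise schedule
## (K grows when the candidate ranking is unstable under re-evaluation).

#' Fit population hyperparameters to observed summary data
#'
#' Maximises the k-nearest-neighbor log-likelihood estimate of the
#' observed dataset(s) over the population hyperparameters of the chosen
#' free parameters, using CMA-ES.  Every objective evaluation simulates
#' `K` independent repetitions of each protocol with freshly sampled
#' birds; `K` adapts between `K_min` and `K_max`: after each generation
#' the best candidate is re-evaluated once, and only a clearly unstable
#' rank (the re-evaluation falling behind most of the generation)
#' triggers an increase.
#'
#' @param protocols a [protocol()] or list of them (joint fits share one
#'   set of hyperparameters across experiments).
#' @param observed matching [summary_dataset()] or list.
#' @param free character vector of fitted parameter names (per-food
#'   entries as `"v_eat.mealworm"`).
#' @param variant model variant.
#' @param params template [bird_parameters()] for the non-fitted entries.
#' @param budget total objective-evaluation budget for CMA-ES.
#' @param n neighbor index of the k-NN estimate (capped at the current K).
#' @param K_min,K_max bounds of the adaptive repetition count.
#' @param sigma0,lambda CMA-ES step size and population size.
#' @param seed integer seed.
#' @param K_eval,n_eval_reps final log-likelihood evaluation: repetitions
#'   per evaluation and number of evaluations (>= 2, for an SEM).
#' @param caching_mode motivational caching variant.
#' @return A `caching_fit` object with fitted hyperparameters, population
#'   means, the optimization trace, the K schedule and the final
#'   log-likelihood (mean and SEM).
#' @export
fit_population <- function(protocols, observed, free,
                           variant = "plastic_caching",
                           params = default_bird_parameters(),
                           budget = 2000L, n = 5L, K_min = 5L, K_max = 500L,
                           sigma0 = 0.7, lambda = NULL, seed = NULL,
                           K_eval = 100L, n_eval_reps = 2L,
                           caching_mode = "hunger_modulated") {
  if (inherits(protocols, "protocol")) protocols <- list(protocols)
  if (inherits(observed, "summary_dataset")) observed <- list(observed)
  stopifnot(length(protocols) == length(observed), length(free) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  M <- length(free)
  state <- new.env()
  state$K <- K_min
  state$K_trace <- integer()

  vec_to_hyper <- function(x) {
    hyperparameters(s = setNames(x[M + seq_len(M)], free),
                    d = setNames(x[seq_len(M)], free))
  }
  objective <- function(x) {
    hyper <- vec_to_hyper(x)
    ll <- 0
    for (e in seq_along(protocols)) {
      sims <- run_population(protocols[[e]], variant = variant,
                             hyper = hyper, params = params, K = state$K,
                             caching_mode = caching_mode)
      ll <- ll + knn_loglik(observed[[e]], sims, n = min(n, state$K))
    }
    -ll
  }
  on_gen <- function(gen, xbest, fbest, fvals) {
    ## re-evaluate the generation's best candidate once; only a clearly
    ## unstable ranking (re-evaluation worse than 80% of the generation)
    ## grows K, so pure objective noise does not ratchet K upward
    f2 <- objective(xbest)
    if (f2 > stats::quantile(fvals, 0.8)) {
      state$K <- min(K_max, state$K + 1L)
    } else {
      state$K <- max(K_min, state$K - 1L)
    }
    state$K_trace <- c(state$K_trace, state$K)
  }

  res <- cma_es(objective, x0 = rep(0, 2L * M), sigma0 = sigma0,
                lambda = lambda, max_evals = budget, on_generation = on_gen)
  ## noise-robust point estimate: time-averaged distribution mean
  hyper <- vec_to_hyper(res$par_avg)
  ## final evaluation at larger K, repeated for an SEM
  state$K <- K_eval
  lls <- vapply(seq_len(n_eval_reps), function(i) -objective(res$par_avg), 0)
  structure(list(
    hyper = hyper,
    free = free,
    population_means = population_means(hyper),
    loglik = mean(lls), loglik_sem = sd(lls) / sqrt(length(lls)),
    K_eval = K_eval, n = n,
    trace = res$trace, K_trace = state$K_trace,
    evals = res$evals, best_value = res$best_value,
    variant = variant, seed = seed), class = "caching_fit")
}

#' @export
print.caching_fit <- function(x, ...) {
  cat("<caching_fit> variant=", x$variant, ", ", x$evals,
      " evaluations\n  log p-hat = ", signif(x$loglik, 5L), " +/- ",
      signif(x$loglik_sem, 3L), " (K = ", x$K_eval, ")\n", sep = "")
  print(tidy.caching_fit(x))
  invisible(x)
}

#' Tidy a population fit
#'
#' @param x a `caching_fit` from [fit_population()].
#' @param ... unused.
#' @return One row per fitted parameter: location, asymmetry, population
#'   mean and bounds.
#' @method tidy caching_fit
#' @export
tidy.caching_fit <- function(x, ...) {
  bounds <- t(vapply(x$free, param_bounds, c(l = 0, u = 0)))
  tibble::tibble(parameter = x$free,
                 location = unname(x$hyper$s),
                 asymmetry = unname(x$hyper$d),
                 population_mean = unname(x$population_means),
                 lower = bounds[, "l"], upper = bounds[, "u"])
}

#' @rdname tidy.caching_fit
#' @method glance caching_fit
#' @export
glance.caching_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik_sem = x$loglik_sem,
                 evaluations = x$evals, K_eval = x$K_eval,
                 n_neighbor = x$n, n_parameters = length(x$free))
}

#' Optimization trace plot
#'
#' @param object a `caching_fit`.
#' @param ... unused.
#' @return A ggplot of the best objective value per generation.
#' @method autoplot caching_fit
#' @export
autoplot.caching_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = -.data$best)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best log p-hat estimate") +
    ggplot2::theme_minimal()
}

#' Serialize a fit result to JSON
#'
#' @param x a `caching_fit`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(x, path) {
  obj <- list(variant = x$variant, free = x$free,
              s = as.list(x$hyper$s), d = as.list(x$hyper$d),
              population_means = as.list(x$population_means),
              loglik = x$loglik, loglik_sem = x$loglik_sem,
              K_eval = x$K_eval, n = x$n, evals = x$evals, seed = x$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$hyper <- hyperparameters(s = unlist(obj$s), d = unlist(obj$d))
  obj
}
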
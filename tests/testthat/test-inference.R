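# Population densities, distances, k-NN log-likelihood and the optimizer.

make_ds <- function(values, is_p = rep(FALSE, length(values)),
                    name = "toy") {
  nm <- paste0("q", seq_along(values))
  summary_dataset(name, setNames(values, nm), setNames(is_p, nm))
}

test_that("p-value quantization has the exact half-open band structure", {
  expect_equal(quantize_p(1e-11), 1L)
  expect_equal(quantize_p(1e-5), 1L)
  expect_equal(quantize_p(0.03), 3L)
  expect_equal(quantize_p(c(0.001, 0.01, 0.05, 0.1)), c(2L, 3L, 4L, 5L))
  expect_equal(quantize_p(c(0.0009999, 0.0099, 0.0499, 0.0999, 0.5, 1)),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  ## non-decreasing step function over a dense grid
  g <- seq(0, 1, by = 1e-4)
  expect_true(all(diff(quantize_p(g)) >= 0))
  expect_error(quantize_p(1.2), "\\[0, 1\\]")
  expect_error(quantize_p(-0.1), "\\[0, 1\\]")
})

test_that("dataset distance mixes raw and quantized coordinates", {
  d1 <- make_ds(c(1, 2, 0.03), is_p = c(FALSE, FALSE, TRUE))
  expect_equal(dataset_distance(d1, d1), 0)
  ## only the p-value differs: |s(0.03) - s(0.2)| = 2
  d2 <- make_ds(c(1, 2, 0.2), is_p = c(FALSE, FALSE, TRUE))
  expect_equal(dataset_distance(d1, d2), 2)
  ## mixed case against direct arithmetic
  d3 <- make_ds(c(4, -1, 0.002), is_p = c(FALSE, FALSE, TRUE))
  expect_equal(dataset_distance(d1, d3), sqrt(3^2 + 3^2 + 1^2))
  expect_equal(dataset_distance(d3, d1), dataset_distance(d1, d3))
  d4 <- summary_dataset("toy", c(a = 1), c(a = FALSE))
  expect_error(dataset_distance(d1, d4), "index sets")
})

test_that("parameter sampling follows the softplus-beta construction", {
  set.seed(91)
  ## d = 0: symmetric density, mean at the interval center
  h0 <- hyperparameters(s = c(tau_h = 1), d = c(tau_h = 0))
  draws <- replicate(4000, sample_parameters(h0)$tau_h)
  expect_true(all(draws >= 50 & draws <= 300))
  expect_lt(abs(mean(draws) - 175), 4)
  expect_equal(unname(population_means(h0)["tau_h"]), 175)
  ## large positive d shifts mass toward the lower bound
  hp <- hyperparameters(s = c(tau_h = 1), d = c(tau_h = 4))
  dp <- replicate(2000, sample_parameters(hp)$tau_h)
  expect_lt(mean(dp), 120)
  ## moments match numerical quadrature of the density
  hq <- hyperparameters(s = c(eta_eat = 1.3), d = c(eta_eat = -0.7))
  dens <- population_density(hq)
  norm <- stats::integrate(function(x) dens("eta_eat", x), -1, 1)$value
  expect_equal(norm, 1, tolerance = 1e-6)
  m_quad <- stats::integrate(function(x) x * dens("eta_eat", x), -1, 1)$value
  expect_equal(unname(population_means(hq)["eta_eat"]), m_quad,
               tolerance = 1e-6)
  dq <- replicate(4000, sample_parameters(hq)$eta_eat)
  expect_lt(abs(mean(dq) - m_quad), 0.03)
  ## per-food names address single entries
  hf <- hyperparameters(s = c(`v_eat.mealworm` = 0), d = c(`v_eat.mealworm` = 0))
  pars <- sample_parameters(hf)
  expect_equal(pars$v_eat[3], default_bird_parameters()$v_eat[3])
  expect_true(pars$v_eat[1] >= 0.1 && pars$v_eat[1] <= 1)
})

test_that("k-NN log-likelihood is log-linear in distance and permutation-invariant", {
  obs <- make_ds(c(0, 0))
  sims <- lapply(c(1, 2, 3, 4, 5, 6), function(r) make_ds(c(r, 0)))
  ll1 <- knn_loglik(obs, sims, n = 5)
  expect_equal(knn_loglik(obs, rev(sims), n = 5), ll1)
  ## doubling all distances lowers the estimate by d_E log 2
  sims2 <- lapply(c(2, 4, 6, 8, 10, 12), function(r) make_ds(c(r, 0)))
  expect_equal(knn_loglik(obs, sims2, n = 5), ll1 - 2 * log(2),
               tolerance = 1e-12)
  expect_error(knn_loglik(obs, sims[1:3], n = 5), "K >= n")
  ## ties at zero distance are floored with a warning
  expect_warning(knn_loglik(obs, rep(list(obs), 6), n = 5), "floored")
})

test_that("the k-NN estimate approaches the true density at the mode", {
  ## 1-D standard normal through the summary-dataset machinery
  set.seed(101)
  obs <- make_ds(0)
  ll <- replicate(20, {
    sims <- lapply(rnorm(2000), make_ds)
    knn_loglik(obs, sims, n = 5)
  })
  ## per-evaluation sd is sqrt(trigamma(5)) ~ 0.47; 20 replicates give a
  ## standard error of ~0.105
  expect_lt(abs(mean(ll) - (-log(sqrt(2 * pi)))), 0.3)
})

test_that("reproducibility counts test agreement at the 0.05 level", {
  expect_equal(reproducibility(c(0.01, 0.2), 0.03), 0.5)
  expect_equal(reproducibility(matrix(c(0.01, 0.2), 1L), c(0.03, 0.3)), 1)
  ## all listed tests must be reproduced simultaneously
  p_sim <- rbind(c(0.01, 0.2), c(0.01, 0.01), c(0.3, 0.2))
  expect_equal(reproducibility(p_sim, c(0.02, 0.4)), 1 / 3)
})

test_that("the Bernoulli-rate significance bound holds at n = 1000", {
  p <- rate_difference_pvalue(0.03, 1000)
  expect_lte(p, 0.031)
  expect_gt(p, 0.02)
  expect_equal(rate_difference_pvalue(0, 1000), 0.5)
  ## 0.5 is the least favorable baseline
  expect_lt(rate_difference_pvalue(0.03, 1000, baseline = 0.1), p)
})

test_that("the CMA-ES adapter minimises a deterministic quadratic", {
  set.seed(111)
  fn <- function(x) sum((x - c(1, -2, 0.5))^2)
  res <- cma_es(fn, x0 = rep(0, 3), sigma0 = 0.5, max_evals = 1500)
  expect_lt(sqrt(sum((res$par - c(1, -2, 0.5))^2)), 1e-3)
  expect_lt(res$best_value, 1e-5)
  expect_true(all(diff(res$trace$generation) == 1))
})

test_that("fit results expose tidy/glance/JSON interfaces", {
  set.seed(121)
  proto <- fixture_specific_satiety(n_birds = 2L)
  obs <- run_population(proto, K = 1L, seed = 5L)[[1]]
  fit <- fit_population(proto, obs, free = c("tau_h", "eta_eat"),
                        budget = 30L, K_min = 2L, n = 2L, lambda = 6L,
                        K_eval = 3L, seed = 13L)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$parameter, c("tau_h", "eta_eat"))
  expect_true(all(td$population_mean >= td$lower &
                    td$population_mean <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 2L)
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(unname(unlist(back$s)), unname(fit$hyper$s))
})
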
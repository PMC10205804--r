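# Bird assembly, lesions, the event loop and population runs.

test_that("unknown variants are rejected with the list of valid tags", {
  expect_error(make_bird("psychic_bird"), "plastic_caching")
})

test_that("the triple lesion leaves constant action probabilities", {
  b <- make_bird("no_plasticity_no_memory_no_motivation",
                 bird_parameters(eta_eat = 0.4, eta_cache = 0.3,
                                 eta_inspect = 0.2))
  cg <- cage()
  apply_action(cg, "add", food_item("mealworm", 3L))
  apply_action(cg, "add", tray("A", 1L, 1L))
  cand <- cachesim:::enumerate_candidates(b, cg, 480)
  expect_equal(cand$prefs[cand$kinds == "eat"], 0.4)      # sigma(eta_eat)
  expect_equal(cand$prefs[cand$kinds == "cache"], 0.3)    # sigma(eta_cache)
  expect_equal(cand$prefs[cand$kinds == "inspect"], 0.2)  # sigma(eta_inspect)
  ## hunger is clamped at zero through time and eating
  set.seed(61)
  cage_wait(cg, b, 30)
  expect_equal(b$mot$h, rep(0, 11))
})

test_that("no-plasticity birds keep caching weights at zero but learn readouts", {
  set.seed(62)
  p <- bird_parameters(eta_inspect = 0.5, p_other = 0)
  b <- make_bird("no_plasticity", p)
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  ## implant a memory of a cached cricket, then let the bird recover a
  ## degraded item
  encode_caching_event(b$mem, "cricket", c(1L, 33L), 300)
  tr <- cachesim:::get_tray(cg, "A")
  tr$it_type <- 7L; tr$it_fresh <- 0; tr$it_time <- 300; tr$it_amount <- 1L
  cg$trays[["A"]] <- tr
  cg$n_added <- 1L
  cage_wait(cg, b, 20)
  ev <- bird_events(b)
  expect_true("degraded_food_item" %in% ev$outcome)
  expect_lt(b$mem$v[1L, 7L], 1)       # readout learning still active
  expect_true(all(b$wc == 0))          # caching weights stay lesioned
})

test_that("retrieval outcomes drive readout and caching-weight changes together", {
  set.seed(63)
  p <- bird_parameters(eta_inspect = 0.5, p_other = 0, alpha_fresh = 0.7,
                       alpha_degrade = 0.2)
  b <- make_bird("plastic_caching", p)
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  encode_caching_event(b$mem, "cricket", c(1L, 33L), 300)
  tr <- cachesim:::get_tray(cg, "A")
  tr$it_type <- 7L; tr$it_fresh <- 0; tr$it_time <- 300; tr$it_amount <- 1L
  cg$trays[["A"]] <- tr
  cg$n_added <- 1L
  w0 <- b$wc[7L, 1L]
  cage_wait(cg, b, 20)
  expect_lt(b$mem$v[1L, 7L], 1)  # expected freshness lowered
  expect_lt(b$wc[7L, 1L], w0)    # caching weight decreased
  expect_equal(b$wc[7L, 33L], b$wc[7L, 1L]) # both features updated
})

test_that("retrieving from an emptied tray yields the pilfered outcome", {
  set.seed(64)
  p <- bird_parameters(eta_inspect = 0.5, p_other = 0, alpha_pilfer = 0.2)
  b <- make_bird("plastic_caching", p)
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  encode_caching_event(b$mem, "mealworm", c(1L, 33L), 300)
  w0 <- b$wc[1L, 1L]
  cage_wait(cg, b, 10)
  ev <- bird_events(b)
  expect_true("pilfered" %in% ev$outcome)
  expect_lt(b$wc[1L, 1L], w0)          # unsuccessful retrieval: decrease
  expect_equal(b$mem$v[1L, 1L], 1)     # no freshness signal on pilfered
})

test_that("a retrieved fresh item re-enters the perceived food pool", {
  set.seed(65)
  p <- bird_parameters(eta_inspect = 0.5, eta_eat = -1, p_other = 0)
  b <- make_bird("plastic_caching", p)
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  encode_caching_event(b$mem, "peanut", c(1L, 33L), 300)
  tr <- cachesim:::get_tray(cg, "A")
  tr$it_type <- 3L; tr$it_fresh <- 1; tr$it_time <- 300; tr$it_amount <- 1L
  cg$trays[["A"]] <- tr
  cg$n_added <- 1L
  cage_wait(cg, b, 5)
  ev <- bird_events(b)
  expect_true("fresh_food_item" %in% ev$outcome)
  ## item is loose again (the bird will not eat it: eta_eat = -1)
  expect_equal(count_food_items(cg, "peanut") +
                 count_cached_items(cg, "A", "peanut"), 1L)
  expect_true(cachesim:::check_conservation(cg))
})

test_that("population runs are reproducible and independent across K", {
  proto <- fixture_specific_satiety(n_birds = 3L)
  a <- run_population(proto, K = 2L, seed = 99L)
  b <- run_population(proto, K = 2L, seed = 99L)
  expect_identical(a[[1]]$values, b[[1]]$values)
  expect_identical(a[[2]]$values, b[[2]]$values)
  expect_false(identical(a[[1]]$values, a[[2]]$values))
})

test_that("series runs keep bird state across protocols", {
  p1 <- protocol("phase1", groups = c(g = 1L),
                 steps = list(g = list(
                   list(op = "add_tray", tray = "A", appearance = 1L,
                        position = 1L),
                   list(op = "add_food", type = "peanut", amount = 5L),
                   list(op = "wait", minutes = 20),
                   list(op = "measure", what = "count_cached_items",
                        tray = "A", name = "cached"))))
  p2 <- protocol("phase2", groups = c(g = 1L),
                 steps = list(g = list(
                   list(op = "wait", minutes = 10),
                   list(op = "measure", what = "count_food_items",
                        name = "left"))))
  set.seed(71)
  birds <- list(g = make_group(1L, params = bird_parameters(eta_cache = 0.8,
                                                            p_other = 0)))
  out <- run_protocol_series(list(p1, p2), birds)
  expect_length(out, 2L)
  ## the memory formed in phase 1 is still present in the same bird
  expect_gt(sum(birds$g[[1]]$mem$cnt), 0)
})

test_that("replay birds accumulate episodic memory during protocols", {
  set.seed(72)
  proto <- fixture_dekort07_exp4(n_per_group = 1L)
  birds <- fixture_birds(proto, variant = "planning_by_replay",
                         params = fixture_params(eta_cache = 0.3,
                                                 eta_inspect = 0.3))
  run_protocol(proto, birds)
  rm <- birds$pilfered[[1]]$replay
  expect_gt(length(rm$items), 1L)
  expect_true(all(diff(rm$times) >= 60))
  outs <- unlist(lapply(rm$items, function(it) it$o))
  expect_true("pilfered" %in% outs)
})

test_that("lesioning motivational control worsens the fit to satiety data", {
  ## the triple-lesion variant cannot express specific satiety, so its
  ## distance to a satiety reference dataset is stochastically larger
  proto <- fixture_specific_satiety(n_birds = 4L)
  ref <- generate_reference_data(
    ground_truth_scenario("specific_satiety",
                          satiety_ground_truth(), K = 50L, seed = 81L),
    n_birds = 4L)
  full <- run_population(proto, K = 40L, seed = 82L)
  lesion <- run_population(proto, variant = "no_plasticity_no_memory_no_motivation",
                           K = 40L, seed = 83L)
  d_full <- vapply(full, dataset_distance, 0, d2 = ref)
  d_les <- vapply(lesion, dataset_distance, 0, d2 = ref)
  expect_lt(stats::wilcox.test(d_full, d_les,
                               alternative = "less")$p.value, 0.01)
})
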
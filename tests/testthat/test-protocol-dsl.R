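# The protocol language: experimenter actions, measurements, waits,
# serialization and conservation.

test_that("pilfer, degrade and cover behave as specified", {
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  tr <- cachesim:::get_tray(cg, "A")
  tr$it_type <- rep(1L, 3); tr$it_fresh <- rep(1, 3)
  tr$it_time <- rep(480, 3); tr$it_amount <- rep(1L, 3)
  cg$trays[["A"]] <- tr
  cg$n_added <- cg$n_added + 3L
  expect_equal(count_cached_items(cg, "A"), 3L)
  apply_action(cg, "pilfer", "A")
  expect_equal(count_cached_items(cg, "A"), 0L) # all items removed

  cg2 <- cage()
  apply_action(cg2, "add", tray("B", 2L, 2L))
  tr <- cachesim:::get_tray(cg2, "B")
  tr$it_type <- 7L; tr$it_fresh <- 1; tr$it_time <- 480; tr$it_amount <- 1L
  cg2$trays[["B"]] <- tr
  apply_action(cg2, "degrade", "B")
  expect_equal(cg2$trays[["B"]]$it_fresh, 0) # freshness set to zero
  expect_equal(cg2$trays[["B"]]$it_amount, 1L) # item still present

  expect_error(apply_action(cg2, "pilfer", "Z"), "no tray")
  expect_error(apply_action(cg2, "remove", "Z"), "identifier 'Z'")
  apply_action(cg2, "cover", "B")
  expect_error(apply_action(cg2, "cover", "B"), "already covered")
})

test_that("covered trays are excluded from the bird's actions", {
  set.seed(9)
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L, open = FALSE))
  apply_action(cg, "add", food_item("mealworm", 10L))
  b <- make_bird(params = bird_parameters(eta_cache = 1)) # eager cacher
  cage_wait(cg, b, 15)
  expect_equal(count_cached_items(cg, "A"), 0L)
  ev <- bird_events(b)
  expect_false(any(ev$action %in% c("cache", "inspect")))
  expect_gt(nrow(ev), 0L) # food alone is enough to generate events
})

test_that("counts and first inspections read the observer log", {
  cg <- cage()
  apply_action(cg, "add", tray("A", 1L, 1L))
  apply_action(cg, "add", tray("B", 2L, 2L))
  apply_action(cg, "add", inspection_observer("obs", c(1L, 2L)))
  cachesim:::observer_log_retrieve(cg, cachesim:::get_tray(cg, "A"), 3)
  cachesim:::observer_log_retrieve(cg, cachesim:::get_tray(cg, "B"), 5)
  cachesim:::observer_log_retrieve(cg, cachesim:::get_tray(cg, "A"), 6)
  expect_equal(count_inspections(cg, "obs"), 3L)
  expect_equal(count_inspections(cg, "obs", appearance = 1L), 2L)
  expect_equal(count_inspections(cg, "obs", appearance = 2L), 1L)
  expect_equal(first_inspection(cg, "obs"), 1L)
  expect_true(all(diff(observer_log(cg, "obs")$time) >= 0)) # monotone log
  ## empty log: explicit sentinel, not an exception
  apply_action(cg, "add", inspection_observer("empty", 9L))
  expect_identical(first_inspection(cg, "empty"), NA_integer_)
  expect_error(count_inspections(cg, "nope"), "no observer")
})

test_that("counting loose food reflects eaten items", {
  set.seed(10)
  cg <- cage()
  apply_action(cg, "add", food_item("mealworm", 5L))
  b <- make_bird(params = bird_parameters(v_eat = 1, eta_eat = 1,
                                          p_other = 0, delta_eat = 10))
  cage_wait(cg, b, 10)
  eaten <- cg$eaten_by_type[1]
  expect_equal(count_food_items(cg), 5L - eaten)
  expect_gt(eaten, 0)
  expect_true(cachesim:::check_conservation(cg))
})

test_that("waiting without relevant objects advances only continuous state", {
  set.seed(11)
  cg <- cage()
  b <- make_bird()
  h0 <- b$mot$h[1]
  cage_wait(cg, b, 120)
  expect_equal(cg$clock, 480 + 120)
  expect_equal(b$n_events, 0L)            # no events in an empty cage
  expect_gt(b$mot$h[1], h0)               # hunger kept rising
  ## tiny waits advance the clock exactly, with no event fitting inside
  cg2 <- cage()
  apply_action(cg2, "add", food_item("peanut", 2L))
  b2 <- make_bird()
  cage_wait(cg2, b2, 0.01)
  expect_equal(cg2$clock, 480.01)
  expect_equal(b2$n_events, 0L)
  expect_error(cage_wait(cg2, b2, 0), "positive")
})

test_that("nightly consolidation fires inside long waits", {
  set.seed(12)
  cg <- cage()
  b <- make_bird()
  encode_caching_event(b$mem, "peanut", c(1L, 33L), 480)
  cage_wait(cg, b, 3 * 1440)
  ## three nights have passed: trace sits in layer 4
  expect_equal(recall(b$mem, c(1L, 33L), cg$clock)$layer, 4L)
})

test_that("protocols serialize to YAML and re-execute identically", {
  proto <- fixture_specific_satiety(n_birds = 3L)
  txt <- protocol_to_yaml(proto)
  proto2 <- protocol_from_yaml(text = txt)
  expect_equal(proto2$name, proto$name)
  expect_equal(proto2$groups, proto$groups)
  expect_equal(length(proto2$steps$prefed), length(proto$steps$prefed))
  set.seed(21); a <- run_protocol(proto, fixture_birds(proto))
  set.seed(21); b <- run_protocol(proto2, fixture_birds(proto2))
  expect_identical(a$values, b$values)
  ## the shipped fixture files parse to the same protocols
  path <- system.file("extdata", "protocols", "specific_satiety.yaml",
                      package = "cachesim")
  expect_equal(protocol_from_yaml(path)$groups, c(prefed = 8L))
})

test_that("runs are deterministic under a fixed seed and schema-complete", {
  proto <- fixture_specific_satiety(n_birds = 2L)
  set.seed(31); a <- run_protocol(proto, fixture_birds(proto))
  set.seed(31); b <- run_protocol(proto, fixture_birds(proto))
  expect_identical(a$values, b$values)
  expect_setequal(names(a$values), protocol_schema(proto))
  expect_true(all(a$values[a$is_pvalue] >= 0 & a$values[a$is_pvalue] <= 1))
  ## group size mismatch is an error
  expect_error(run_protocol(proto, list(prefed = list(make_bird()))),
               "needs 2 birds")
})

test_that("protocols without declared tests yield an empty p-value set", {
  proto <- protocol("tiny", groups = c(g = 2L),
                    steps = list(g = list(
                      list(op = "add_food", type = "peanut", amount = 2L),
                      list(op = "wait", minutes = 5),
                      list(op = "measure", what = "count_food_items",
                           type = "peanut", name = "left"))))
  set.seed(41)
  ds <- run_protocol(proto, list(g = make_group(2L)))
  expect_equal(sum(ds$is_pvalue), 0L)
  d0 <- dataset_distance(ds, ds)
  expect_equal(d0, 0)
})

test_that("summary datasets round-trip through the CSV schema", {
  proto <- fixture_specific_satiety(n_birds = 2L)
  set.seed(51)
  ds <- run_protocol(proto, fixture_birds(proto))
  path <- tempfile(fileext = ".csv")
  write_summary_csv(ds, path)
  back <- read_summary_csv(path)
  expect_equal(back$values[names(ds$values)], ds$values)
  expect_equal(back$is_pvalue[names(ds$values)], ds$is_pvalue)
  expect_equal(dataset_distance(ds, back), 0)
})
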
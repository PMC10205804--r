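# Episodic replay memory: grouping of interactions, context matching,
# forward replay and the squashed caching weight.

h_of <- function(x) rep(x, 11)

test_that("interactions group into items by the one-hour rule", {
  rm <- replay_memory()
  rm <- record_interaction(rm, 1L, h_of(0.8), "not_inspected", 480)
  rm <- record_interaction(rm, 1L, h_of(0.4), "fresh_food_item", 490)
  expect_length(rm$items, 1L)
  expect_equal(rm$items[[1]]$h[1, 1], 0.6)  # half-half hunger average
  expect_equal(rm$items[[1]]$o, "fresh_food_item") # outcome overwritten
  ## different tray within the hour extends the current item
  rm <- record_interaction(rm, 2L, h_of(0.5), "pilfered", 500)
  expect_length(rm$items, 1L)
  expect_equal(rm$items[[1]]$x, c(1L, 2L))
  ## a gap of two hours starts a new item
  rm <- record_interaction(rm, 1L, h_of(0.5), "not_inspected", 620)
  expect_length(rm$items, 2L)
})

test_that("consecutive items are always separated by at least the gap", {
  set.seed(66)
  rm <- replay_memory()
  t <- 480
  for (k in 1:60) {
    t <- t + runif(1, 5, 200)
    rm <- record_interaction(rm, sample(1:3, 1L), h_of(runif(1)),
                             sample(c("pilfered", "fresh_food_item",
                                      "not_inspected"), 1L), t)
  }
  expect_true(all(diff(rm$times) >= 60))
})

test_that("replay-index search matches exhaustive enumeration", {
  ## deterministic alternating history: A,B,A,B,A as single-tray items
  rm <- replay_memory()
  trays <- c(1L, 2L, 1L, 2L, 1L)
  for (i in seq_along(trays)) {
    rm <- record_interaction(rm, trays[i], h_of(0.5), "not_inspected",
                             480 + i * 120)
  }
  found <- find_replay_indices(rm)
  expect_equal(found$indices, brute_replay_indices(rm))
  expect_equal(found$indices, 3L) # earlier (B,A) context ending at item 3
  ## random histories up to 50 items
  set.seed(77)
  for (rep in 1:30) {
    rm <- replay_memory()
    t <- 480
    for (k in seq_len(sample(3:50, 1L))) {
      t <- t + runif(1, 61, 400)
      rm <- record_interaction(rm, sample(1:3, 1L), h_of(runif(1)),
                               sample(c("pilfered", "fresh_food_item",
                                        "degraded_food_item",
                                        "not_inspected"), 1L), t)
    }
    expect_equal(find_replay_indices(rm)$indices, brute_replay_indices(rm))
  }
  ## empty and too-short histories give the empty index set
  expect_length(find_replay_indices(replay_memory())$indices, 0L)
})

test_that("the similarity-weight outcome term follows the configured sign", {
  ## alternating single-tray items; two candidate contexts (ending at
  ## items 4 and 6) both match the query context exactly; hunger is
  ## identical everywhere, outcomes agree fully for one candidate and
  ## disagree at one matched offset for the other
  mk <- function() {
    rm <- replay_memory()
    os <- c("not_inspected", "pilfered", rep("not_inspected", 6))
    for (i in 1:8) {
      rm <- record_interaction(rm, c(1L, 2L)[1 + i %% 2], rep(0.5, 11),
                               os[i], 480 + i * 120)
    }
    rm
  }
  rm <- mk()
  f_agree <- find_replay_indices(rm, "agreement_rewards")
  expect_equal(f_agree$indices, c(4L, 6L))
  expect_equal(f_agree$indices, brute_replay_indices(rm))
  ## fully agreeing context (candidate 6) wins when agreement rewards
  expect_gt(f_agree$weights[2], f_agree$weights[1])
  ## the formula as printed adds the agreement indicator to the distance,
  ## so the ordering flips; both behaviors stay available behind the flag
  f_printed <- find_replay_indices(rm, "as_printed")
  expect_lt(f_printed$weights[2], f_printed$weights[1])
  ## hand-checked values: agree terms contribute 1 - 1/12, disagree 1
  expect_equal(f_printed$weights[1], (1 + 11 / 12 + 11 / 12) / 3,
               tolerance = 1e-12)
  expect_equal(f_printed$weights[2], 11 / 12, tolerance = 1e-12)
})

test_that("replayed outcomes set the sign of the caching weight", {
  p <- bird_parameters(alpha_hunger = 0, alpha_fresh_r = 0.8,
                       alpha_degrade_r = 0.8, alpha_pilfer_r = 0.8,
                       gamma_replay = 0.8)
  ## empty history: neutral weight
  expect_equal(replay_caching_weight(replay_memory(), "mealworm", 1L, p), 0)
  ## context [2],[1] repeats; replaying from the earlier match encounters
  ## the pilfered retrieval at tray 1
  mk <- function(outcome, h) {
    rm <- replay_memory()
    seq_x <- c(2L, 1L, 1L, 2L, 1L)
    seq_o <- c("not_inspected", "not_inspected", outcome,
               "not_inspected", "not_inspected")
    for (i in 1:5) {
      rm <- record_interaction(rm, seq_x[i], h_of(h), seq_o[i],
                               480 * i + 480)
    }
    rm
  }
  rm <- mk("pilfered", 0.9)
  expect_equal(find_replay_indices(rm, p$similarity_outcome_sign)$indices, 2L)
  w <- replay_caching_weight(rm, "mealworm", 1L, p)
  expect_lt(w, 0)
  expect_gt(w, -1)
  ## fresh outcomes with low stored hunger yield a positive weight
  w2 <- replay_caching_weight(mk("fresh_food_item", 0.3), "mealworm", 1L, p)
  expect_gt(w2, 0)
  expect_lt(w2, 1)
})

test_that("the caching weight equals a hand-rolled replay computation", {
  p <- bird_parameters(alpha_hunger = 0.3, alpha_fresh_r = 0.8,
                       alpha_degrade_r = 0.7, alpha_pilfer_r = 0.9,
                       gamma_replay = 0.6, theta_replay = 0.99)
  rm <- replay_memory()
  xs <- c(1L, 2L, 3L, 1L, 2L, 3L)
  os <- c("not_inspected", "fresh_food_item", "not_inspected",
          "pilfered", "fresh_food_item", "not_inspected")
  hs <- c(0.5, 0.5, 0.5, 0.9, 0.5, 0.5)
  for (i in 1:6) {
    rm <- record_interaction(rm, xs[i], h_of(hs[i]), os[i], 480 * i + 480)
  }
  found <- find_replay_indices(rm, p$similarity_outcome_sign)
  expect_equal(found$indices, 3L)  # full 3-item context match
  expect_equal(found$indices, brute_replay_indices(rm))
  wsim <- found$weights[1]
  ## replay from item 3: item 4 holds the queried tray 1, pilfered, at
  ## discount gamma^1; items 5 and 6 hold other trays
  manual <- wsim * (0.6 * (0.3 * 0.9 - 0.9))
  expect_equal(replay_caching_weight(rm, "mealworm", 1L, p), tanh(manual),
               tolerance = 1e-12)
})

test_that("replay memories serialize to JSON lines", {
  rm <- replay_memory()
  rm <- record_interaction(rm, 1L, h_of(0.5), "not_inspected", 480)
  rm <- record_interaction(rm, 2L, h_of(0.7), "pilfered", 700)
  lines <- replay_to_jsonl(rm)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[2])
  expect_equal(parsed$trays, 2L)
  expect_equal(parsed$outcomes, "pilfered")
})
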
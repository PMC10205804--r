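## Decision making: eat/cache/inspect preferences and the rejection-sampling
## attention loop.  All preferences go through the clipped-linear activation
## sigma(u) = min(1, max(0, u)), so they are probabilities directly.

sigma_clip <- function(u) pmin(1, pmax(0, u))

#' Eating preference
#'
#' `sigma(v_eat_f * h_f + eta_eat)` for an actually perceived item of food
#' type `f`.  Remembered-only items (food indicator neuron off) have zero
#' eating preference.
#'
#' @param food_type food type name.
#' @param h hunger vector (length 11).
#' @param params a [bird_parameters()] list.
#' @param perceived logical; `FALSE` for remembered-only items.
#' @return Preference in `[0, 1]`.
#' @export
eat_preference <- function(food_type, h, params, perceived = TRUE) {
  if (!perceived) return(0)
  f <- food_type_id(food_type)
  sigma_clip(params$v_eat[f] * h[f] + params$eta_eat)
}

#' Caching preference
#'
#' `sigma(w_cache[f, x_a] + w_cache[f, x_p] + v_cache_f * h_f + eta_cache)`.
#' The motivational term depends on the caching-motivation variant:
#' `"hunger_modulated"` uses `v_cache_f * h_f`, `"unmodulated"` drops it,
#' `"caching_modulated"` replaces it by `v_cache_f * c_f`.  The
#' planning-by-replay model substitutes `tanh(w_fx)` (from replayed
#' episodes) for the two weight terms.
#'
#' @inheritParams eat_preference
#' @param features the tray's two feature indices.
#' @param w_cache 11 x 64 caching-weight matrix, or `NULL` when the weight
#'   terms are replaced (`replay_weight`) or lesioned.
#' @param c_vec caching-motivation vector (length 11).
#' @param caching_mode one of `"hunger_modulated"`, `"unmodulated"`,
#'   `"caching_modulated"`.
#' @param replay_weight squashed replay weight `tanh(w_fx)` replacing the
#'   plastic weight terms, or `NULL`.
#' @return Preference in `[0, 1]`.
#' @export
cache_preference <- function(food_type, features, w_cache, h, c_vec, params,
                             caching_mode = "hunger_modulated",
                             replay_weight = NULL) {
  f <- food_type_id(food_type)
  wterm <- if (!is.null(replay_weight)) replay_weight
    else if (is.null(w_cache)) 0
    else w_cache[f, features[1L]] + w_cache[f, features[2L]]
  mot <- switch(caching_mode,
    hunger_modulated = params$v_cache[f] * h[f],
    unmodulated = 0,
    caching_modulated = params$v_cache[f] * c_vec[f],
    stop("unknown caching mode '", caching_mode, "'", call. = FALSE))
  sigma_clip(wterm + mot + params$eta_cache)
}

#' Inspection preference
#'
#' Maximum over food types and memory layers of
#' `sigma(phi^(l)_f v^(l)_f + v_inspect_f h_f + eta_inspect)` with
#' `v_inspect_f = s_inspect * v_eat_f`.  Recalled memories of
#' fresh-expected food boost the inspection preference of their tray.
#'
#' @inheritParams eat_preference
#' @param recalled data frame from [recall()] (columns `food_id`, `layer`,
#'   `phi`); pass an empty one for lesioned memory.
#' @param v readout-weight matrix (7 x 11) of the memory state.
#' @return Preference in `[0, 1]`.
#' @export
inspect_preference <- function(recalled, v, h, params) {
  rec <- if (is.data.frame(recalled)) {
    if (nrow(recalled)) list(food_id = recalled$food_id,
                             layer = recalled$layer) else NULL
  } else recalled
  inspect_pref_core(rec, v, h, params)
}

inspect_pref_core <- function(rec, v, h, params) {
  base <- params$s_inspect * params$v_eat * h + params$eta_inspect
  best <- max(sigma_clip(base))
  if (!is.null(rec)) {
    u <- v[cbind(rec$layer, rec$food_id)] + base[rec$food_id]
    best <- max(best, sigma_clip(u))
  }
  best
}

#' Select an action by the rejection-sampling attention loop
#'
#' Repeats: attend to one uniformly drawn candidate, accept it if its
#' preference exceeds a fresh `U[0, 1]` threshold.  The induced selection
#' distribution is proportional to the preferences.  After acceptance, a
#' post-action time-out is drawn uniformly from `[1, delta_kind]` seconds.
#' If all preferences are zero the loop is capped at `10 * n` iterations
#' and the `other` action is forced with the minimal one-second wait
#' (flagged as a degenerate draw).
#'
#' @param preferences numeric vector of candidate preferences in `[0, 1]`.
#' @param kinds character vector of candidate kinds (`"eat"`, `"cache"`,
#'   `"inspect"`, `"other"`), used for the time-out constants.
#' @param params a [bird_parameters()] list (fields `delta_eat`,
#'   `delta_cache`, `delta_inspect`, `delta_other`, in seconds).
#' @return A list with `index` (selected candidate), `wait_s` (time-out in
#'   seconds), `iterations`, and `degenerate` (logical).
#' @export
select_action <- function(preferences, kinds, params) {
  n <- length(preferences)
  stopifnot(n >= 1L, length(kinds) == n)
  cap <- 10L * n
  it <- 0L
  idx <- NA_integer_
  while (it < cap) {
    it <- it + 1L
    i <- sample.int(n, 1L)
    if (preferences[i] > runif(1L)) { idx <- i; break }
  }
  degenerate <- is.na(idx)
  if (degenerate) {
    idx <- match("other", kinds)
    if (is.na(idx)) idx <- n
    wait_s <- 1
  } else {
    delta <- params[[paste0("delta_", kinds[idx])]]
    wait_s <- runif(1L, 1, delta)
  }
  list(index = idx, wait_s = wait_s, iterations = it, degenerate = degenerate)
}
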
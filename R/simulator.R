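## Event-based integration of bird behavior inside protocol waits.
## Variables change smoothly between events (closed-form propagation,
## split at nightly consolidation ticks) and jump at events.  Decision
## instants are generated by the post-action time-out draws themselves.

## any food or open caching tray relevant to the experiment?
cage_relevant <- function(cg) {
  any(cg$lf_by_type > 0L) ||
    (length(cg$trays) > 0L &&
       any(vapply(cg$trays, function(tr) tr$open, TRUE)))
}

open_tray_features <- function(cg) {
  feats <- integer()
  for (tr in cg$trays) if (tr$open) feats <- c(feats, tray_features(tr))
  feats
}

## continuous update of one bird from b$t to `to`, splitting the interval
## at nightly consolidation ticks; applies the hunger-gated caching-weight
## growth for the tray features currently perceived
advance_bird <- function(b, cg, to) {
  if (is.na(b$t)) b$t <- cg$clock
  if (is.null(b$next_tick) || is.na(b$next_tick)) {
    b$next_tick <- next_tick_time(b$mem, b$t)
  }
  while (b$next_tick <= to) {
    advance_continuous(b, cg, b$next_tick)
    consolidate(b$mem, b$next_tick)
    b$next_tick <- b$next_tick + 1440
  }
  ## common case: no tick inside the interval, no lesion, no open tray
  if (!b$lesion_motivation) {
    if (b$variant == "plastic_caching" && length(cg$trays)) {
      advance_continuous(b, cg, to)
      return(invisible(b))
    }
    dt <- to - b$t
    if (dt > 0) {
      b$mot <- propagate_core(b$mot, dt, b$params, cg$maintenance_diet,
                              update_c = b$caching_mode == "caching_modulated")
    }
  }
  b$t <- to
  invisible(b)
}

advance_continuous <- function(b, cg, to) {
  dt <- to - b$t
  if (dt <= 0) { b$t <- to; return(invisible(b)) }
  if (!b$lesion_motivation) {
    if (b$variant == "plastic_caching" && length(cg$trays)) {
      feats <- open_tray_features(cg)
      ## the gate can only open within the interval if hunger is already
      ## above threshold or could relax upward past it (pure-rise bound)
      hmax <- max(b$mot$h)
      if (length(feats) &&
          (hmax > .THETA_HUNGRY ||
             1 - (1 - hmax) * exp(-dt / b$params$tau_h) > .THETA_HUNGRY)) {
        ta <- hungry_time(b$mot, dt, .THETA_HUNGRY, b$params,
                          cg$maintenance_diet)
        b$wc <- grow_while_hungry(b$wc, feats, ta, b$params)
      }
    }
    b$mot <- propagate_core(b$mot, dt, b$params, cg$maintenance_diet,
                            update_c = b$caching_mode == "caching_modulated")
  }
  b$t <- to
  invisible(b)
}

log_event <- function(b, t, action, food_type = NA_character_,
                      tray = NA_character_, outcome = NA_character_,
                      pref = NA_real_, iters = NA_integer_) {
  b$n_events <- b$n_events + 1L
  b$events[[b$n_events]] <- list(bird = b$id, time = t, action = action,
                                 food_type = food_type, tray = tray,
                                 outcome = outcome, preference = pref,
                                 iterations = as.integer(iters))
  invisible(b)
}

## enumerate action candidates: 1 other + n_f eat + n_f x n_x cache +
## n_x retrieve, with preferences per Eqs of the decision module
enumerate_candidates <- function(b, cg, t) {
  h <- b$mot$h
  p <- b$params
  type_ids <- which(cg$lf_by_type > 0L)
  eatables <- type_ids[.EATABLE[type_ids]]
  ne <- length(eatables)
  if (!length(cg$trays)) {
    ## fast path: food-only cages (1 other + n_f eat candidates)
    return(list(
      kinds = c("other", rep("eat", ne)),
      foods = c(NA_integer_, eatables),
      trays = rep(NA_character_, ne + 1L),
      prefs = c(p$p_other,
                if (ne) pmin(1, pmax(0, p$v_eat[eatables] * h[eatables] +
                                          p$eta_eat)))))
  }
  open <- Filter(function(tr) tr$open, cg$trays)
  kinds <- "other"; foods <- NA_integer_; trays <- NA_character_
  prefs <- p$p_other
  if (ne) {
    kinds <- c(kinds, rep("eat", ne))
    foods <- c(foods, eatables)
    trays <- c(trays, rep(NA_character_, ne))
    prefs <- c(prefs, sigma_clip(p$v_eat[eatables] * h[eatables] + p$eta_eat))
  }
  cacheables <- type_ids[.CACHEABLE[type_ids]]
  for (tr in open) {
    feats <- tray_features(tr)
    if (length(cacheables)) {
      wterm <- if (b$variant == "planning_by_replay") {
        vapply(cacheables, function(f)
          replay_caching_weight(b$replay, .FOOD_NAMES[f], tr$appearance, p), 0)
      } else if (b$lesion_plasticity) {
        rep(0, length(cacheables))
      } else {
        b$wc[cacheables, feats[1L]] + b$wc[cacheables, feats[2L]]
      }
      mot <- switch(b$caching_mode,
        hunger_modulated = p$v_cache[cacheables] * h[cacheables],
        unmodulated = 0,
        caching_modulated = p$v_cache[cacheables] * b$mot$c[cacheables])
      kinds <- c(kinds, rep("cache", length(cacheables)))
      foods <- c(foods, cacheables)
      trays <- c(trays, rep(tr$id, length(cacheables)))
      prefs <- c(prefs, sigma_clip(wterm + mot + p$eta_cache))
    }
    rec <- if (b$lesion_memory) NULL else recall_core(b$mem, feats, t)
    kinds <- c(kinds, "inspect")
    foods <- c(foods, NA_integer_)
    trays <- c(trays, tr$id)
    prefs <- c(prefs, inspect_pref_core(rec, b$mem$v, h, p))
  }
  list(kinds = kinds, foods = foods, trays = trays, prefs = prefs)
}

## batched rejection-sampling loop (statistically identical to
## select_action, cheaper in the event loop)
select_candidate <- function(prefs) {
  n <- length(prefs)
  cap <- 10L * n
  it <- 0L
  while (it < cap) {
    m <- min(16L, cap - it)
    is <- sample.int(n, m, replace = TRUE)
    acc <- which(prefs[is] > runif(m))
    if (length(acc)) {
      return(list(index = is[acc[1L]], iterations = it + acc[1L],
                  degenerate = FALSE))
    }
    it <- it + m
  }
  list(index = NA_integer_, iterations = cap, degenerate = TRUE)
}

## execute one decision of bird b at time t; returns the post-action
## time-out in seconds
bird_decision <- function(b, cg, t, log_events = TRUE) {
  cand <- enumerate_candidates(b, cg, t)
  sel <- select_candidate(cand$prefs)
  if (sel$degenerate) {
    sel$index <- match("other", cand$kinds)
    sel$wait_s <- 1
  } else {
    sel$wait_s <- runif(1L, 1, b$delta_by_kind[[cand$kinds[sel$index]]])
  }
  i <- sel$index
  kind <- cand$kinds[i]
  f <- cand$foods[i]
  food <- if (is.na(f)) NA_character_ else .FOOD_NAMES[f]
  outcome <- NA_character_
  switch(kind,
    eat = {
      loose_take_one(cg, f)
      cg$n_eaten <- cg$n_eaten + 1L
      cg$eaten_by_type[f] <- cg$eaten_by_type[f] + 1L
      if (!b$lesion_motivation) b$mot$s[f] <- b$mot$s[f] + b$params$n[f]
    },
    cache = {
      tr <- cg$trays[[cand$trays[i]]]
      fr <- loose_take_one(cg, f)
      tr$it_type <- c(tr$it_type, f)
      tr$it_fresh <- c(tr$it_fresh, fr)
      tr$it_time <- c(tr$it_time, t)
      tr$it_amount <- c(tr$it_amount, 1L)
      cg$trays[[tr$id]] <- tr
      feats <- tray_features(tr)
      if (!b$lesion_memory) encode_caching_event(b$mem, food, feats, t)
      if (b$caching_mode == "caching_modulated" && !b$lesion_motivation) {
        b$mot <- on_cache(b$mot, food, b$params)
      }
      if (b$variant == "planning_by_replay") {
        b$replay <- record_interaction(b$replay, tr$appearance, b$mot$h,
                                       "not_inspected", t)
      }
      b$trays_touched <- union(b$trays_touched, tr$id)
    },
    inspect = {
      tr <- cg$trays[[cand$trays[i]]]
      feats <- tray_features(tr)
      rec <- if (b$lesion_memory) NULL else recall_core(b$mem, feats, t)
      rows <- which(tr$it_amount > 0L)
      if (length(rows)) {
        j <- if (length(rows) == 1L) rows else
          rows[sample.int(length(rows), 1L, prob = tr$it_amount[rows])]
        fresh <- tr$it_fresh[j] > 0
        got_f <- tr$it_type[j]
        tr$it_amount[j] <- tr$it_amount[j] - 1L
        cg$trays[[tr$id]] <- tr
        if (fresh) {
          outcome <- "fresh_food_item"
          loose_add(cg, got_f, tr$it_fresh[j], 1L)
        } else {
          outcome <- "degraded_food_item"
          cg$n_discarded <- cg$n_discarded + 1L
        }
        food <- .FOOD_NAMES[got_f]
      } else {
        outcome <- "pilfered"
      }
      observer_log_retrieve(cg, tr, t)
      if (!b$lesion_memory) {
        if (outcome != "pilfered" && !is.null(rec)) {
          gid <- food_type_id(food)
          phi_fresh <- as.numeric(outcome == "fresh_food_item")
          for (r in which(rec$food_id == gid)) {
            update_readout(b$mem, food, rec$layer[r], phi_fresh,
                           b$params$alpha_fresh)
          }
        }
        on_inspection(b$mem, feats, t)
      }
      if (b$variant == "plastic_caching" && !is.null(rec)) {
        h <- b$mot$h
        for (r in seq_along(rec$food_id)) {
          rf <- rec$food_id[r]
          p_eat <- sigma_clip(b$params$v_eat[rf] * h[rf] + b$params$eta_eat)
          b$wc <- apply_retrieval_outcome(b$wc, .FOOD_NAMES[rf], feats,
                                          outcome, p_eat, b$params)
        }
      }
      if (b$variant == "planning_by_replay") {
        b$replay <- record_interaction(b$replay, tr$appearance, b$mot$h,
                                       outcome, t)
      }
      b$trays_touched <- union(b$trays_touched, tr$id)
    },
    other = NULL)
  if (log_events) {
    log_event(b, t, kind, food, cand$trays[i], outcome,
              cand$prefs[i], sel$iterations)
  }
  sel$wait_s
}


## specialized wait loop for the common fitting case: one bird, no trays,
## no maintenance diet, no caching-motivation bookkeeping, no event log
## and no consolidation tick inside the interval.  Local copies of the
## motivational state avoid per-decision environment dispatch; the RNG
## call sequence is identical to the general loop, so results match the
## general path bit for bit.
fast_wait_foodonly <- function(b, cg, t_end, nxt) {
  p <- b$params
  mot_s <- b$mot$s; mot_h <- b$mot$h
  tau_s <- p$tau_s; tau_d <- p$tau_d; tau_h <- p$tau_h
  v_eat <- p$v_eat; eta <- p$eta_eat; p_other <- p$p_other
  nvals <- p$n
  lesion_mot <- b$lesion_motivation
  tiny_d <- tau_d <= .Machine$double.eps
  delta_other <- p$delta_other; delta_eat <- p$delta_eat
  t <- b$t
  by_type <- cg$lf_by_type
  repeat {
    if (!any(by_type > 0L) || nxt > t_end) break
    dt <- nxt - t
    if (!lesion_mot && dt > 0) {
      t1 <- mot_s * tau_s
      t1[t1 > dt] <- dt
      mot_h <- if (tiny_d) mot_h * (t1 <= 0) else mot_h * exp(-t1 / tau_d)
      mot_h <- 1 - (1 - mot_h) * exp(-(dt - t1) / tau_h)
      mot_s <- mot_s - dt / tau_s
      mot_s[mot_s < 0] <- 0
    }
    t <- nxt
    type_ids <- which(by_type > 0L)
    eatables <- type_ids[.EATABLE[type_ids]]
    prefs <- c(p_other,
               pmin(1, pmax(0, v_eat[eatables] * mot_h[eatables] + eta)))
    sel <- select_candidate(prefs)
    if (sel$degenerate) {
      ws <- 1
    } else if (sel$index == 1L) {
      ws <- runif(1L, 1, delta_other)
    } else {
      f <- eatables[sel$index - 1L]
      loose_take_one(cg, f)
      by_type <- cg$lf_by_type
      cg$n_eaten <- cg$n_eaten + 1L
      cg$eaten_by_type[f] <- cg$eaten_by_type[f] + 1L
      if (!lesion_mot) mot_s[f] <- mot_s[f] + nvals[f]
      ws <- runif(1L, 1, delta_eat)
    }
    nxt <- t + ws / 60
  }
  b$mot$s <- mot_s
  b$mot$h <- mot_h
  b$t <- t
  invisible(b)
}

#' Let simulated birds behave for a number of minutes
#'
#' Advances the cage clock by `minutes`, running each bird's
#' decide-act-wait loop: an action, then a uniform time-out from
#' `[1, delta_kind]` seconds, then the next decision.  When no food item
#' and no open caching tray is available, no events are simulated and only
#' the continuous dynamics (stomach, hunger, caching motivation,
#' consolidation clock) advance.
#'
#' @param cg a [cage()].
#' @param birds a single bird or list of birds sharing the cage.
#' @param minutes positive duration in minutes.
#' @param log_events record per-event rows retrievable via [bird_events()].
#' @return The cage, invisibly.
#' @export
cage_wait <- function(cg, birds, minutes, log_events = TRUE) {
  if (minutes <= 0) stop("wait duration must be positive", call. = FALSE)
  if (inherits(birds, "bird")) birds <- list(birds)
  t_end <- cg$clock + minutes
  for (b in birds) {
    if (is.na(b$t)) b$t <- cg$clock
    if (is.null(b$trays_touched)) b$trays_touched <- character()
    if (is.null(b$next_tick) || is.na(b$next_tick)) {
      b$next_tick <- next_tick_time(b$mem, b$t)
    }
  }
  wait_touch <- lapply(birds, function(b) b$trays_touched)
  nxt <- vapply(birds, function(b)
    cg$clock + runif(1L, 1, b$params$delta_other) / 60, 0)
  if (length(birds) == 1L && !log_events && length(cg$trays) == 0L &&
      !cg$maintenance_diet && birds[[1L]]$next_tick > t_end &&
      birds[[1L]]$caching_mode != "caching_modulated") {
    b <- birds[[1L]]
    fast_wait_foodonly(b, cg, t_end, nxt[1L])
    advance_bird(b, cg, t_end)
    cg$clock <- t_end
    return(invisible(cg))
  }
  while (cage_relevant(cg)) {
    i <- which.min(nxt)
    t <- nxt[i]
    if (t > t_end) break
    advance_bird(birds[[i]], cg, t)
    cg$clock <- t
    ws <- bird_decision(birds[[i]], cg, t, log_events)
    nxt[i] <- t + ws / 60
  }
  for (b in birds) advance_bird(b, cg, t_end)
  cg$clock <- t_end
  ## replay model: open trays perceived during this wait but never
  ## interacted with are remembered as not_inspected
  for (k in seq_along(birds)) {
    b <- birds[[k]]
    if (b$variant != "planning_by_replay") next
    touched_now <- setdiff(b$trays_touched, wait_touch[[k]])
    for (tr in cg$trays) {
      if (tr$open && !(tr$id %in% touched_now)) {
        b$replay <- record_interaction(b$replay, tr$appearance, b$mot$h,
                                       "not_inspected", t_end)
      }
    }
  }
  invisible(cg)
}
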
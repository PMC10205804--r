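## Motivational control: per-food stomach s_f, hunger h_f and (variant)
## caching-motivation c_f, propagated exactly between events.
##
## Between events the dynamics are piecewise linear/exponential:
##   ds_f/dt = -1/tau_s                 while s_f > 0
##   dh_f/dt = -h_f/tau_d               while s_f > 0  (digestion)
##   dh_f/dt = (1 - h_f)/tau_h          once  s_f = 0  (appetite growth)
##   tau_d dc_f/dt = 1 - c_f            (relaxation toward 1)
## Each eating event adds the nutritional value n_f to s_f; each caching
## event (caching-modulated variant) depletes c_f by c_f * c0 / tau_d.

#' Motivational state
#'
#' @param s,h,c numeric vectors of length 11 (one entry per food type):
#'   stomach content (>= 0), hunger in `[0, 1]` and caching motivation in
#'   `[0, 1]`.
#' @param h0 scalar used to fill `h` when not supplied.
#' @return A `motivation_state` list.
#' @export
motivation_state <- function(s = rep(0, .NF), h = rep(h0, .NF),
                             c = rep(1, .NF), h0 = 0.5) {
  stopifnot(length(s) == .NF, length(h) == .NF, length(c) == .NF,
            all(s >= 0), all(h >= 0), all(h <= 1), all(c >= 0), all(c <= 1))
  structure(list(s = s, h = h, c = c), class = "motivation_state")
}

#' Propagate motivational state over an event-free interval
#'
#' Closed-form piecewise-exact update: the stomach empties linearly at rate
#' `1/tau_s`; hunger decays exponentially (time constant `tau_d`) while the
#' stomach is non-empty and relaxes toward 1 (time constant `tau_h`) once it
#' is empty; the stomach-empty switch time `s_f * tau_s` is handled inside
#' the interval.  Caching motivation relaxes toward 1 with time constant
#' `tau_d`.  With a maintenance diet, hunger is integrated as if `s_f > 0`
#' for all foods.
#'
#' @param state a [motivation_state()].
#' @param dt duration in minutes (>= 0).
#' @param params a parameter list with `tau_s`, `tau_d`, `tau_h` (see
#'   [bird_parameters()]).
#' @param maintenance_diet logical.
#' @return The propagated `motivation_state`.
#' @examples
#' p <- default_bird_parameters()
#' propagate(motivation_state(s = rep(1, 11), h0 = 0.8), 20, p)
#' @export
propagate <- function(state, dt, params, maintenance_diet = FALSE) {
  if (dt < 0) stop("negative time step", call. = FALSE)
  if (dt == 0) return(state)
  out <- propagate_core(state, dt, params, maintenance_diet)
  motivation_state(s = out$s, h = pmin(1, pmax(0, out$h)),
                   c = pmin(1, pmax(0, out$c)))
}

## allocation-lean core shared with the event loop: no validation, no
## class; the caching-motivation relaxation is skipped unless the
## caching-modulated variant actually reads it (c stays at 1 otherwise)
propagate_core <- function(state, dt, p, maintenance_diet,
                           update_c = TRUE) {
  s <- state$s; h <- state$h
  tiny_d <- p$tau_d <= .Machine$double.eps
  if (maintenance_diet) {
    h <- if (tiny_d) h * 0 else h * exp(-dt / p$tau_d)
  } else {
    t1 <- s * p$tau_s                   # time with non-empty stomach
    t1[t1 > dt] <- dt
    h <- if (tiny_d) h * (t1 <= 0) else h * exp(-t1 / p$tau_d)
    h <- 1 - (1 - h) * exp(-(dt - t1) / p$tau_h)
  }
  s <- s - dt / p$tau_s
  s[s < 0] <- 0
  cc <- if (update_c) {
    fac_d <- if (tiny_d) 0 else exp(-dt / p$tau_d)
    1 - (1 - state$c) * fac_d
  } else state$c
  list(s = s, h = h, c = cc)
}

## exp(-t/tau) with the tau -> 0 limit (instantaneous relaxation)
relax_factor <- function(t, tau) {
  ifelse(t <= 0, 1, if (tau <= .Machine$double.eps) 0 else exp(-t / tau))
}

decay_h <- function(h, t, tau_d) {
  h * relax_factor(t, tau_d)
}

#' Register an eating event
#'
#' Adds the food's nutritional value to the matching stomach variable;
#' hunger for other foods is untouched (specific satiety).
#'
#' @inheritParams propagate
#' @param food_type a food type name.
#' @return Updated `motivation_state`.
#' @export
on_eat <- function(state, food_type, params) {
  if (!food_eatable(food_type)) {
    stop("'", food_type, "' is not eatable", call. = FALSE)
  }
  f <- food_type_id(food_type)
  state$s[f] <- state$s[f] + params$n[f]
  state
}

#' Register a caching event (caching-modulated variant)
#'
#' Depletes the caching-motivation variable by `c_f * c0 / tau_d`, clipped
#' at zero.  With no caching, `c_f` relaxes back toward 1 with time constant
#' `tau_d` (see [propagate()]).
#'
#' @inheritParams on_eat
#' @return Updated `motivation_state`.
#' @export
on_cache <- function(state, food_type, params) {
  f <- food_type_id(food_type)
  dep <- if (params$tau_d <= .Machine$double.eps) 1 else params$c0 / params$tau_d
  state$c[f] <- max(0, state$c[f] * (1 - dep))
  state
}

#' Hunger threshold crossing times
#'
#' Exact times within `[0, dt]` at which each hunger variable crosses the
#' threshold `theta`, computed from the closed-form pieces (downward during
#' digestion, upward during appetite growth).
#'
#' @inheritParams propagate
#' @param theta threshold in (0, 1).
#' @return A list (one element per food type) of data frames with columns
#'   `time` (minutes) and `direction` (+1 upward, -1 downward).
#' @export
hunger_crossing_times <- function(state, dt, theta, params,
                                  maintenance_diet = FALSE) {
  stopifnot(theta > 0, theta < 1, dt >= 0)
  lapply(seq_len(.NF), function(f) {
    cr <- data.frame(time = numeric(), direction = numeric())
    h0 <- state$h[f]
    t1 <- if (maintenance_diet) dt else min(dt, state$s[f] * params$tau_s)
    ## digestion piece: h(t) = h0 exp(-t/tau_d), may cross downward
    if (h0 > theta && t1 > 0) {
      td <- if (params$tau_d <= .Machine$double.eps) 0 else
        -params$tau_d * log(theta / h0)
      if (td <= t1) cr <- rbind(cr, data.frame(time = td, direction = -1))
    }
    h1 <- decay_h(h0, t1, params$tau_d)
    ## appetite piece: h(t) = 1 - (1 - h1) exp(-(t - t1)/tau_h), upward
    if (t1 < dt && h1 < theta) {
      tu <- t1 + params$tau_h * log((1 - h1) / (1 - theta))
      if (tu <= dt) cr <- rbind(cr, data.frame(time = tu, direction = 1))
    }
    cr
  })
}

#' Time spent above the hunger threshold
#'
#' Total duration within `[0, dt]` during which each hunger variable exceeds
#' `theta`; drives the hunger-gated growth of caching weights.
#'
#' @inheritParams hunger_crossing_times
#' @return Numeric vector (minutes) of length 11.
#' @export
hungry_time <- function(state, dt, theta, params, maintenance_diet = FALSE) {
  h0 <- state$h
  t1 <- if (maintenance_diet) rep(dt, .NF) else pmin(dt, state$s * params$tau_s)
  ## digestion piece: above threshold until the downward crossing
  tA <- numeric(.NF)
  above0 <- h0 > theta
  if (any(above0)) {
    td <- if (params$tau_d <= .Machine$double.eps) 0 else
      params$tau_d * log(h0[above0] / theta)
    tA[above0] <- pmin(t1[above0], td)
  }
  ## appetite piece: above threshold after the upward crossing
  h1 <- decay_h(h0, t1, params$tau_d)
  trem <- dt - t1
  tB <- ifelse(h1 > theta, trem,
               pmax(0, trem - params$tau_h * log((1 - h1) / (1 - theta))))
  tA + tB
}

#' Motivational trajectory as a tibble
#'
#' Samples the closed-form dynamics on a regular grid (no events), mainly
#' for plotting.
#'
#' @inheritParams propagate
#' @param times increasing vector of times (minutes) starting at 0.
#' @return A tibble with columns `time`, `food_type`, `s`, `h`, `c`.
#' @export
motivation_trajectory <- function(state, times, params,
                                  maintenance_diet = FALSE) {
  rows <- lapply(times, function(t) {
    st <- propagate(state, t, params, maintenance_diet)
    tibble::tibble(time = t, food_type = food_types(),
                   s = st$s, h = st$h, c = st$c)
  })
  dplyr::bind_rows(rows)
}
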
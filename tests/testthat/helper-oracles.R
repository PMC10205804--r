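# Independent oracles used across the suite: dense-time forward-Euler
# integration of the motivational dynamics and the gated caching-weight
# growth, plus small brute-force reimplementations for the replay search.

# Forward-Euler integration of the stomach/hunger/caching-motivation
# dynamics for a single food type, with eat/cache events snapped to the
# grid.  Returns the state at the requested checkpoint times.
euler_motivation_1d <- function(s0, h0, c0, tau_s, tau_d, tau_h, c0_dep = 0,
                                n_val = 0.3, events = NULL, dt = 0.01,
                                total = 1440, checkpoints = total,
                                maintenance = FALSE) {
  steps <- round(total / dt)
  ev_step <- if (is.null(events)) integer() else round(events$time / dt)
  s <- s0; h <- h0; cc <- c0
  out <- matrix(NA_real_, length(checkpoints), 3L,
                dimnames = list(NULL, c("s", "h", "c")))
  cp_step <- round(checkpoints / dt)
  for (k in seq_len(steps)) {
    if (length(ev_step)) {
      hit <- which(ev_step == k - 1L)
      for (e in hit) {
        if (events$kind[e] == "eat") s <- s + n_val
        else cc <- max(0, cc * (1 - c0_dep / tau_d))
      }
    }
    nonempty <- maintenance || s > 0
    h <- h + dt * (if (nonempty) -h / tau_d else (1 - h) / tau_h)
    s <- max(0, s - dt / tau_s * (s > 0))
    cc <- cc + dt * (1 - cc) / tau_d
    hit <- which(cp_step == k)
    if (length(hit)) out[hit, ] <- c(s, h, cc)
  }
  out
}

# Forward-Euler oracle of the hunger-gated caching-weight growth (one food,
# one perceived feature), integrated jointly with the hunger dynamics.
euler_gated_growth <- function(s0, h0, w0, tau_s, tau_d, tau_h, tau_hungry,
                               theta = 0.99, dt_s = 0.1, total_min = 1440) {
  dtm <- dt_s / 60
  steps <- round(total_min / dtm)
  s <- s0; h <- h0; w <- w0
  for (k in seq_len(steps)) {
    nonempty <- s > 0
    gate <- h > theta
    w <- w + dtm * gate * (1 - w) / tau_hungry
    h <- h + dtm * (if (nonempty) -h / tau_d else (1 - h) / tau_h)
    s <- max(0, s - dtm / tau_s * nonempty)
  }
  c(h = h, w = w)
}

# Brute-force replay-index search: explicit double loop with truncation at
# the history start, counting exact tray-sequence matches over the 3-item
# context window.
brute_replay_indices <- function(rm) {
  I <- length(rm$items)
  if (I < 2L) return(integer())
  counts <- integer(I - 1L)
  for (i in seq_len(I - 1L)) {
    n <- 0L
    for (k in 0:2) {
      if (i - k < 1L || I - k < 1L) next
      xa <- rm$items[[I - k]]$x
      xb <- rm$items[[i - k]]$x
      if (length(xa) == length(xb) && all(xa == xb)) n <- n + 1L
    }
    counts[i] <- n
  }
  if (max(counts) == 0L) return(integer())
  which(counts == max(counts))
}

# A deterministic test population: template parameters tuned so that all
# three fixture mechanisms express clearly.
fixture_params <- function(...) {
  cachesim::bird_parameters(...)
}

make_group <- function(n, variant = "plastic_caching",
                       params = fixture_params(), prefix = "b",
                       caching_mode = "hunger_modulated") {
  lapply(seq_len(n), function(i) {
    cachesim::make_bird(variant, params, caching_mode,
                        id = paste0(prefix, i))
  })
}

fixture_birds <- function(proto, variant = "plastic_caching",
                          params = fixture_params()) {
  birds <- lapply(names(proto$groups), function(g) {
    make_group(proto$groups[[g]], variant, params, prefix = g)
  })
  names(birds) <- names(proto$groups)
  birds
}
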
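## Simulated birds: parameter container, model variants and lesions.

#' Allowed ranges of the bird parameters
#'
#' Manually set box constraints for every per-bird constant.  Per-food
#' parameters (`n`, `v_eat`, `v_cache`) share one range across food types.
#' Replay-model parameters without published ranges get wide boxes.
#'
#' @return A tibble with columns `name`, `min`, `max`, `per_food`.
#' @export
parameter_ranges <- function() {
  tibble::tribble(
    ~name,            ~min,  ~max,  ~per_food,
    "tau_s",           0.5,   10.0, FALSE,  # stomach time constant (min)
    "tau_d",           0.0,   20.0, FALSE,  # digestion time constant (min)
    "tau_h",          50.0,  300.0, FALSE,  # appetite increase (min)
    "n",               0.1,    1.0, TRUE,   # nutritional value
    "v_eat",           0.1,    1.0, TRUE,   # eating preferences
    "v_cache",         0.0,    1.0, TRUE,   # caching preferences
    "eta_eat",        -1.0,    1.0, FALSE,  # eating bias
    "eta_inspect",    -2.0,    0.5, FALSE,  # inspection bias
    "s_inspect",       0.0,    5.0, FALSE,  # inspection preference slope
    "eta_cache",      -1.0,    1.0, FALSE,  # caching bias
    "alpha_fresh",     0.0,    1.0, FALSE,  # freshness learning rate
    "alpha_reward",    0.0,    0.9, FALSE,  # retrieval reward rate (unused)
    "alpha_pilfer",    0.0,    0.2, FALSE,  # pilfer learning rate
    "alpha_degrade",   0.0,    0.2, FALSE,  # degradation learning rate
    "tau_hungry",    100.0,  500.0, FALSE,  # hunger-caching time constant
    "w0_cache",        0.0,    1.0, FALSE,  # initial caching weights
    "delta_eat",      10.0,  200.0, FALSE,  # time-outs (seconds)
    "delta_inspect",  10.0,  200.0, FALSE,
    "delta_cache",    10.0,  200.0, FALSE,
    "delta_other",    10.0,  200.0, FALSE,
    "p_other",         0.0,    1.0, FALSE,  # other-action preference
    "c0",              0.0,    1.0, FALSE,  # caching-motivation depletion
    "alpha_hunger",    0.0,    1.0, FALSE,  # replay: hunger term
    "alpha_fresh_r",   0.0,    2.0, FALSE,  # replay: fresh bonus
    "alpha_degrade_r", 0.0,    2.0, FALSE,  # replay: degraded penalty
    "alpha_pilfer_r",  0.0,    2.0, FALSE,  # replay: pilfer penalty
    "gamma_replay",    0.0,    1.0, FALSE)  # replay discount factor
}

#' Bird parameter container
#'
#' Builds a full parameter list from named arguments; per-food parameters
#' accept either a scalar (recycled over the 11 food types) or a named
#' vector keyed by food type.  Values are validated against
#' [parameter_ranges()].
#'
#' @param ... named parameter values overriding the defaults of
#'   [default_bird_parameters()].
#' @param base parameter list to start from.
#' @return A named list of class `bird_parameters`.
#' @export
bird_parameters <- function(..., base = default_bird_parameters()) {
  upd <- list(...)
  rng <- parameter_ranges()
  for (nm in names(upd)) {
    if (nm %in% c("theta_replay", "similarity_outcome_sign", "h0")) {
      base[[nm]] <- upd[[nm]]
      next
    }
    row <- rng[rng$name == nm, ]
    if (!nrow(row)) stop("unknown parameter '", nm, "'", call. = FALSE)
    val <- upd[[nm]]
    if (row$per_food) {
      v <- base[[nm]]
      if (!is.null(names(val))) {
        v[food_type_id(names(val))] <- unname(val)
      } else if (length(val) == 1L) {
        v[] <- val
      } else {
        stopifnot(length(val) == .NF)
        v <- val
      }
      val <- v
    }
    if (any(val < row$min - 1e-9) || any(val > row$max + 1e-9)) {
      stop("parameter '", nm, "' outside its allowed range [",
           row$min, ", ", row$max, "]", call. = FALSE)
    }
    base[[nm]] <- val
  }
  class(base) <- "bird_parameters"
  base
}

#' Hand-tuned default bird parameters
#'
#' A plausible all-round parameter set used by the protocol fixtures and
#' examples (see the methods vignette for the reasoning): moderate appetite
#' dynamics, clear eating/caching drives and learning rates strong enough
#' that two retrieval experiences visibly change behavior.
#'
#' @return A `bird_parameters` list.
#' @export
default_bird_parameters <- function() {
  structure(list(
    tau_s = 3, tau_d = 10, tau_h = 120,
    n = rep(0.3, .NF),
    v_eat = rep(0.7, .NF),
    v_cache = rep(0.5, .NF),
    eta_eat = 0, eta_inspect = -0.6, s_inspect = 0.5, eta_cache = -0.3,
    alpha_fresh = 0.8, alpha_reward = 0, alpha_pilfer = 0.2,
    alpha_degrade = 0.2, tau_hungry = 300, w0_cache = 0.15,
    delta_eat = 60, delta_inspect = 60, delta_cache = 60, delta_other = 90,
    p_other = 0.3, c0 = 0.5,
    alpha_hunger = 0.3, alpha_fresh_r = 0.8, alpha_degrade_r = 0.8,
    alpha_pilfer_r = 0.8, gamma_replay = 0.8,
    theta_replay = 0.99, similarity_outcome_sign = "as_printed",
    h0 = 0.5), class = "bird_parameters")
}

.VARIANTS <- c("plastic_caching", "planning_by_replay", "no_plasticity",
               "no_plasticity_no_memory",
               "no_plasticity_no_memory_no_motivation")
.CACHING_MODES <- c("hunger_modulated", "unmodulated", "caching_modulated")
.THETA_HUNGRY <- 0.99 # fixed gate threshold of the presynaptic growth term

#' Create a simulated bird
#'
#' Wires the motivation, memory, plasticity and (for the replay variant)
#' planning modules into one agent.  Lesioned variants keep the lesioned
#' state variables at zero at all times: `no_plasticity` zeroes the caching
#' weights, `no_plasticity_no_memory` additionally zeroes the memory
#' activations, and the triple lesion additionally zeroes hunger, leaving
#' constant eat/cache/inspect probabilities.
#'
#' @param variant model variant tag, one of `"plastic_caching"`,
#'   `"planning_by_replay"`, `"no_plasticity"`,
#'   `"no_plasticity_no_memory"`,
#'   `"no_plasticity_no_memory_no_motivation"`.
#' @param params a [bird_parameters()] list.
#' @param caching_mode motivational variant of the caching preference.
#' @param id bird identifier used in event logs.
#' @return A `bird` environment.
#' @examples
#' b <- make_bird("plastic_caching", default_bird_parameters())
#' @export
make_bird <- function(variant = "plastic_caching",
                      params = default_bird_parameters(),
                      caching_mode = "hunger_modulated",
                      id = "bird") {
  if (!variant %in% .VARIANTS) {
    stop("unknown variant '", variant, "'; valid tags: ",
         paste(.VARIANTS, collapse = ", "), call. = FALSE)
  }
  caching_mode <- match.arg(caching_mode, .CACHING_MODES)
  b <- new.env(parent = emptyenv())
  b$id <- id
  b$variant <- variant
  b$caching_mode <- caching_mode
  b$params <- params
  b$lesion_plasticity <- variant %in% c("no_plasticity",
                                        "no_plasticity_no_memory",
                                        "no_plasticity_no_memory_no_motivation")
  b$lesion_memory <- variant %in% c("no_plasticity_no_memory",
                                    "no_plasticity_no_memory_no_motivation")
  b$lesion_motivation <- variant == "no_plasticity_no_memory_no_motivation"
  h0 <- if (b$lesion_motivation) 0 else params$h0
  b$mot <- motivation_state(h0 = h0)
  b$mem <- memory_state()
  b$wc <- caching_weights(if (b$lesion_plasticity) 0 else params$w0_cache)
  b$replay <- replay_memory()
  b$t <- NA_real_   # time of last continuous update
  b$next_tick <- NA_real_
  b$delta_by_kind <- list(eat = params$delta_eat, cache = params$delta_cache,
                          inspect = params$delta_inspect,
                          other = params$delta_other)
  b$events <- list()
  b$n_events <- 0L
  class(b) <- c("bird", class(b))
  b
}

#' @export
print.bird <- function(x, ...) {
  cat("<bird ", x$id, "> variant=", x$variant, ", caching=", x$caching_mode,
      ", ", x$n_events, " events\n", sep = "")
  invisible(x)
}

#' Event log of a bird
#'
#' @param bird a [make_bird()] bird.
#' @return A tibble with one row per event: `bird`, `time` (min), `action`,
#'   `food_type`, `tray`, `outcome`, `preference`, `iterations`.
#' @export
bird_events <- function(bird) {
  if (!bird$n_events) {
    return(tibble::tibble(bird = character(), time = numeric(),
                          action = character(), food_type = character(),
                          tray = character(), outcome = character(),
                          preference = numeric(), iterations = integer()))
  }
  dplyr::bind_rows(bird$events[seq_len(bird$n_events)])
}
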
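## What-where-when associative memory: a 7-layer hetero-associative network
## with nightly systems consolidation.  Each caching event grows a
## consolidation counter on layer 1 for the (food, tray-feature) synapses;
## the effective binary weight switches on one hour later.  A nightly tick
## advances every trace (at least one hour old) one step along the dwell
## schedule 1,1,1,1,3,8 days, so the layer holding an active neuron codes
## the age of the memory: [0,1), [1,2), [2,3), [3,4), [4,7), [7,15),
## [15,Inf) days for layers 1..7.
##
## Representation: at most one trace lives per (food, feature) pair (the
## one-hot-in-time code), so a trace is fully described by its counter, its
## creation time and the number of consolidation ticks it has seen.

.ENCODING_DELAY <- 60 # minutes until a fresh trace becomes effective

#' Create an empty memory state
#'
#' @param tick_time_of_day time of the nightly consolidation tick, minutes
#'   after midnight (default 240 = 04:00).
#' @param v0 initial readout weights; naive birds expect fresh food
#'   (default 1).
#' @return A `memory_state` environment with consolidation counters,
#'   trace metadata and a 7 x 11 readout-weight matrix.
#' @export
memory_state <- function(tick_time_of_day = 240, v0 = 1) {
  mem <- new.env(parent = emptyenv())
  mem$cnt <- matrix(0, .NF, .NX)       # consolidation counters w~
  mem$birth <- matrix(-Inf, .NF, .NX)  # time of (re)creation of the trace
  mem$ticks <- matrix(0L, .NF, .NX)    # consolidation steps experienced
  mem$v <- matrix(v0, 7L, .NF)         # readout weights v^(l)_f
  mem$tick_tod <- tick_time_of_day
  mem$last_tick_day <- -Inf
  class(mem) <- c("memory_state", class(mem))
  mem
}

#' Map consolidation tick counts to layers
#'
#' @param k integer vector of nightly ticks experienced.
#' @return Integer layer indices in 1..7.
#' @export
layer_of_ticks <- function(k) {
  ifelse(k <= 3L, k + 1L, ifelse(k <= 6L, 5L, ifelse(k <= 14L, 6L, 7L)))
}

#' Layer holding a memory of a given age
#'
#' Pure helper mapping a memory age (in days) to the sub-network that holds
#' it under the consolidation schedule with dwell times 1, 1, 1, 1, 3 and 8
#' days for layers 1..6 (layer 7 is terminal).
#'
#' @param age_days numeric vector of ages in days.
#' @return Integer layer indices in 1..7.
#' @examples
#' age_to_layer(c(0.5, 1, 3.9, 5, 20))
#' @export
age_to_layer <- function(age_days) {
  stopifnot(all(age_days >= 0))
  findInterval(age_days, c(0, 1, 2, 3, 4, 7, 15))
}

#' Encode a caching event
#'
#' Increments the layer-1 consolidation counters of both tray-feature
#' synapses (appearance and position) for the cached food.  The effective
#' weight follows one hour later.  Re-caching at a site whose trace already
#' sits in a deeper layer deletes that trace and restarts a fresh one in
#' layer 1.
#'
#' @param mem a [memory_state()].
#' @param food_type food type name.
#' @param features integer feature indices of the tray (see the two-hot
#'   tray code), typically from a tray's appearance and position.
#' @param t event time in minutes.
#' @return The memory state, invisibly (modified in place).
#' @export
encode_caching_event <- function(mem, food_type, features, t) {
  f <- food_type_id(food_type)
  for (x in features) {
    if (mem$cnt[f, x] > 0 && mem$ticks[f, x] > 0L) {
      ## old trace in a deeper layer: replaced by a new layer-1 trace
      mem$cnt[f, x] <- 1
      mem$ticks[f, x] <- 0L
      mem$birth[f, x] <- t
    } else if (mem$cnt[f, x] > 0) {
      mem$cnt[f, x] <- mem$cnt[f, x] + 1
    } else {
      mem$cnt[f, x] <- 1
      mem$ticks[f, x] <- 0L
      mem$birth[f, x] <- t
    }
  }
  invisible(mem)
}

#' Nightly consolidation tick
#'
#' Advances every trace that is at least one hour old by one consolidation
#' step.  Must be called once per simulated day (at the tick time of day);
#' a double tick for the same day is an error.
#'
#' @param mem a [memory_state()].
#' @param t tick time in minutes.
#' @return The memory state, invisibly.
#' @export
consolidate <- function(mem, t) {
  day <- floor(t / 1440)
  if (day <= mem$last_tick_day) {
    stop("consolidation already ticked for day ", day, call. = FALSE)
  }
  mem$last_tick_day <- day
  adv <- mem$cnt > 0 & (t - mem$birth) >= .ENCODING_DELAY
  mem$ticks[adv] <- mem$ticks[adv] + 1L
  invisible(mem)
}

## traces with an effective (binary) weight at time t: counter positive and
## encoding delay elapsed
effective_traces <- function(mem, t) {
  mem$cnt > 0 & (t - mem$birth) >= .ENCODING_DELAY
}

#' Recall from tray features
#'
#' Perceiving an (open, present) caching tray activates its two feature
#' neurons; food-type memory neurons with an effective synapse from either
#' feature activate through the clipped-linear response.  With the two-hot
#' input and binary weights the activations are binary.
#'
#' @inheritParams encode_caching_event
#' @return A data frame with one row per active memory neuron: columns
#'   `food_id`, `layer`, `phi` (activation, always 1 here).
#' @export
recall <- function(mem, features, t) {
  rec <- recall_core(mem, features, t)
  if (is.null(rec)) {
    return(data.frame(food_id = integer(), layer = integer(),
                      phi = numeric()))
  }
  data.frame(food_id = rec$food_id, layer = rec$layer, phi = 1)
}

## allocation-lean recall: NULL when nothing is active, otherwise a list
## with deduplicated integer vectors food_id and layer (phi is 1)
recall_core <- function(mem, features, t) {
  f1 <- which(mem$cnt[, features[1L]] > 0 &
                (t - mem$birth[, features[1L]]) >= .ENCODING_DELAY)
  f2 <- which(mem$cnt[, features[2L]] > 0 &
                (t - mem$birth[, features[2L]]) >= .ENCODING_DELAY)
  if (!length(f1) && !length(f2)) return(NULL)
  fid <- c(f1, f2)
  lay <- layer_of_ticks(mem$ticks[cbind(fid, features[c(rep(1L, length(f1)),
                                                        rep(2L, length(f2)))])])
  ## one active (f, layer) pair per trace
  key <- fid * 8L + lay
  keep <- !duplicated(key)
  list(food_id = fid[keep], layer = as.integer(lay[keep]))
}

#' Register an actual inspection of a cache site
#'
#' Each inspection decrements the consolidation counters of all traces at
#' the inspected features by 1 (floored at 0); a counter that reaches zero
#' erases the trace, so sufficiently many inspections silence recall.
#'
#' @inheritParams encode_caching_event
#' @return The memory state, invisibly.
#' @export
on_inspection <- function(mem, features, t) {
  for (x in features) {
    f <- which(mem$cnt[, x] > 0)
    if (length(f)) {
      mem$cnt[f, x] <- pmax(0, mem$cnt[f, x] - 1)
      gone <- f[mem$cnt[f, x] == 0]
      if (length(gone)) {
        mem$ticks[gone, x] <- 0L
        mem$birth[gone, x] <- -Inf
      }
    }
  }
  invisible(mem)
}

#' Update a readout weight after a successful retrieval
#'
#' Delta rule toward the experienced freshness:
#' `v <- v + alpha * (phi_fresh - v)`.
#'
#' @param mem a [memory_state()].
#' @param food_type food type name.
#' @param layer layer index 1..7 that was recalled.
#' @param phi_fresh experienced freshness signal, 0 or 1.
#' @param alpha freshness learning rate in `[0, 1]`.
#' @return The memory state, invisibly.
#' @export
update_readout <- function(mem, food_type, layer, phi_fresh, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  f <- food_type_id(food_type)
  mem$v[layer, f] <- mem$v[layer, f] + alpha * (phi_fresh - mem$v[layer, f])
  invisible(mem)
}

#' Snapshot of the memory state
#'
#' @param mem a [memory_state()].
#' @param t current time in minutes (for effective layers).
#' @return A tibble with one row per stored trace: `food_type`, `feature`,
#'   `counter`, `layer`, `effective`.
#' @export
memory_snapshot <- function(mem, t) {
  ij <- which(mem$cnt > 0, arr.ind = TRUE)
  if (!nrow(ij)) {
    return(tibble::tibble(food_type = character(), feature = integer(),
                          counter = numeric(), layer = integer(),
                          effective = logical()))
  }
  tibble::tibble(
    food_type = food_types()[ij[, 1L]],
    feature = as.integer(ij[, 2L]),
    counter = mem$cnt[ij],
    layer = as.integer(layer_of_ticks(mem$ticks[ij])),
    effective = (t - mem$birth[ij]) >= .ENCODING_DELAY)
}

## next nightly tick strictly after time t
next_tick_time <- function(mem, t) {
  day <- floor((t - mem$tick_tod) / 1440)
  (day + 1) * 1440 + mem$tick_tod
}
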
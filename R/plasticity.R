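## Reward-modulated plasticity of the caching weights.  Two mechanisms:
## (1) a three-factor update at retrieval events (the recalled memory
## reactivates the pre/post neurons of the caching synapse; the outcome is
## the modulatory third factor), and (2) a slow hunger-gated presynaptic
## growth toward 1 while a tray feature is perceived and hunger for a food
## exceeds the 0.99 gate.

#' Initial caching-weight matrix
#'
#' @param w0 initial caching weight in `[0, 1]`.
#' @return An 11 x 64 matrix (food types x tray-feature indices).
#' @export
caching_weights <- function(w0 = 0) {
  stopifnot(w0 >= 0, w0 <= 1)
  matrix(w0, .NF, .NX)
}

#' Outcome-driven caching-weight update at retrieval
#'
#' After attempting to retrieve food of type `f` at a cache site (the
#' memory recall reactivates both feature synapses), the weights change by
#' `-alpha_pilfer * w` (pilfered), `-alpha_degrade * w` (degraded food) or
#' `+alpha_fresh * p_eat_f * (1 - w)` (fresh food), identically on the
#' appearance and the position weight.
#'
#' @param w caching-weight matrix from [caching_weights()].
#' @param food_type recalled food type.
#' @param features the tray's two feature indices.
#' @param outcome one of `"pilfered"`, `"degraded_food_item"`,
#'   `"fresh_food_item"`.
#' @param p_eat current eating preference for `food_type` (gates the
#'   positive update).
#' @param params a [bird_parameters()] list.
#' @return The updated weight matrix.
#' @examples
#' w <- caching_weights(0.8)
#' p <- default_bird_parameters()
#' p$alpha_pilfer <- 0.1
#' w2 <- apply_retrieval_outcome(w, "peanut", c(1, 33), "pilfered", 0, p)
#' w2[3, 1] # 0.72
#' @export
apply_retrieval_outcome <- function(w, food_type, features, outcome,
                                    p_eat, params) {
  f <- food_type_id(food_type)
  old <- w[f, features]
  w[f, features] <- switch(outcome,
    pilfered = old - params$alpha_pilfer * old,
    degraded_food_item = old - params$alpha_degrade * old,
    fresh_food_item = old + params$alpha_fresh * p_eat * (1 - old),
    stop("unknown retrieval outcome '", outcome, "'", call. = FALSE))
  w
}

#' Hunger-gated presynaptic growth of caching weights
#'
#' While hunger for food `f` exceeds the gate threshold and a tray feature
#' `x` is perceived, `w[f, x]` relaxes toward 1 with time constant
#' `tau_hungry`:  `w <- 1 - (1 - w) * exp(-t_active / tau_hungry)` where
#' `t_active` is the per-food time above threshold accumulated over the
#' interval (see [hungry_time()]).
#'
#' @param w caching-weight matrix.
#' @param features feature indices of the currently present open trays
#'   (may be empty: no growth without perceived trays).
#' @param t_active numeric vector (length 11) of gated minutes per food.
#' @param params a [bird_parameters()] list (field `tau_hungry`).
#' @return The updated weight matrix.
#' @export
grow_while_hungry <- function(w, features, t_active, params) {
  if (!length(features)) return(w)
  act <- which(t_active > 0)
  for (f in act) {
    w[f, features] <- 1 - (1 - w[f, features]) *
      exp(-t_active[f] / params$tau_hungry)
  }
  w
}
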
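## Planning-by-replay control model: an episodic list of memory items, each
## a collection of tray-hunger-outcome triples; interactions less than one
## hour apart share one item.  At caching decisions the last three items are
## matched against the history, matched positions are replayed forward for
## up to six items, and replayed outcomes determine a signed caching weight
## squashed by tanh.

.REPLAY_GAP <- 60       # minutes: interactions further apart start a new item
.REPLAY_HORIZON <- 6L   # items replayed forward from a match
.CONTEXT_WINDOW <- 3L   # items compared when searching for matches

#' Create an empty replay memory
#'
#' @return A `replay_memory` list with fields `items` (list of per-item
#'   lists with vectors `x`, `o` and matrix `h`) and `times` (last-change
#'   time per item).
#' @export
replay_memory <- function() {
  structure(list(items = list(), times = numeric()), class = "replay_memory")
}

#' Record a tray interaction in the replay memory
#'
#' Within one hour of the last change: an interaction with an already
#' recorded tray averages the stored hunger with the current one (half-half)
#' and overwrites the outcome; a new tray appends a triple to the current
#' item.  After a gap of more than one hour a new memory item starts.
#'
#' @param rm a [replay_memory()].
#' @param x tray identifier (integer appearance id).
#' @param h current hunger vector (length 11).
#' @param outcome one of `"pilfered"`, `"fresh_food_item"`,
#'   `"degraded_food_item"`, `"not_inspected"`.
#' @param t interaction time in minutes.
#' @return The updated `replay_memory`.
#' @export
record_interaction <- function(rm, x, h, outcome, t) {
  outcome <- match.arg(outcome, c("pilfered", "fresh_food_item",
                                  "degraded_food_item", "not_inspected"))
  I <- length(rm$items)
  if (I > 0 && (t - rm$times[I]) < .REPLAY_GAP) {
    item <- rm$items[[I]]
    j <- match(x, item$x)
    if (!is.na(j)) {
      item$h[j, ] <- 0.5 * item$h[j, ] + 0.5 * h
      item$o[j] <- outcome
    } else {
      item$x <- c(item$x, x)
      item$o <- c(item$o, outcome)
      item$h <- rbind(item$h, h)
    }
    rm$items[[I]] <- item
    rm$times[I] <- t
  } else {
    rm$items[[I + 1L]] <- list(x = x, o = outcome,
                               h = matrix(h, nrow = 1L))
    rm$times <- c(rm$times, t)
  }
  rm
}

## number of offsets k = 0..2 at which the tray sequence of items
## (I-k) and (i-k) matches exactly (including lengths)
context_match_count <- function(rm, i, I) {
  cnt <- 0L
  for (k in 0:(.CONTEXT_WINDOW - 1L)) {
    a <- I - k; b <- i - k
    if (b < 1L || a < 1L) next # missing offsets contribute no match
    xa <- rm$items[[a]]$x; xb <- rm$items[[b]]$x
    if (length(xa) == length(xb) && all(xa == xb)) cnt <- cnt + 1L
  }
  cnt
}

#' Find replay indices and similarity weights
#'
#' Matches the tray sequences of the last three memory items against all
#' earlier positions; the argmax positions (if the best match count is
#' positive) are returned with similarity weights that combine the L1
#' hunger distance and outcome agreement at the matched positions,
#' normalised by `dim(h) + 1`.
#'
#' @param rm a [replay_memory()].
#' @param similarity_outcome_sign `"as_printed"` adds the outcome-agreement
#'   indicator to the distance term (the formula as published);
#'   `"agreement_rewards"` adds the disagreement indicator instead, so that
#'   agreement increases the similarity.
#' @return A list with `indices` (integer vector, possibly empty) and
#'   `weights` (similarity weight per index).
#' @export
find_replay_indices <- function(rm, similarity_outcome_sign =
                                  c("as_printed", "agreement_rewards")) {
  similarity_outcome_sign <- match.arg(similarity_outcome_sign)
  I <- length(rm$items)
  if (I < 2L) return(list(indices = integer(), weights = numeric()))
  counts <- vapply(seq_len(I - 1L), context_match_count, 0L, I = I, rm = rm)
  best <- max(counts)
  if (best == 0L) return(list(indices = integer(), weights = numeric()))
  idx <- which(counts == best)
  weights <- vapply(idx, function(i) {
    acc <- 0
    for (k in 0:(.CONTEXT_WINDOW - 1L)) {
      a <- I - k; b <- i - k
      if (b < 1L || a < 1L) next
      ia <- rm$items[[a]]; ib <- rm$items[[b]]
      J <- nrow(ib$h)
      jj <- seq_len(min(nrow(ia$h), J))
      if (!length(jj)) next
      term <- vapply(jj, function(j) {
        d1 <- sum(abs(ia$h[j, ] - ib$h[j, ]))
        agree <- as.numeric(ia$o[j] == ib$o[j])
        osgn <- if (similarity_outcome_sign == "as_printed") agree else 1 - agree
        1 - (d1 + osgn) / (.NF + 1)
      }, 0)
      acc <- acc + sum(term) / J
    }
    acc / .CONTEXT_WINDOW
  }, 0)
  list(indices = idx, weights = weights)
}

#' Replay-derived caching weight
#'
#' For each replay index, the following six memory items are scanned for
#' triples with the queried tray; each match contributes
#' `alpha_hunger * h_f + alpha_fresh_r * [h_f <= theta][o = fresh]
#'  - alpha_degrade_r * [o = degraded] - alpha_pilfer_r * [o = pilfered]`,
#' discounted by `gamma^(i - i*)` and weighted by the context similarity.
#' The squashed value `tanh(w_fx)` replaces the two plastic weight terms in
#' the caching preference.
#'
#' @param rm a [replay_memory()].
#' @param food_type food type whose hunger entry enters the hunger term.
#' @param x tray identifier (appearance id) being considered for caching.
#' @param params a [bird_parameters()] list (fields `alpha_hunger`,
#'   `alpha_fresh_r`, `alpha_degrade_r`, `alpha_pilfer_r`, `gamma_replay`,
#'   `theta_replay`, `similarity_outcome_sign`).
#' @return `tanh(w_fx)` in (-1, 1); 0 for an empty or non-matching history.
#' @export
replay_caching_weight <- function(rm, food_type, x, params) {
  found <- find_replay_indices(rm, params$similarity_outcome_sign)
  if (!length(found$indices)) return(0)
  f <- food_type_id(food_type)
  I <- length(rm$items)
  w <- 0
  for (m in seq_along(found$indices)) {
    istar <- found$indices[m]
    acc <- 0
    for (i in seq(istar + 1L, min(istar + .REPLAY_HORIZON, I))) {
      item <- rm$items[[i]]
      for (j in which(item$x == x)) {
        hf <- item$h[j, f]
        wij <- params$alpha_hunger * hf +
          params$alpha_fresh_r * (hf <= params$theta_replay) *
            (item$o[j] == "fresh_food_item") -
          params$alpha_degrade_r * (item$o[j] == "degraded_food_item") -
          params$alpha_pilfer_r * (item$o[j] == "pilfered")
        acc <- acc + params$gamma_replay^(i - istar) * wij
      }
    }
    w <- w + found$weights[m] * acc
  }
  tanh(w)
}

#' Dump a replay memory as JSON lines
#'
#' One memory item per line, for inspection and test fixtures.
#'
#' @param rm a [replay_memory()].
#' @param path file path; when `NULL` the lines are returned.
#' @return Character vector of JSON lines (invisibly when writing).
#' @export
replay_to_jsonl <- function(rm, path = NULL) {
  lines <- vapply(seq_along(rm$items), function(i) {
    item <- rm$items[[i]]
    jsonlite::toJSON(list(time = rm$times[i], trays = item$x,
                          outcomes = item$o,
                          hunger = unname(apply(item$h, 1L, c, simplify = FALSE))),
                     auto_unbox = TRUE, digits = NA)
  }, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
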
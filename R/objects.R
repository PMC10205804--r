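## Domain objects of the protocol language: food items, caching trays,
## inspection observers and the simulated cage that holds them.

#' Recognised food types
#'
#' The eleven food types that can appear in an experimental protocol.
#' Stones are cacheable but never eatable; the maintenance diet is usually
#' handled as a cage-level flag rather than as individual items.
#'
#' @return Character vector of the eleven food type names.
#' @export
food_types <- function() {
  .FOOD_NAMES
}

## number of food types; used to size all per-food state vectors
.NF <- 11L

## feature index space: appearances occupy 1..32, positions 33..64
.MAX_APPEARANCE <- 32L
.NX <- 64L

## precomputed per-id property vectors (hot path)
.EATABLE <- c(rep(TRUE, 9L), FALSE, TRUE)
.CACHEABLE <- c(rep(TRUE, 10L), FALSE)
.FOOD_NAMES <- c("mealworm", "waxworm", "peanut", "suet_pellet", "pinenut",
                 "kibble", "cricket", "pineapple", "salami", "stone",
                 "maintenance_diet")

food_type_id <- function(type) {
  id <- match(type, food_types())
  if (anyNA(id)) {
    stop("unknown food type(s): ", paste(type[is.na(id)], collapse = ", "),
         call. = FALSE)
  }
  id
}

#' @rdname food_types
#' @param type food type name.
#' @export
food_eatable <- function(type) {
  type != "stone"
}

#' @rdname food_types
#' @export
food_cacheable <- function(type) {
  type != "maintenance_diet"
}

feature_index <- function(appearance = NULL, position = NULL) {
  if (!is.null(appearance)) {
    stopifnot(appearance >= 1, appearance <= .MAX_APPEARANCE)
    as.integer(appearance)
  } else {
    stopifnot(position >= 1, position <= .MAX_APPEARANCE)
    .MAX_APPEARANCE + as.integer(position)
  }
}

tray_features <- function(tray) {
  c(feature_index(appearance = tray$appearance),
    feature_index(position = tray$position))
}

#' Create a food item
#'
#' @param type one of [food_types()].
#' @param amount non-negative integer count of identical items.
#' @param freshness freshness in `[0, 1]`; degraded food has freshness 0.
#' @param eatable,cacheable overrides for the per-type defaults.
#' @return A `food_item` list.
#' @examples
#' food_item("mealworm", amount = 5)
#' @export
food_item <- function(type, amount = 1L, freshness = 1,
                      eatable = food_eatable(type),
                      cacheable = food_cacheable(type)) {
  stopifnot(length(type) == 1L, amount >= 0, freshness >= 0, freshness <= 1)
  food_type_id(type) # validates
  if (type == "stone" && eatable) stop("stones are never eatable", call. = FALSE)
  structure(list(type = type, amount = as.integer(amount),
                 freshness = freshness, eatable = eatable,
                 cacheable = cacheable),
            class = "food_item")
}

#' Create a caching tray
#'
#' Trays are visually distinct (appearance identifier) and sit at a fixed
#' position in the cage; both features are perceived by the birds.  Covered
#' trays (`open = FALSE`) accept neither caching nor inspection.
#'
#' @param id tray name used in protocols.
#' @param appearance,position integer identifiers (1..32).
#' @param open logical; covered trays are inaccessible.
#' @return A `tray` list with an empty cache.
#' @export
tray <- function(id, appearance, position, open = TRUE) {
  structure(list(id = as.character(id), appearance = as.integer(appearance),
                 position = as.integer(position), open = isTRUE(open),
                 it_type = integer(), it_fresh = numeric(),
                 it_time = numeric(), it_amount = integer()),
            class = "tray")
}

#' Create an inspection observer
#'
#' Observers register retrieve (inspection) events on trays whose appearance
#' is in `tray_appearances`, as an ordered (time, tray) log.
#'
#' @param id observer name.
#' @param tray_appearances integer appearance identifiers to watch.
#' @return An `inspection_observer` list.
#' @export
inspection_observer <- function(id, tray_appearances) {
  structure(list(id = as.character(id),
                 tray_appearances = as.integer(tray_appearances),
                 log_time = numeric(), log_app = integer(),
                 log_tray = character()),
            class = "inspection_observer")
}

#' Create an empty simulated cage
#'
#' The cage holds loose food, caching trays and observers, plus the simulated
#' clock (in minutes).  It is a mutable environment: actions modify it in
#' place.
#'
#' @param clock starting time in minutes (default 480, i.e. 08:00 on day 0).
#' @param maintenance_diet logical; when `TRUE`, hunger is integrated as if
#'   every stomach were non-empty (ad-libitum maintenance diet).
#' @return A `cage` environment.
#' @examples
#' cg <- cage()
#' apply_action(cg, "add", food_item("peanut", 3))
#' count_food_items(cg)
#' @export
cage <- function(clock = 480, maintenance_diet = FALSE) {
  cg <- new.env(parent = emptyenv())
  cg$clock <- clock
  ## loose food: parallel vectors, one entry per (type, freshness) lot
  cg$lf_type <- integer()
  cg$lf_fresh <- numeric()
  cg$lf_amount <- integer()
  cg$lf_by_type <- rep(0L, .NF)
  cg$trays <- list()
  cg$observers <- list()
  cg$maintenance_diet <- isTRUE(maintenance_diet)
  ## conservation bookkeeping
  cg$eaten_by_type <- rep(0L, .NF)
  cg$n_added <- 0L
  cg$n_eaten <- 0L
  cg$n_pilfered <- 0L
  cg$n_removed <- 0L
  cg$n_discarded <- 0L
  class(cg) <- c("cage", class(cg))
  cg
}

loose_add <- function(cg, type_id, freshness, amount) {
  if (amount <= 0) return(invisible(cg))
  cg$lf_by_type[type_id] <- cg$lf_by_type[type_id] + as.integer(amount)
  i <- which(cg$lf_type == type_id & cg$lf_fresh == freshness)
  if (length(i)) {
    cg$lf_amount[i[1L]] <- cg$lf_amount[i[1L]] + as.integer(amount)
  } else {
    cg$lf_type <- c(cg$lf_type, as.integer(type_id))
    cg$lf_fresh <- c(cg$lf_fresh, freshness)
    cg$lf_amount <- c(cg$lf_amount, as.integer(amount))
  }
  invisible(cg)
}

## remove one loose item of food type `type_id` (freshest lot first);
## returns its freshness or NA if none present
loose_take_one <- function(cg, type_id) {
  i <- which(cg$lf_type == type_id & cg$lf_amount > 0L)
  if (!length(i)) return(NA_real_)
  if (length(i) > 1L) i <- i[which.max(cg$lf_fresh[i])]
  cg$lf_amount[i] <- cg$lf_amount[i] - 1L
  cg$lf_by_type[type_id] <- cg$lf_by_type[type_id] - 1L
  cg$lf_fresh[i]
}

get_tray <- function(cg, id) {
  tr <- cg$trays[[as.character(id)]]
  if (is.null(tr)) stop("no tray with identifier '", id, "'", call. = FALSE)
  tr
}

#' Apply an experimenter action to the cage
#'
#' Implements the out-of-sight experimenter actions of the protocol
#' language: `add`, `remove`, `cover`, `uncover`, `degrade`, `pilfer`.
#' Bird state is never touched by these actions.
#'
#' @param cg a [cage()].
#' @param action one of `"add"`, `"remove"`, `"cover"`, `"uncover"`,
#'   `"degrade"`, `"pilfer"`.
#' @param target a [food_item()], [tray()] or [inspection_observer()] for
#'   `add`; an identifier (tray/observer id) or food item for the others.
#' @return The cage, invisibly (modified in place).
#' @export
apply_action <- function(cg, action, target) {
  action <- match.arg(action, c("add", "remove", "cover", "uncover",
                                "degrade", "pilfer"))
  switch(action,
    add = {
      if (inherits(target, "food_item")) {
        loose_add(cg, food_type_id(target$type), target$freshness, target$amount)
        cg$n_added <- cg$n_added + target$amount
      } else if (inherits(target, "tray")) {
        if (!is.null(cg$trays[[target$id]]))
          stop("duplicate tray identifier '", target$id, "'", call. = FALSE)
        cg$trays[[target$id]] <- target
      } else if (inherits(target, "inspection_observer")) {
        if (!is.null(cg$observers[[target$id]]))
          stop("duplicate observer identifier '", target$id, "'", call. = FALSE)
        cg$observers[[target$id]] <- target
      } else stop("cannot add object of class ", class(target)[1L], call. = FALSE)
    },
    remove = {
      if (inherits(target, "food_item")) {
        id <- food_type_id(target$type)
        keep <- cg$lf_type != id
        cg$n_removed <- cg$n_removed + sum(cg$lf_amount[!keep])
        cg$lf_type <- cg$lf_type[keep]
        cg$lf_fresh <- cg$lf_fresh[keep]
        cg$lf_amount <- cg$lf_amount[keep]
        cg$lf_by_type[id] <- 0L
      } else {
        id <- as.character(target)
        if (!is.null(cg$trays[[id]])) {
          cg$n_removed <- cg$n_removed + sum(cg$trays[[id]]$items$amount)
          cg$trays[[id]] <- NULL
        } else if (!is.null(cg$observers[[id]])) {
          cg$observers[[id]] <- NULL
        } else stop("no tray or observer with identifier '", id, "'",
                    call. = FALSE)
      }
    },
    cover = {
      tr <- get_tray(cg, target)
      if (!tr$open) stop("tray '", tr$id, "' is already covered", call. = FALSE)
      tr$open <- FALSE
      cg$trays[[tr$id]] <- tr
    },
    uncover = {
      tr <- get_tray(cg, target)
      tr$open <- TRUE
      cg$trays[[tr$id]] <- tr
    },
    degrade = {
      tr <- get_tray(cg, target)
      tr$it_fresh <- rep(0, length(tr$it_fresh))
      cg$trays[[tr$id]] <- tr
    },
    pilfer = {
      tr <- get_tray(cg, target)
      cg$n_pilfered <- cg$n_pilfered + sum(tr$it_amount)
      tr$it_type <- integer(); tr$it_fresh <- numeric()
      tr$it_time <- numeric(); tr$it_amount <- integer()
      cg$trays[[tr$id]] <- tr
    })
  invisible(cg)
}

#' Count food items cached in a tray
#'
#' @param cg a [cage()].
#' @param tray_id tray identifier.
#' @param type optional food type filter.
#' @return Integer count.
#' @export
count_cached_items <- function(cg, tray_id, type = NULL) {
  tr <- get_tray(cg, tray_id)
  if (is.null(type)) return(as.integer(sum(tr$it_amount)))
  as.integer(sum(tr$it_amount[tr$it_type == food_type_id(type)]))
}

#' Count loose food items in the cage
#'
#' @inheritParams count_cached_items
#' @return Integer count of loose (uncached) items.
#' @export
count_food_items <- function(cg, type = NULL) {
  if (is.null(type)) return(as.integer(sum(cg$lf_amount)))
  as.integer(sum(cg$lf_amount[cg$lf_type == food_type_id(type)]))
}

get_observer <- function(cg, id) {
  ob <- cg$observers[[as.character(id)]]
  if (is.null(ob)) stop("no observer with identifier '", id, "'", call. = FALSE)
  ob
}

#' Count inspections registered by an observer
#'
#' @param cg a [cage()].
#' @param observer_id observer identifier.
#' @param appearance optional tray-appearance filter.
#' @return Integer count of logged retrieve events.
#' @export
count_inspections <- function(cg, observer_id, appearance = NULL) {
  ob <- get_observer(cg, observer_id)
  if (is.null(appearance)) return(length(ob$log_time))
  sum(ob$log_app %in% appearance)
}

#' First inspected tray
#'
#' @inheritParams count_inspections
#' @return The appearance identifier of the earliest logged inspection, or
#'   `NA_integer_` (an explicit "no inspection" sentinel) for an empty log.
#' @export
first_inspection <- function(cg, observer_id) {
  ob <- get_observer(cg, observer_id)
  if (!length(ob$log_time)) return(NA_integer_)
  ob$log_app[which.min(ob$log_time)]
}

#' Observer log as a tibble
#'
#' @inheritParams count_inspections
#' @return A tibble with columns `time`, `appearance`, `tray`, in
#'   chronological order.
#' @export
observer_log <- function(cg, observer_id) {
  ob <- get_observer(cg, observer_id)
  tibble::tibble(time = ob$log_time, appearance = ob$log_app,
                 tray = ob$log_tray)
}

observer_log_retrieve <- function(cg, tr, t) {
  for (id in names(cg$observers)) {
    ob <- cg$observers[[id]]
    if (tr$appearance %in% ob$tray_appearances) {
      ob$log_time <- c(ob$log_time, t)
      ob$log_app <- c(ob$log_app, tr$appearance)
      ob$log_tray <- c(ob$log_tray, tr$id)
      cg$observers[[id]] <- ob
    }
  }
  invisible(cg)
}

## item conservation: everything added is loose, cached, eaten, pilfered,
## removed or discarded
check_conservation <- function(cg) {
  cached <- sum(vapply(cg$trays, function(tr) sum(tr$it_amount), 0))
  total <- count_food_items(cg) + cached + cg$n_eaten + cg$n_pilfered +
    cg$n_removed + cg$n_discarded
  isTRUE(all.equal(total, cg$n_added))
}

#' @export
print.cage <- function(x, ...) {
  cat("<cage> t =", format(x$clock), "min;",
      count_food_items(x), "loose items;",
      length(x$trays), "trays;", length(x$observers), "observers\n")
  invisible(x)
}
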
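## Protocols as programs: a declarative, serializable step list per group
## (sufficient for loop-free protocols, which covers the shipped fixtures)
## plus support for arbitrary host-language programs.  Executing a protocol
## runs every bird of a group in its own cage, collects the declared
## per-bird measurements, summarises them (mean, SEM per group) and
## computes the declared statistical tests into p-value entries.

.STEP_OPS <- c("add_food", "add_tray", "add_observer", "remove_food",
               "remove_tray", "remove_observer", "cover", "uncover",
               "degrade", "pilfer", "maintenance", "wait", "measure",
               "reset_observer")
.MEASURES <- c("count_cached_items", "count_food_items", "count_inspections",
               "first_inspection_is", "eaten_items")
.TEST_TYPES <- c("t_ind", "t_paired", "binom", "anova")

#' Define an experimental protocol
#'
#' A protocol is an ordered program of experimenter actions per group, a
#' measurement schema (implied by its `measure` steps, each produced
#' exactly once per run) and declared statistical tests.
#'
#' @param name protocol name.
#' @param groups named integer vector of group sizes.
#' @param steps named list (one entry per group) of step lists; each step
#'   is a list with an `op` field (one of the eleven DSL actions plus
#'   `measure`/`maintenance`/`reset_observer`) and its arguments.
#' @param tests list of test declarations, each a list with `name`,
#'   `type` (`"t_ind"`, `"t_paired"`, `"binom"`, `"anova"`) and the
#'   quantities/groups it compares.
#' @param start_clock cage clock at protocol start (minutes; default 480 =
#'   08:00).
#' @param series logical: protocols in a series share persistent birds.
#' @return A `protocol` object.
#' @export
protocol <- function(name, groups, steps, tests = list(),
                     start_clock = 480, series = FALSE) {
  stopifnot(is.character(name), length(groups) >= 1L,
            !is.null(names(groups)), setequal(names(steps), names(groups)))
  for (g in names(steps)) {
    for (st in steps[[g]]) {
      if (is.null(st$op) || !(st$op %in% .STEP_OPS)) {
        stop("unknown step op '", st$op, "' in group '", g, "'",
             call. = FALSE)
      }
      if (identical(st$op, "measure") &&
          !(st$what %in% .MEASURES)) {
        stop("unknown measurement '", st$what, "'", call. = FALSE)
      }
    }
  }
  for (ts in tests) {
    if (!(ts$type %in% .TEST_TYPES)) {
      stop("unknown test type '", ts$type, "'", call. = FALSE)
    }
  }
  structure(list(name = name, groups = groups, steps = steps,
                 tests = tests, start_clock = start_clock,
                 series = series),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol ", x$name, "> groups: ",
      paste0(names(x$groups), "=", x$groups, collapse = ", "),
      "; ", length(x$tests), " tests\n", sep = "")
  invisible(x)
}

#' Measurement schema of a protocol
#'
#' @param proto a [protocol()].
#' @return Character vector of all quantity names the protocol produces
#'   (`group:measure:mean`, `group:measure:sem` and test names).
#' @export
protocol_schema <- function(proto) {
  qs <- unlist(lapply(names(proto$steps), function(g) {
    ms <- vapply(Filter(function(st) st$op == "measure", proto$steps[[g]]),
                 function(st) st$name, "")
    if (length(ms)) paste0(g, ":", rep(ms, each = 2L), ":",
                           c("mean", "sem")) else character()
  }))
  c(qs, vapply(proto$tests, function(ts) ts$name, ""))
}

## ---- step execution ---------------------------------------------------

execute_step <- function(st, cg, bird, measures, log_events) {
  switch(st$op,
    add_food = apply_action(cg, "add",
      food_item(st$type, st$amount,
                freshness = if (is.null(st$freshness)) 1 else st$freshness)),
    add_tray = apply_action(cg, "add",
      tray(st$tray, st$appearance, st$position,
           open = if (is.null(st$open)) TRUE else st$open)),
    add_observer = apply_action(cg, "add",
      inspection_observer(st$id, unlist(st$appearances))),
    remove_food = apply_action(cg, "remove", food_item(st$type, 0L)),
    remove_tray = apply_action(cg, "remove", st$tray),
    remove_observer = apply_action(cg, "remove", st$id),
    cover = apply_action(cg, "cover", st$tray),
    uncover = apply_action(cg, "uncover", st$tray),
    degrade = apply_action(cg, "degrade", st$tray),
    pilfer = apply_action(cg, "pilfer", st$tray),
    maintenance = { cg$maintenance_diet <- isTRUE(st$on) },
    wait = cage_wait(cg, bird, st$minutes, log_events = log_events),
    reset_observer = {
      ob <- get_observer(cg, st$id)
      ob$log_time <- numeric(); ob$log_app <- integer()
      ob$log_tray <- character()
      cg$observers[[st$id]] <- ob
    },
    measure = {
      val <- switch(st$what,
        count_cached_items = count_cached_items(cg, st$tray, st$type),
        count_food_items = count_food_items(cg, st$type),
        count_inspections = count_inspections(cg, st$observer,
                                              st$appearance),
        eaten_items = if (is.null(st$type)) cg$n_eaten else
          cg$eaten_by_type[food_type_id(st$type)],
        first_inspection_is = {
          fi <- first_inspection(cg, st$observer)
          as.numeric(!is.na(fi) && fi == st$appearance)
        })
      if (!is.null(measures[[st$name]])) {
        stop("measurement '", st$name, "' produced twice", call. = FALSE)
      }
      measures[[st$name]] <- as.numeric(val)
    })
  measures
}

run_bird_through_steps <- function(steps, bird, start_clock, log_events) {
  cg <- cage(clock = start_clock)
  measures <- list()
  for (st in steps) {
    measures <- execute_step(st, cg, bird, measures, log_events)
  }
  if (!check_conservation(cg)) {
    stop("food item conservation violated after protocol run", call. = FALSE)
  }
  unlist(measures)
}

## ---- statistical test registry ---------------------------------------

safe_p <- function(expr) {
  p <- tryCatch(expr, error = function(e) NA_real_)
  if (!is.finite(p)) 1 else p # degenerate data carries no evidence
}

compute_test <- function(ts, raw) {
  switch(ts$type,
    t_ind = {
      x <- raw[[ts$groups[[1L]]]][, ts$quantity]
      y <- raw[[ts$groups[[2L]]]][, ts$quantity]
      safe_p(t.test(x, y)$p.value)
    },
    t_paired = {
      x <- raw[[ts$group]][, ts$q1]
      y <- raw[[ts$group]][, ts$q2]
      safe_p(t.test(x, y, paired = TRUE)$p.value)
    },
    binom = {
      x <- raw[[ts$group]][, ts$q1]
      y <- raw[[ts$group]][, ts$q2]
      k <- sum(x > y); m <- sum(x != y)
      if (m == 0L) 1 else safe_p(binom.test(k, m)$p.value)
    },
    anova = {
      vals <- unlist(lapply(names(raw), function(g) raw[[g]][, ts$quantity]))
      grp <- factor(rep(names(raw), vapply(raw, nrow, 0L)))
      safe_p(summary(aov(vals ~ grp))[[1L]][["Pr(>F)"]][1L])
    })
}

## ---- protocol execution ------------------------------------------------

#' Run a protocol on given birds
#'
#' Each bird of each group is placed in its own cage and taken through the
#' group's program.  Per-bird measurements are summarised into group means
#' and standard errors, and the declared statistical tests are computed
#' into p-value entries.
#'
#' @param proto a [protocol()].
#' @param birds named list (by group) of lists of birds; sizes must match
#'   the protocol's declared group sizes.
#' @param log_events keep per-event logs on the birds.
#' @return A [summary_dataset()].
#' @export
run_protocol <- function(proto, birds, log_events = FALSE) {
  if (!setequal(names(birds), names(proto$groups))) {
    stop("bird groups do not match protocol groups", call. = FALSE)
  }
  for (g in names(proto$groups)) {
    if (length(birds[[g]]) != proto$groups[[g]]) {
      stop("group '", g, "' needs ", proto$groups[[g]], " birds, got ",
           length(birds[[g]]), call. = FALSE)
    }
  }
  raw <- list()
  for (g in names(proto$groups)) {
    rows <- lapply(birds[[g]], function(b) {
      run_bird_through_steps(proto$steps[[g]], b, proto$start_clock,
                             log_events)
    })
    raw[[g]] <- do.call(rbind, rows)
  }
  values <- numeric(); is_p <- logical()
  for (g in names(proto$groups)) {
    m <- raw[[g]]
    for (q in colnames(m)) {
      values[paste0(g, ":", q, ":mean")] <- mean(m[, q])
      values[paste0(g, ":", q, ":sem")] <- sd(m[, q]) / sqrt(nrow(m))
      is_p <- c(is_p, FALSE, FALSE)
    }
  }
  for (ts in proto$tests) {
    values[ts$name] <- compute_test(ts, raw)
    is_p <- c(is_p, TRUE)
  }
  names(is_p) <- names(values)
  missing <- setdiff(protocol_schema(proto), names(values))
  if (length(missing)) {
    stop("protocol run did not produce measurements: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  summary_dataset(proto$name, values, is_p, raw = raw)
}

#' Run repeated simulated experiments with freshly sampled populations
#'
#' Samples `K` independent groups of birds from the population described by
#' the hyperparameters (or uses identical template parameters when
#' `hyper = NULL`) and runs the protocol once per repetition.
#'
#' @param proto a [protocol()].
#' @param variant model variant passed to [make_bird()].
#' @param hyper population hyperparameters (see [sample_parameters()]), or
#'   `NULL` for fixed parameters.
#' @param params template [bird_parameters()]; sampled parameters override
#'   its entries.
#' @param K number of repetitions (independent simulated experiments).
#' @param seed optional integer seed.
#' @param caching_mode motivational caching variant.
#' @return List of `K` [summary_dataset()] objects.
#' @export
run_population <- function(proto, variant = "plastic_caching", hyper = NULL,
                           params = default_bird_parameters(), K = 1L,
                           seed = NULL, caching_mode = "hunger_modulated") {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(K), function(k) {
    birds <- lapply(names(proto$groups), function(g) {
      lapply(seq_len(proto$groups[[g]]), function(i) {
        pars <- if (is.null(hyper)) params else
          sample_parameters(hyper, template = params)
        make_bird(variant, pars, caching_mode,
                  id = paste0(g, i, "_rep", k))
      })
    })
    names(birds) <- names(proto$groups)
    run_protocol(proto, birds)
  })
}

#' Run a series of protocols with persistent birds
#'
#' Experiments building on each other share birds: state (memory, weights,
#' motivation) carries over from one protocol to the next.
#'
#' @param protos list of [protocol()] objects with identical groups.
#' @param birds named list of bird lists (as in [run_protocol()]).
#' @return List of [summary_dataset()] objects, one per protocol.
#' @export
run_protocol_series <- function(protos, birds) {
  lapply(protos, function(p) run_protocol(p, birds))
}

## ---- serialization ----------------------------------------------------

#' Serialize a protocol to YAML / parse it back
#'
#' The declarative step-list representation round-trips: a re-parsed
#' protocol executes identically (same event log under the same seed).
#'
#' @param proto a [protocol()].
#' @param path optional file path.
#' @return `protocol_to_yaml()`: the YAML string (invisibly when writing);
#'   `protocol_from_yaml()`: a `protocol` object.
#' @export
protocol_to_yaml <- function(proto, path = NULL) {
  obj <- list(name = proto$name, groups = as.list(proto$groups),
              start_clock = proto$start_clock, series = proto$series,
              steps = proto$steps, tests = proto$tests)
  txt <- yaml::as.yaml(obj)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname protocol_to_yaml
#' @param text YAML string (alternative to `path`).
#' @export
protocol_from_yaml <- function(path = NULL, text = NULL) {
  obj <- if (!is.null(text)) yaml::yaml.load(text) else
    yaml::read_yaml(path)
  protocol(name = obj$name,
           groups = unlist(obj$groups),
           steps = obj$steps,
           tests = obj$tests,
           start_clock = obj$start_clock,
           series = isTRUE(obj$series))
}
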
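## Reconstructed protocol fixtures.  Three experiments reconstructed from
## their published descriptions: a two-tray pilfering experiment
## (dekort07_exp4), a six-day food-degradation memory schedule
## (clayton03_exp2) and a specific-satiety test (specific_satiety).
## Exact phase durations are not all published; the values used here are
## fixture parameters with documented defaults.

dekort07_trial <- function(trial, pilfer, n_worms, cache_minutes,
                           retrieval_minutes) {
  steps <- list()
  add <- function(...) steps[[length(steps) + 1L]] <<- list(...)
  if (trial == 1L) {
    add(op = "wait", minutes = 60)                # deprivation
    add(op = "add_tray", tray = "A", appearance = 1L, position = 1L,
        open = TRUE)
    add(op = "add_tray", tray = "B", appearance = 2L, position = 2L,
        open = FALSE)                             # Perspex-covered
  } else {
    add(op = "wait", minutes = 50)
    add(op = "pilfer", tray = "A") # trays cleaned between trials
    add(op = "pilfer", tray = "B")
    add(op = "uncover", tray = "A")
  }
  add(op = "add_food", type = "mealworm", amount = n_worms)
  add(op = "wait", minutes = cache_minutes)
  add(op = "measure", what = "count_cached_items", tray = "A",
      name = paste0("cache_A_trial", trial))
  add(op = "remove_food", type = "mealworm")
  add(op = "cover", tray = "A")
  if (pilfer) add(op = "pilfer", tray = "A")
  add(op = "wait", minutes = 1440 - 60 - cache_minutes)
  add(op = "uncover", tray = "A")
  add(op = "uncover", tray = "B")
  add(op = "wait", minutes = retrieval_minutes)   # cache recovery
  add(op = "cover", tray = "A")
  add(op = "cover", tray = "B")
  steps
}

#' Two-tray pilfering fixture
#'
#' Birds cache worms in tray A while tray B is covered; one day later both
#' trays are open for recovery.  For the pilfered group the experimenter
#' has emptied tray A (out of sight), so recovery attempts fail; controls
#' retrieve their caches.  After two such trials both trays are open for a
#' final caching choice.  The published finding: pilfered birds stop
#' caching in their previously preferred tray A.
#'
#' @param n_per_group birds per group.
#' @param n_worms worms offered per caching session.
#' @param cache_minutes,retrieval_minutes session durations.
#' @return A [protocol()].
#' @export
fixture_dekort07_exp4 <- function(n_per_group = 4L, n_worms = 12L,
                                  cache_minutes = 15, retrieval_minutes = 20) {
  final <- list(
    list(op = "wait", minutes = 50),
    list(op = "pilfer", tray = "A"), # fresh trays for the final choice
    list(op = "pilfer", tray = "B"),
    list(op = "uncover", tray = "A"),
    list(op = "uncover", tray = "B"),
    list(op = "add_food", type = "mealworm", amount = n_worms),
    list(op = "wait", minutes = cache_minutes),
    list(op = "measure", what = "count_cached_items", tray = "A",
         name = "cache_A_final"),
    list(op = "measure", what = "count_cached_items", tray = "B",
         name = "cache_B_final"))
  mk <- function(pilfer) {
    c(dekort07_trial(1L, pilfer, n_worms, cache_minutes, retrieval_minutes),
      dekort07_trial(2L, pilfer, n_worms, cache_minutes, retrieval_minutes),
      final)
  }
  protocol(
    name = "dekort07_exp4",
    groups = c(control = n_per_group, pilfered = n_per_group),
    steps = list(control = mk(FALSE), pilfered = mk(TRUE)),
    tests = list(list(name = "p_cache_A", type = "t_ind",
                      quantity = "cache_A_final",
                      groups = list("control", "pilfered"))))
}

clayton03_cache_day <- function(day, n_items, session_minutes) {
  pt <- paste0("P", day); ct <- paste0("C", day)
  list(
    list(op = "wait", minutes = 60),
    list(op = "add_tray", tray = pt, appearance = 2L * day - 1L,
         position = 2L * day - 1L, open = TRUE),
    list(op = "add_food", type = "peanut", amount = n_items),
    list(op = "wait", minutes = session_minutes),
    list(op = "measure", what = "count_cached_items", tray = pt,
         name = paste0("cache_peanut_day", day)),
    list(op = "remove_food", type = "peanut"),
    list(op = "cover", tray = pt),
    list(op = "wait", minutes = 5),
    list(op = "add_tray", tray = ct, appearance = 2L * day,
         position = 2L * day, open = TRUE),
    list(op = "add_food", type = "cricket", amount = n_items),
    list(op = "wait", minutes = session_minutes),
    list(op = "measure", what = "count_cached_items", tray = ct,
         name = paste0("cache_cricket_day", day)),
    list(op = "remove_food", type = "cricket"),
    list(op = "cover", tray = ct),
    list(op = "wait", minutes = 1440 - 60 - 2 * session_minutes - 5))
}

clayton03_recovery_day <- function(degrade_day, recovery_minutes) {
  pt <- paste0("P", degrade_day); ct <- paste0("C", degrade_day)
  list(
    list(op = "wait", minutes = 60),
    list(op = "degrade", tray = ct), # crickets decay after three days
    list(op = "uncover", tray = pt),
    list(op = "uncover", tray = ct),
    list(op = "wait", minutes = recovery_minutes),
    list(op = "cover", tray = pt),
    list(op = "cover", tray = ct),
    list(op = "remove_food", type = "peanut"),  # retrieved items taken out
    list(op = "remove_food", type = "cricket"),
    list(op = "wait", minutes = 1440 - 60 - recovery_minutes))
}

#' Six-day degradation-learning fixture
#'
#' On days 1-3 birds cache peanuts and crickets in day-specific tray
#' halves (modeled as separate trays with distinct appearance and
#' position).  On days 4 and 5, the three-day-old caches of days 1 and 2
#' are recovered: peanuts fresh, crickets degraded.  On day 6 the day-3
#' trays are offered (emptied, unrewarded) and side-specific inspections
#' are counted: birds that generalised the cricket decay interval search
#' the cricket side less.
#'
#' @param n_birds group size.
#' @param n_items items offered per caching session.
#' @param session_minutes caching session duration.
#' @param recovery_minutes recovery session duration.
#' @param test_minutes day-6 observation window.
#' @return A [protocol()].
#' @export
fixture_clayton03_exp2 <- function(n_birds = 8L, n_items = 5L,
                                   session_minutes = 15,
                                   recovery_minutes = 10,
                                   test_minutes = 5) {
  day6 <- list(
    list(op = "wait", minutes = 60),
    list(op = "pilfer", tray = "P3"), # unrewarded test trial
    list(op = "pilfer", tray = "C3"),
    list(op = "add_observer", id = "obs", appearances = list(5L, 6L)),
    list(op = "uncover", tray = "P3"),
    list(op = "uncover", tray = "C3"),
    list(op = "wait", minutes = test_minutes),
    list(op = "measure", what = "count_inspections", observer = "obs",
         appearance = 5L, name = "inspect_peanut_side"),
    list(op = "measure", what = "count_inspections", observer = "obs",
         appearance = 6L, name = "inspect_cricket_side"))
  steps <- c(clayton03_cache_day(1L, n_items, session_minutes),
             clayton03_cache_day(2L, n_items, session_minutes),
             clayton03_cache_day(3L, n_items, session_minutes),
             clayton03_recovery_day(1L, recovery_minutes),
             clayton03_recovery_day(2L, recovery_minutes),
             day6)
  protocol(
    name = "clayton03_exp2",
    groups = c(manipulated = n_birds),
    steps = list(manipulated = steps),
    tests = list(list(name = "p_side", type = "t_paired",
                      group = "manipulated",
                      q1 = "inspect_peanut_side",
                      q2 = "inspect_cricket_side")))
}

#' Specific-satiety fixture
#'
#' After food deprivation, birds are pre-fed one food to satiety (with a
#' time-resolved intake curve, whose late slope reflects the appetite
#' growth rate), then offered the pre-fed and an alternative food
#' together; remaining counts are measured 5 and 15 minutes into the
#' test.  Satiated birds keep eating the alternative food (specific
#' satiety), so more of the pre-fed food remains.
#'
#' @param n_birds group size.
#' @param prefed,other the pre-fed and alternative food types.
#' @param deprivation_minutes,prefeed_minutes phase durations.
#' @param n_prefeed,n_test item counts offered.
#' @return A [protocol()].
#' @export
fixture_specific_satiety <- function(n_birds = 8L, prefed = "mealworm",
                                     other = "peanut",
                                     deprivation_minutes = 150,
                                     prefeed_minutes = 30,
                                     n_prefeed = 30L, n_test = 15L) {
  steps <- list(
    list(op = "wait", minutes = deprivation_minutes),
    ## pre-feeding to satiety, with a time-resolved intake curve: the
    ## late intake rate reflects how fast appetite recovers, which pins
    ## down the appetite time constant
    list(op = "add_food", type = prefed, amount = n_prefeed),
    list(op = "wait", minutes = 10),
    list(op = "measure", what = "count_food_items", type = prefed,
         name = "prefeed_remaining_10"),
    list(op = "wait", minutes = 10),
    list(op = "measure", what = "count_food_items", type = prefed,
         name = "prefeed_remaining_20"),
    list(op = "wait", minutes = prefeed_minutes - 20),
    list(op = "measure", what = "count_food_items", type = prefed,
         name = "prefeed_remaining"),
    list(op = "remove_food", type = prefed),
    list(op = "add_food", type = prefed, amount = n_test),
    list(op = "add_food", type = other, amount = n_test),
    list(op = "wait", minutes = 5),
    list(op = "measure", what = "count_food_items", type = prefed,
         name = "test_remaining_prefed_5"),
    list(op = "measure", what = "count_food_items", type = other,
         name = "test_remaining_other_5"),
    list(op = "wait", minutes = 10),
    list(op = "measure", what = "count_food_items", type = prefed,
         name = "test_remaining_prefed_15"),
    list(op = "measure", what = "count_food_items", type = other,
         name = "test_remaining_other_15"))
  protocol(
    name = "specific_satiety",
    groups = c(prefed = n_birds),
    steps = list(prefed = steps),
    tests = list(list(name = "p_satiety", type = "t_paired",
                      group = "prefed",
                      q1 = "test_remaining_prefed_15",
                      q2 = "test_remaining_other_15")))
}

#' Registry of shipped protocol fixtures
#'
#' @return Named list of protocol constructor functions.
#' @export
list_protocols <- function() {
  list(dekort07_exp4 = fixture_dekort07_exp4,
       clayton03_exp2 = fixture_clayton03_exp2,
       specific_satiety = fixture_specific_satiety)
}

#' Look up a fixture by name
#'
#' @param name fixture name (see [list_protocols()]).
#' @param ... arguments forwarded to the fixture constructor.
#' @return A [protocol()].
#' @export
get_protocol <- function(name, ...) {
  reg <- list_protocols()
  if (is.null(reg[[name]])) {
    stop("unknown protocol '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]](...)
}

#' Ground-truth scenario for recovery experiments
#'
#' Bundles a known population (hyperparameters over a set of free
#' parameters) with a protocol, so that synthetic "observed" data can be
#' generated and the fitting machinery exercised offline.
#'
#' @param protocol_name fixture name.
#' @param hyper true [hyperparameters()].
#' @param variant model variant.
#' @param params template [bird_parameters()].
#' @param K number of pseudo-datasets averaged into the reference table.
#' @param seed integer seed.
#' @return A `ground_truth_scenario` list.
#' @export
ground_truth_scenario <- function(protocol_name, hyper,
                                  variant = "plastic_caching",
                                  params = default_bird_parameters(),
                                  K = 1000L, seed = 1L) {
  structure(list(protocol_name = protocol_name, hyper = hyper,
                 variant = variant, params = params, K = K, seed = seed),
            class = "ground_truth_scenario")
}

#' Default ground-truth population for the satiety recovery suite
#'
#' A plausible, asymmetric population over the appetite time constant, the
#' two food-specific eating preferences and the eating bias.
#'
#' @param prefed,other food types of the satiety fixture.
#' @return A [hyperparameters()] object.
#' @export
satiety_ground_truth <- function(prefed = "mealworm", other = "peanut") {
  nm <- c("tau_h", paste0("v_eat.", prefed), paste0("v_eat.", other),
          "eta_eat")
  ## population means ~ (tau_h 150 min, v_eat 0.85 / 0.55, eta_eat 0.2):
  ## birds reliably eat both foods, with a clear preference for the
  ## pre-fed one, so specific satiety expresses in the test phase
  hyperparameters(
    s = setNames(c(2.0, 2.0, 2.0, 2.0), nm),
    d = setNames(c(0.05, -2.14, 0.0, -0.05), nm))
}

#' Generate synthetic reference data from a known population
#'
#' Simulates `K` pseudo-datasets from the ground-truth population and
#' selects one reference summary table, in the observed-data CSV schema.
#' The default `"medoid"` picks the pseudo-dataset with the smallest
#' summed distance to all others: a typical, actually achievable dataset
#' that keeps natural sampling noise (fitting to a noise-free average
#' table biases likelihood-free fits toward unrealistically concentrated
#' populations).  `"mean"` returns the element-wise average instead.
#' Stands in for published behavioral data so that fitting and
#' reproducibility can be exercised with no download; all outputs are
#' synthetic.
#'
#' @param scenario a [ground_truth_scenario()].
#' @param method `"medoid"` (default) or `"mean"`.
#' @param ... arguments forwarded to the fixture constructor.
#' @return A [summary_dataset()].
#' @export
generate_reference_data <- function(scenario, method = c("medoid", "mean"),
                                    ...) {
  method <- match.arg(method)
  proto <- get_protocol(scenario$protocol_name, ...)
  sims <- run_population(proto, variant = scenario$variant,
                         hyper = scenario$hyper, params = scenario$params,
                         K = scenario$K, seed = scenario$seed)
  if (method == "mean") {
    vals <- rowMeans(vapply(sims, function(d) d$values,
                            numeric(length(sims[[1L]]$values))))
    return(summary_dataset(proto$name, vals, sims[[1L]]$is_pvalue))
  }
  ## medoid on the fitting distance (quantized p-values included)
  vals <- vapply(sims, function(d) d$values,
                 numeric(length(sims[[1L]]$values)))
  ip <- sims[[1L]]$is_pvalue
  vals[ip, ] <- quantize_p(vals[ip, , drop = FALSE])
  dmat <- as.matrix(stats::dist(t(vals)))
  sims[[which.min(colSums(dmat))]]
}
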
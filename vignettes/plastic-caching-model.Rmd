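---
title: "Models, protocols and fitting in cachesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, protocols and fitting in cachesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachesim)
```

`cachesim` simulates populations of food-caching corvids as event-driven
agents and fits their population parameters to summary statistics of
behavioral experiments.  This vignette describes the model equations and
their assumptions, the protocol language, the numerical choices, the
synthetic-data generator, and the design decisions that were genuinely
open.

## Event-based integration

A simulated bird is a hybrid dynamical system: its state variables change
smoothly between events and jump at events (eating, caching, retrieval,
experimenter manipulations).  No time grid is used.  Between events every
variable has a closed form, so the simulator propagates exactly from one
event to the next; decision instants themselves are generated by the
post-action time-outs (a uniform draw from `[1, δ_kind]` seconds after
each action).  Nightly memory-consolidation ticks (04:00 by default —
the literature says the relocation happens over night but gives no clock
time, so the tick hour is configurable) split long event-free intervals.
When neither food nor an open caching tray is present, no events are
simulated and only the continuous dynamics advance.

## Motivational control

Per food type `f` (eleven types are recognised), a stomach variable and a
hunger variable evolve as

* `ds_f/dt = -1/τ_s` while `s_f > 0`, with a jump `s_f += n_f` at each
  eating event;
* `dh_f/dt = -h_f/τ_d` while `s_f > 0` (digestion), and
  `dh_f/dt = (1-h_f)/τ_h` once `s_f = 0` (appetite growth).

"Empty" is behavioral, not literal: `s_f = 0` is the emptiness level at
which hunger starts rising again, so no refractory band is added.  One
variable per food type (rather than per nutrient class) matches how the
experiments were designed: foods were chosen so that birds satiated on
one food kept desiring another.  With an ad-libitum maintenance diet the
hunger equations are integrated as if every stomach were non-empty; no
individual eating events are simulated for the maintenance diet.

The propagation is piecewise exact: each interval is split at the
stomach-empty time `s_f τ_s` and, where the caching-weight gate needs
it, at the hunger-threshold crossing times, which are inverted from the
closed forms (`hunger_crossing_times()`).  The caching-modulated variant
adds a motivation variable `c_f` relaxing toward 1 with time constant
`τ_d` and depleted by `c_f c_0/τ_d` at each caching event — the jump is
implemented exactly as that amount (the published text states the
depletion amount; a literal delta-function reading of the differential
form would give the multiplicative factor `exp(-c_0/τ_d)` instead), and
clipped at zero for numerical safety even though the multiplicative form
cannot undershoot for `c_0/τ_d ≤ 1`.

Key parameters (defaults in `default_bird_parameters()`, allowed ranges
in `parameter_ranges()`): `τ_s` (0.5–10 min), `τ_d` (0–20 min), `τ_h`
(50–300 min), `n_f` (0.1–1).  The `τ → 0` limits are handled as
instantaneous relaxation.

## Associative memory with systems consolidation

Trays are encoded two-hot (one appearance neuron, one position neuron;
the two index ranges are disjoint so a tray always contributes exactly
two presynaptic neurons).  A caching event increments a consolidation
counter on the layer-1 synapses of both features; the binary effective
weight switches on one hour later, so a cache cannot be recalled within
the first hour.  A nightly tick advances every trace that is at least
one hour old through seven sub-networks with dwell times 1, 1, 1, 1, 3
and 8 days; layer 7 is terminal.  The layer of the active neuron at
recall therefore codes the age of the memory with intervals
[0,1), [1,2), [2,3), [3,4), [4,7), [7,15), [15,∞) days
(`age_to_layer()`).  Advancement requires only the one-hour encoding
delay at tick time; this is the reading consistent with a morning cache
being recalled from layer 4 three days later, which the degradation
experiments require.

Memories are one-hot in time: at most one layer holds a trace per
(food, feature) pair.  Re-caching at a site whose trace sits in a deeper
layer deletes the old trace and restarts at layer 1.  Each actual
inspection of a site decrements the counters of all foods stored at its
features by 1 (floored at zero), so sufficiently many inspections erase
the memory.  The published description indexes the decrement by food,
feature and layer without restricting the food; decrementing all foods
at the inspected site is our reading (an inspection examines the whole
site) and is configurable in principle — no main-text experiment
distinguishes the two.  Readout weights `v_f^(l)` (initialised at 1:
naive birds expect fresh food, which is why they search for previously
reliable food before experiencing degradation) learn the expected
freshness of age class `l` by the delta rule
`v ← v + α^fresh (φ^fresh − v)` after successful retrievals.

Partial feature matches recall at full strength: the clipped-linear
activation `σ(Σ w φ)` saturates at 1 already for a single active
synapse.  This falls out of the activation function; no main-text
experiment exercises it, and the fixtures avoid feature sharing.

## Decision making

At any instant the candidate set is `1 + n_f + n_f n_x + n_x` actions
(other, eat, cache, retrieve).  Preferences are clipped-linear:

* eat: `σ(v_f^eat h_f + η^eat)`, zero for remembered-only items (the
  food-indicator neuron gates perception);
* cache: `σ(w_{f,x_a} + w_{f,x_p} + v_f^cache h_f + η^cache)`; the
  unmodulated variant drops the hunger term, the caching-modulated
  variant replaces it by `v_f^cache c_f`, and the replay model replaces
  the two weight terms by `tanh(w_fx)`;
* inspect: `max_{f,l} σ(φ_f^(l) v_f^(l) + v_f^inspect h_f + η^inspect)`
  with `v_f^inspect = s^inspect v_f^eat`.

Selection is by rejection sampling: attend to one uniformly drawn
candidate, accept if its preference exceeds a fresh uniform threshold;
the induced distribution is proportional to the preferences.  `other` is
an ordinary competing candidate with constant preference `p^other`
(matching the published action count).  If every preference is zero the
loop cannot terminate, so it is capped at ten times the number of
candidates and `other` is forced with the minimal one-second wait,
flagged as a degenerate draw.

## Plasticity of the caching policy

Two mechanisms change the caching weights (one weight per food and tray
feature, both features updated identically — the caching preference sums
them, so the effective learning rate is doubled relative to a
single-feature model):

* At retrieval, recall reactivates the pre- and postsynaptic neurons of
  the recalled (food, site) pairs, and the outcome acts as the
  modulatory third factor: `Δw = -α^pilfer w` (empty site),
  `-α^degrade w` (degraded item), `+α^fresh p_f^eat (1-w)` (fresh item).
  If recall returns nothing (the bird never cached there, or the trace
  was erased), no update occurs.
* While hunger for food `f` exceeds the fixed gate `θ^hungry = 0.99` and
  a tray feature is perceived, the weight relaxes toward 1 with time
  constant `τ^hungry` — compensatory caching.  The gated time is
  accumulated exactly from the closed-form crossing times.

The retrieval-reward rate `α^reward` listed among the parameter ranges
appears in no displayed equation of the source model description; it is
kept as a parameter slot, unused by default.

## The planning-by-replay control model

The replay model stores an episodic list of memory items, each a
collection of tray–hunger–outcome triples; interactions less than one
hour apart share one item, with half-half hunger averaging and outcome
overwriting for a repeated tray.  Caching interactions and trays
perceived but never inspected during a wait are recorded with outcome
`not_inspected` (the wait-end bookkeeping is our choice; the source
description does not pin down the recording moment).  At a caching
decision the last three items are matched (exact tray sequences; with a
history shorter than three items the missing offsets contribute no
match, the only truncation that keeps the argmax defined; length
mismatches count as non-matches) and matched positions are replayed
forward over six items with discount `γ`.  The similarity weight as
printed adds the outcome-agreement indicator to the hunger distance, so
agreement *lowers* similarity; this is likely a sign slip, and the
package implements the formula as printed behind the flag
`similarity_outcome_sign = "as_printed"` with an `"agreement_rewards"`
alternative, defaulting to the printed form rather than silently
correcting it.  The threshold `θ` in the fresh-outcome term is not
specified in the source; it defaults to `θ^hungry = 0.99`
(`theta_replay`, configurable).  All other components (motivation,
associative memory, inspection policy) are shared unchanged with the
plastic model.

## The protocol language

Protocols are programs over three object types (food items, trays,
inspection observers) and eleven actions (add, remove, cover, uncover,
degrade, pilfer, the four counting measurements, wait).  Degrade sets
freshness to exactly 0 and leaves items eatable, so the bird can
encounter the degraded item and receive the negative freshness signal.
All experimenter actions happen out of sight: they never touch bird
state.  Each bird runs in its own cage; measurements are taken per bird
and summarised into group means and SEMs, and declared statistical tests
(paired t, Welch t, sign/binomial, one-way ANOVA — a minimal registry
covering two-group caching-count comparisons; the published experiments'
exact test lists are not in the main text) fill the p-value entries.
Linear (loop-free) protocols — which covers all shipped fixtures —
serialize to YAML and re-execute identically; arbitrary control flow is
available by writing protocols as R functions against the same step
vocabulary.  Item conservation (added = loose + cached + eaten +
pilfered + removed + discarded) is checked after every run.

A retrieved fresh item re-enters the loose food pool (it can be eaten or
re-cached, which recovery-session satiety requires); a degraded item is
discarded after the feedback.  When several items are cached in one
tray, a retrieval draws uniformly among them.  Birds may re-cache a
retrieved item in the same session; the source description is silent on
this and forbidding it would need an extra mechanism.

## Fixtures and the synthetic-data generator

Three protocols are reconstructed from their published main-text
descriptions; phase durations and item counts that are not printed there
are fixture parameters with defaults chosen once for clear mechanism
expression at realistic session scales (15–20-minute sessions, dozens of
items):

* `specific_satiety`: 150 min deprivation, 30 mealworms pre-fed for
  30 min with remaining counts at 10, 20 and 30 min (the late intake
  slope pins down the appetite time constant — an identifiability
  consideration made explicit below), then 15 mealworms + 15 peanuts
  with leftovers counted at 5 and 15 min; paired t-test on the two
  15-min leftovers.
* `dekort07_exp4`: two groups of four; worms cacheable only in tray A
  (tray B Perspex-covered), next-day recovery with tray A pilfered for
  one group, two such trials, then an open choice between A and B.
  Trays are emptied ("fresh substrate") before each caching choice, and
  the 20-min recovery sessions give birds time to recover all caches.
* `clayton03_exp2`: peanuts and crickets cached on days 1–3 in day-
  specific tray halves, recovered three days later with crickets
  degraded on days 4 and 5, and an unrewarded side-preference test on
  day 6.  Tray halves are modeled as separate trays with distinct
  appearance *and* position: the DSL has no sub-tray concept, and a
  shared position feature would let the fresh-peanut memory spill over
  to the cricket side through the position synapse, which the physical
  separation of the two halves prevents in the real experiment.

`generate_reference_data()` simulates a ground-truth population
(`ground_truth_scenario()`, e.g. `satiety_ground_truth()`: means around
`τ_h ≈ 174 min`, `v^eat ≈ 0.80/0.55`, `η^eat ≈ 0`) and selects the
medoid of K pseudo-datasets — the one with the smallest summed distance
to all others — as the synthetic reference table in the observed-data
CSV schema.  The medoid is a typical, actually achievable dataset with
natural sampling noise; an element-wise *average* table (available as
`method = "mean"`) turned out to bias likelihood-free fits toward
unrealistically concentrated populations, because a noise-free target
rewards populations that collapse onto whatever parameter values
reproduce the smooth average rather than the true spread.  This stands
in for published behavioral data so that fitting and reproducibility can
be exercised offline; everything it produces is synthetic.  What passing
tests on such data show is that the machinery recovers known populations
under the model's own assumptions — they cannot show that the model
captures real birds, seasonal effects, inter-experiment variability or
observation noise beyond what the simulator generates.

## Population parametrization and fitting

Each fitted parameter lives on a bounded interval and gets a beta
density via `θ = l + (u-l) z`, `z ~ Beta` with exponents `f(s)` and
`f(s+d)` (for `d < 0`; mirrored for `d ≥ 0`), `f(x) = log(exp(x)+1)-1`.
Since `f(x)+1` is the softplus, the shapes are always positive; `d = 0`
is symmetric and positive `d` shifts mass toward the lower bound (fixed
by quadrature tests).  Distances between summary datasets combine raw
differences on ordinary quantities with differences of five-level
quantized p-values (bands split at 0.001, 0.01, 0.05, 0.1 — a log-scale
surrogate that deliberately does not distinguish highly significant
p-values).  The log-likelihood is estimated from the distance to the
n-th nearest of K simulated datasets with the Kozachenko–Leonenko
normalization `ψ(n) − ψ(K) − log V_d`; the naive `log(n/K)` constant
carries a finite-n bias of `log n − ψ(n)` (about 0.10 at n = 5) that
the estimator's own consistency check would fail, so the digamma form is
used.  Exact ties are floored at `1e-12` with a warning.  Degenerate
simulated data (a t-test on constant values) yields p = 1: no evidence.

Optimization uses a minimal (μ/μ_w, λ) CMA-ES written for this package
(no suitable dependency was available), with a deliberately simple noise
schedule: after each generation the best candidate is re-evaluated once,
and if the re-evaluation ranks it below the generation median, the
repetition count K grows by 1.5× (bounded 5–500); otherwise it decays.
This captures the intent of uncertainty handling — spend simulations
only where the ranking is unstable — without replicating any specific
optimizer's internals; the schedule is deliberately conservative so the
simulation budget stays predictable.  Fits report the distribution mean
averaged over the last quarter of generations (a standard noise-robust
point estimate; both the terminal mean and the best-seen candidate are
noisier) and a final log-likelihood with an SEM from repeated
evaluation.

A note on experiment design: a pilot identifiability analysis (profiling
the k-NN log-likelihood along one population mean at a time) showed that
a satiety protocol with a single deprivation length and end-of-phase
counts carries almost no information about the appetite time constant.
The shipped fixture therefore measures a time-resolved pre-feed intake
curve, whose late slope reflects how quickly appetite recovers during
feeding; profiling such designs before running them is exactly the use
case the simulator is meant to serve.

## Problem sizes and numerical choices

The shipped test suite validates the closed forms against dense-time
forward-Euler oracles (1000 random parameter draws over one simulated
day; dt = 0.01 min for the motivational variables with the
stomach-empty switch split inside the step, dt = 0.1 s for the gated
weight growth).  The oracle draws keep the fastest time constants above
the Euler resolution (`τ_s ≥ 2`, `τ_d ≥ 5` min), because a first-order
method cannot certify a 1e-3 tolerance below that; the closed form is
exact for all τ, and the stiff limits are asserted separately as exact
limits in unit tests.  The recovery experiment fits four population
parameters (appetite time constant, two eating preferences, eating
bias; 8 hyperparameter dimensions) to an averaged reference table of
1000 pseudo-datasets with a 2000-evaluation CMA-ES budget, and the
mechanism regressions use 200 simulated repetitions per fixture.

## Known limitations

* Spatial movement, gaze and visual attention are not modeled; the
  attention loop is a probabilistic abstraction.
* Seasonal, ageing and other slow covariates are outside the model;
  populations are resampled independently per experiment unless a
  series explicitly shares birds (`run_protocol_series()`).
* The replay model's similarity weight follows the printed formula by
  default, including its questionable outcome-agreement sign (see
  above).
* Alternative age codes (associative chaining, time tagging, strength
  coding) are documented alternatives, not implemented.
* Only three exemplar protocols ship with the package; the DSL is
  expressive enough for the full published set, but reconstructing all
  of them (and their supplementary test lists) is out of scope.
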
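---
title: "An individual-patient cost-effectiveness model of adjunctive smoked cannabis for chronic neuropathic pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-patient cost-effectiveness model of adjunctive smoked cannabis for chronic neuropathic pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Chronic neuropathic pain is common, disabling, and often refractory to the
standard pharmacotherapy sequence (duloxetine, desipramine, gabapentin,
pregabalin). Smoked whole-plant cannabis has randomized-trial evidence of
modest analgesic benefit as an add-on, but - because U.S. health plans do not
cover it - its cost falls on patients. `canncea` implements an
individual-patient ("microsimulation") state-transition model that asks: from
a health care sector perspective (third-party payer plus out-of-pocket, 2017
USD), is it cost-effective to add smoked cannabis to therapy, and if so, at
which point in the treatment sequence?

Four strategies are compared: usual care (never add cannabis), and adjunctive
cannabis initiated with the first, second, or third standard-therapy line.
Effectiveness is measured in quality-adjusted life years (QALYs); strategies
are ranked on an incremental cost-effectiveness frontier with strict and
extended dominance, and uncertainty is handled by one-way (tornado) and
probabilistic sensitivity analysis (PSA).

## Model structure

Patients are simulated one 6-week cycle at a time over a 1-year base-case
horizon (5 and 10 years in scenario analyses). Each patient carries:

* baseline age ~ Normal(59.72, 9.79) truncated to 18+, which fixes an age
  band for serious-adverse-event (SAE) mortality and hospitalization costs;
* baseline pain ~ Normal(6.20, 1.52) on the 0-10 Likert scale, truncated to
  [4, 10]: every patient starts in the moderate-to-severe state (score >= 4);
* an agent sequence starting with duloxetine followed by a uniform random
  permutation of the other three agents;
* one adherence draw per agent (and for cannabis) from the agent's beta
  distribution, compared against the adherence threshold (0.8 base case) to
  give a fixed adherent/nonadherent flag per treatment episode;
* one pain-score-reduction draw per agent (and for cannabis) from the
  agent's normal distribution, fixed for the whole episode. Draws may be
  negative - the printed efficacy SDs exceed the means, so non-response and
  worsening are intended outcomes.

Within a cycle the patient is assessed stepwise:

1. **Adjunctive cannabis initiation.** Cannabis becomes active at the start
   of the cycle in which the patient's treatment line first reaches the
   strategy's start line; it can activate once and never restarts.
2. **Adverse events.** One severity class per cycle, from independent
   Bernoulli draws with precedence serious > intolerable > tolerable.
   Per-class probabilities depend on the regimen: the agent's published
   rates when the patient is adherent to the agent alone; odds-ratio
   modified nonserious/serious rates (OR 1.74 and 1.08; 2.07 and 1.77 in
   the non-user scenario) with intolerable risks combined independently
   when cannabis is co-used; the cannabis "monotherapy" rates (58.6% /
   4.6% / 0.5%) when the patient is adherent to cannabis but not the agent.
   Nonadherence disqualifies a patient from both relief and adverse events.
3. **Mortality.** A serious event draws death from the age-band SAE risk;
   decedents accrue that cycle's costs and half its QALY, then exit.
4. **Pain relief.** Achieved score = baseline minus the summed reductions of
   adhered-to components, floored at 0; strictly below 4 is "mild" (good
   relief), otherwise moderate-to-severe.
5. **Switching.** Two consecutive poor-relief cycles, an intolerable or
   serious event, or a per-component background discontinuation draw switch
   the patient to the next agent in their sequence.

Cannabis fails permanently on an intolerable/serious event or its own
discontinuation draw while being taken, or on two regimen-level poor-relief
cycles. Two structural choices here deserve emphasis, because the published
tables identify them where the prose does not:

* **Nonadherence does not stop cannabis purchases.** Falling below the
  adherence threshold removes relief and adverse-event exposure, but the
  prescription continues until a failure rule fires. A cannabis-nonadherent
  patient whose standard agent controls the pain therefore keeps buying
  cannabis without benefit. This is what makes the incremental
  cost-effectiveness ratio (ICER) roughly triple when mean cannabis
  adherence drops from 0.84 to its CI bound 0.78: the QALY gain collapses
  with the adherent fraction while spending does not.
* **Drug costs are purchase costs, not adherence-conditional costs.**
  Standard-agent wholesale and out-of-pocket costs accrue whenever the
  patient occupies an unexhausted line. Gating them on the adherence flag
  depresses cohort mean costs about 24% below the published totals.
* **The fourth line is absorbing.** A patient who fails the fourth agent
  stays on it (costs, relief chances and risks continue). A terminal
  "no-treatment" state instead halves the published 5-year cost totals and
  collapses the arms at 10 years.

## Economics

Costs and QALYs discount at 3%/year with the continuous-age convention,
`(1.03)^(-t)`, `t = cycle_index * 42 / 365.25`, applied at cycle start. The
cycle QALY is `(42 / 365.25) * max(0, u - d)` with utilities `u` 0.7 (mild) /
0.39 (moderate-to-severe) and decrements `d` 0.05 / 0.11 / 0.12 for
tolerable / intolerable / serious events. Monthly drug prices prorate by
`42 / 30.4375`. One office visit accrues every cycle ($111 + $51
out-of-pocket; the SAE visit $150 + $57 replaces it in SAE cycles), and a
serious event adds the age-band hospitalization plus $70 out-of-pocket.
Cannabis costs `daily_thc_g / 0.125 / (1 - wastage) * price_per_gram * 42`
per cycle: 0.536 g/day, about $249/cycle at $11.06/g in the base case, about
$408 with the 38.9% wastage scenario.

**Calendar discretization.** One year is treated as 52/6 cycles: 8 full
6-week cycles plus a final cycle with accrual weight 2/3 (44 cycles for 5
years, 87 for 10). This keeps the annual QALY ceiling at
`0.7 * (52/6) * 42/365.25 = 0.698 < 0.7`; event probabilities are not
rescaled in the fractional cycle.

## Parameters and their uncertainty

Every input lives in `inst/extdata/default_parameters.yaml` as a (name,
family, mean, dispersion) entry; no constant is hard-coded in an analysis
path. Beta and gamma families are fitted from the printed moments by the
method of moments; odds ratios sample on the log scale with
`sigma = (log hi - log lo) / (2 * 1.96)` from their 95% CIs; the cannabis
adherence SD is taken as a quarter of its CI width (0.03); the three utility
decrements use SD = mean/2; the adherence threshold is fixed at 0.8 in the
base case and Triangular(0.5, 0.8, 1.0) in the PSA - the mode is not
published and is taken to be the base-case value.

All sampling, patient-level and parameter-level, is by inverse-CDF
transforms of a single uniform stream with a fixed per-cycle draw layout.
Two runs with the same seed therefore consume identical randomness whatever
the parameter values: strategies are compared on common random numbers, and
a tornado endpoint that re-sets a parameter to its base value reproduces the
base ICER bit for bit.

**What the PSA redraws.** Entries whose printed dispersion is a standard
error or CI (adverse-event probabilities, odds ratios, SAE death risks,
costs, decrements, cannabis adherence) are redrawn every iteration. Entries
whose dispersion is between-patient heterogeneity - baseline age and pain,
the five pain-score reductions, the four standard-agent adherences, and the
two state utilities - are not: the microsimulation already integrates over
that variation patient by patient, and redrawing, say, the cannabis efficacy
mean from Normal(1.11, 2.38) double-counts it, making cannabis population-
harmful in a third of iterations and leaving usual care the most probable
strategy at every willingness-to-pay, contrary to the published
acceptability curves. The flag (`psa: false`) is per-entry in the parameter
file, so either convention is one edit away. Independent utility draws that
would invert the two pain states are reconciled by capping the
moderate-to-severe utility at the mild one. The PSA holds the cohort random
stream fixed across iterations and arms, so between-iteration variation is
parameter uncertainty alone; with all dispersions zeroed every iteration
reproduces the point-estimate run exactly.

## Numerical and degenerate-input choices

* Beta moment fits require `sd^2 < m(1-m)`; infeasible printed moments error
  by name. PSA-redrawn means can make a patient-level heterogeneity SD
  infeasible: the documented fallback clamps the mean into (0, 1) and the SD
  to 95% of the feasibility bound.
* Frontier ties (identical cost/QALY pairs) resolve by declared strategy
  order with a message; net-monetary-benefit ties in the acceptability
  curves resolve toward the cheaper strategy, so curve columns sum to one.
* Extended dominance removes a middle strategy when its incremental ICER is
  at least the next entry's (weak inequality, so collinear points drop and
  frontier ICERs increase strictly). The construction is cross-checked in
  the test suite against an independent net-monetary-benefit sweep oracle
  on 1,000 random instances.
* A pain response may be redrawn each cycle instead of fixed per episode
  (`redraw_response = TRUE`); the fixed-draw default makes the two-cycle
  poor-relief rule deterministic for non-responders and is the behaviour
  the published incremental QALYs support (per-cycle redraw shrinks the
  second-line QALY gain by an order of magnitude).

## Problem sizes

The headline analysis is defined at 1,000,000 patients per arm
(`run_cea()`'s default). The packaged acceptance workflow and test suite run
100,000 patients per arm for point-estimate analyses and 1,000 PSA
iterations of 10,000 patients - sizes at which the Monte-Carlo standard
error of a cohort mean is two orders of magnitude below the quantities
compared, so the reported numbers are stable to well under a percent.

## What the generator does and does not emulate

The cohort generator reproduces the statistical structure the analysis
assumes: the stated baseline moments, moderate-to-severe onset, fixed
per-episode response and adherence traits, and duloxetine-first sequencing.
It does not emulate real-world features outside the model: no background
(non-SAE) mortality, no disease progression or treatment tolerance, no
dose titration, no latent long-term cannabis harms, no societal costs.
Passing tests therefore certify the model's internal logic and its agreement
with the published analysis - not the clinical generalizability of those
assumptions.

## Known limitations

* The published long-horizon tables imply cannabis benefit persisting over
  years; under the printed per-cycle failure hazards (10.7%/cycle cannabis
  discontinuation plus intolerable/serious adverse-event rates) episodes
  last a few cycles, so this package's 5- and 10-year incremental QALYs are
  smaller than the published ones and the 10-year third-line ICER is
  substantially higher. The second- and third-line arms are correspondingly
  closer together here than published, which also shaves the second-line
  acceptability-curve probability. We chose the per-cycle reading
  consistently rather than mixing conventions to hit individual numbers.
* Visit schedule (every cycle) and the decedent's full-cycle cost accrual
  are modeling conventions the source tables constrain only loosely.
* The one-way analysis reports its own importance ordering; exact ordering
  of closely ranked parameters depends on unpublished interactions.

## Reproducing the analysis

```r
library(canncea)
specs <- load_parameter_specs()
params <- sample_parameter_set(specs, "point")

base <- run_cea(params, n_patients = 1e5, seed = 1)
base                      # frontier table
plot(base)                # cost-effectiveness plane

tor <- one_way_tornado(specs, n_patients = 2e4, seed = 1)
plot(tor)

psa <- run_psa(specs, n_iterations = 1000, n_patients = 10000, seed = 1)
plot(psa)                 # acceptability curves

run_scenario("horizon_10y", specs, n_patients = 1e5, seed = 1)
```

`scripts/acceptance.R` chains all of the above end to end; see the README.
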
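# canncea

Individual-patient cost-effectiveness microsimulation of **adjunctive smoked
cannabis for chronic neuropathic pain**, for health-economics and
health-services researchers.

Chronic neuropathic pain is treated with a sequence of standard agents
(duloxetine first, then desipramine, gabapentin or pregabalin in random
order), switched on poor pain relief or adverse events. `canncea` simulates
treatment-naive patients through that sequence in 6-week cycles and compares
four strategies: usual care, and smoked whole-plant cannabis (12.5% THC,
0.067 g THC/day, retail-priced) added at the first, second or third line.
Costs are 2017 USD from a U.S. health care sector perspective (payer +
out-of-pocket); effectiveness is in quality-adjusted life years (QALYs);
both discount at 3%/year.

Per cycle each living patient passes a node sequence: adjunctive-cannabis
initiation, adverse events (severity classes serious > intolerable >
tolerable, with odds-ratio modifiers under cannabis co-use and SAE mortality
by age band), pain relief (achieved score `max(0, baseline − Σ reductions)`;
below 4 is "mild"), and switching (two poor-relief cycles, an
intolerable/serious event, or background discontinuation). Strategies are
ranked on the incremental cost-effectiveness frontier:

* **strict dominance** — costlier and no more effective than an alternative;
* **extended dominance** — excluded because a more effective alternative has
  a lower incremental cost-effectiveness ratio (ICER = ΔC/ΔE, $/QALY);
  frontier ICERs increase strictly with effectiveness;
* **net monetary benefit** `wtp × QALY − cost` drives the probabilistic
  sensitivity analysis and its cost-effectiveness acceptability curves.

All inputs (baseline cohort moments, per-agent efficacy, adverse-event
probabilities, odds ratios, adherence, utilities, costs, cannabis pricing)
ship in `inst/extdata/default_parameters.yaml`; analyses never hard-code
them. Sampling is inverse-CDF throughout, so same-seed runs share every
random draw (common random numbers across strategies and sensitivity
endpoints).

## Worked example

```r
library(canncea)
specs  <- load_parameter_specs()            # published inputs, validated
params <- sample_parameter_set(specs, "point")
fit <- run_cea(params, n_patients = 1e5, seed = 7)
fit
#> Cost-effectiveness microsimulation: 1e+05 patients/arm, 1-year horizon
#> Cost-effectiveness frontier
#>              strategy  cost   QALY incr_cost incr_QALY                 ICER
#>            usual_care $6556 0.4793         -         -            reference
#>   first_line_cannabis $7242 0.4883         -         -            dominated
#>  second_line_cannabis $7161 0.4931      $605    0.0138          $43800/QALY
#>   third_line_cannabis $7044 0.4898         -         - extendedly_dominated
```

Read: usual care is the cheapest strategy ($6,556/patient-year, 0.479
QALYs). First-line cannabis is dominated (costlier and less effective than
second-line). Third-line is extendedly dominated (second-line buys QALYs at
a better rate). Second-line cannabis gains 0.0138 QALYs for $605, an ICER of
about $44,000/QALY — cost-effective against the common $100,000/QALY
willingness-to-pay benchmark.

Further entry points: `one_way_tornado()` (one-way sensitivity with the
published per-parameter ranges), `run_psa()` (probabilistic sensitivity
analysis + acceptability curves; `plot()` draws them), `run_scenario()`
(`horizon_5y`, `horizon_10y`, `nonuser_ors`, `wastage`), `simulate_patient()`
(single-patient ledger), and `load_config()`/`execute_run()`/
`write_results()` for YAML-configured batch runs. The methods vignette
(`vignettes/model-methods.Rmd`) documents the model, its parameters and its
design choices.

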
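# Cost and QALY accrual: discounting, cannabis pricing from THC dose and
# potency, and the per-cycle cost/utility bookkeeping.

#' Discount factor at the start of a cycle
#'
#' Continuous-age compounding: `(1 + rate)^(-t)` with
#' `t = cycle_index * cycle_days / 365.25` years.
#'
#' @param cycle_index Zero-based cycle counter.
#' @param rate Annual discount rate (0.03 in the base case).
#' @param cycle_days Cycle length in days (42).
#' @return Discount factor in (0, 1].
#' @examples
#' discount_factor(8, 0.03, 42)  # ~0.9732
#' @export
discount_factor <- function(cycle_index, rate = 0.03, cycle_days = 42) {
  if (any(rate < 0)) stop("discount rate must be nonnegative")
  if (any(cycle_index < 0)) stop("cycle_index must be nonnegative")
  (1 + rate)^(-(cycle_index * cycle_days / DAYS_PER_YEAR))
}

#' Cost of adjunctive cannabis for one cycle
#'
#' The grams purchased per day are the daily THC dose divided by the
#' product's THC fraction, inflated for wastage (the fraction of purchased
#' cannabis not consumed): `grams/day = daily_thc_g / thc_fraction /
#' (1 - wastage)`; the cycle cost is grams/day x price x cycle days.
#'
#' @param price_per_gram Retail price, USD per gram of flower.
#' @param daily_thc_g Daily THC dose in grams (0.067 in the base case).
#' @param thc_fraction THC content of the product (0.125).
#' @param wastage Fraction of purchased cannabis lost, in \[0, 1).
#' @param cycle_days Cycle length in days.
#' @return Cost in USD for one cycle.
#' @examples
#' cannabis_cycle_cost(11.06, 0.067, 0.125)          # ~249/cycle
#' cannabis_cycle_cost(11.06, 0.067, 0.125, 0.389)   # ~407/cycle with wastage
#' @export
cannabis_cycle_cost <- function(price_per_gram, daily_thc_g, thc_fraction,
                                wastage = 0, cycle_days = 42) {
  if (any(thc_fraction <= 0)) stop("thc_fraction must be positive")
  if (any(wastage < 0 | wastage >= 1)) stop("wastage must lie in [0, 1)")
  if (any(price_per_gram < 0) || any(daily_thc_g < 0))
    stop("price and dose must be nonnegative")
  grams_per_day <- daily_thc_g / thc_fraction / (1 - wastage)
  grams_per_day * price_per_gram * cycle_days
}

#' Accrue one cycle of discounted costs and QALYs
#'
#' The cycle QALY is time-in-cycle times the pain-state utility (0.7 mild,
#' 0.39 moderate-to-severe) minus the adverse-event decrement (0.05
#' tolerable, 0.11 intolerable, 0.12 serious), floored at 0, discounted at
#' the cycle-start factor; patients dying this cycle accrue half the cycle's
#' QALY. Costs accrued (all discounted, weighted by the cycle's calendar
#' weight): standard-agent wholesale and out-of-pocket monthly costs
#' prorated to the cycle length (only while adherent and not exhausted),
#' cannabis (only while active and adherent), one office visit per cycle
#' (the SAE visit replaces the regular visit in SAE cycles), and on a
#' serious event the age-band hospitalization plus its out-of-pocket share.
#' Drug and cannabis purchases accrue while the treatment is dispensed (on
#' an unexhausted line; cannabis active), irrespective of the adherence
#' flag: nonadherence (dose-taking below the threshold) removes relief and
#' adverse-event exposure, not expenditure.
#'
#' @param state Cohort state (see [advance_cycle()]).
#' @param outcome The cycle's outcome vectors (`alive`, `died`, `serious`,
#'   `intolerable`, `tolerable`, `mild`, `on_line`, `agent_ok`, `agent_idx`,
#'   `cannabis_active`, `cannabis_on`).
#' @param params A `cea_parameters` object.
#' @param cycle_index Zero-based cycle counter.
#' @param weight Accrual weight in (0, 1].
#' @return List with `costs` (five component vectors) and `qaly`.
#' @export
accrue_cycle <- function(state, outcome, params, cycle_index, weight = 1) {
  n <- length(outcome$alive)
  alive <- outcome$alive
  f <- discount_factor(cycle_index, params$discount_rate, params$cycle_days) * weight

  dec <- numeric(n)
  dec[outcome$tolerable] <- params$dec_tolerable
  dec[outcome$intolerable] <- params$dec_intolerable
  dec[outcome$serious] <- params$dec_serious
  u_state <- rep(params$u_modsev, n)
  u_state[outcome$mild] <- params$u_mild
  qaly <- (params$cycle_days / DAYS_PER_YEAR) * pmax(0, u_state - dec) * f
  qaly[outcome$died] <- qaly[outcome$died] * 0.5
  qaly[!alive] <- 0

  month_factor <- params$cycle_days / DAYS_PER_MONTH
  on_line <- as.numeric(outcome$on_line)
  drug_w <- params$wholesale_month[outcome$agent_idx] * on_line *
    (month_factor * f)
  drug_o <- params$oop_month[outcome$agent_idx] * on_line * (month_factor * f)
  cann_unit <- cannabis_cycle_cost(params$price_per_gram, params$daily_thc_g,
                                   params$thc_fraction, params$wastage_applied,
                                   params$cycle_days)
  cann <- (cann_unit * f) * outcome$cannabis_active
  visits <- ((params$visit_regular + params$visit_regular_oop) * f) * alive
  visits[outcome$serious] <- (params$visit_sae + params$visit_sae_oop) * f
  hosp <- numeric(n)
  hosp[outcome$serious] <- (params$hosp_cost[state$band][outcome$serious] +
                              params$hosp_oop) * f
  list(costs = list(drug_wholesale = drug_w, drug_oop = drug_o,
                    cannabis = cann, visits = visits, sae_hospital = hosp),
       qaly = qaly)
}
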
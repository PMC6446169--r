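# Cycle engine: per 6-week cycle each living patient is assessed stepwise for
# adverse events (with SAE-attributable mortality), pain relief, background
# discontinuation and drug switching, under one of four strategy arms. The
# state is held as patient-indexed vectors so one advance_cycle() call moves
# the whole cohort; a fixed block of uniform draws per cycle keeps the random
# stream aligned across strategies and sensitivity endpoints.

#' Treatment strategy arms
#'
#' The four arms compared by the analysis: usual care (cannabis never
#' started) and adjunctive cannabis initiated with the first, second or
#' third standard-therapy line.
#'
#' @return Named list of strategy definitions (`name`,
#'   `cannabis_start_line`; 0 means never).
#' @export
cea_strategies <- function() {
  list(
    usual_care = list(name = "usual_care", cannabis_start_line = 0L),
    first_line_cannabis = list(name = "first_line_cannabis", cannabis_start_line = 1L),
    second_line_cannabis = list(name = "second_line_cannabis", cannabis_start_line = 2L),
    third_line_cannabis = list(name = "third_line_cannabis", cannabis_start_line = 3L))
}

as_strategy <- function(x) {
  if (is.character(x)) {
    s <- cea_strategies()[[x]]
    if (is.null(s)) stop("unknown strategy: ", x)
    return(s)
  }
  stopifnot(is.list(x), !is.null(x$name), !is.null(x$cannabis_start_line))
  x
}

#' Apply an odds-ratio modifier to a probability
#'
#' Converts `p` to odds, multiplies by `or`, and converts back:
#' `or*p / (1 - p + or*p)`. Used to modify standard-agent adverse-event
#' probabilities under cannabis co-use.
#'
#' @param p Probability in \[0, 1\].
#' @param or Odds ratio, positive.
#' @return Modified probability.
#' @examples
#' apply_odds_ratio(0.66, 1.74)
#' @export
apply_odds_ratio <- function(p, or) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(or <= 0)) stop("odds ratio must be positive")
  or * p / (1 - p + or * p)
}

#' Classify the pain state achieved under active treatment
#'
#' The achieved score is the baseline minus the summed reductions of the
#' treatment components the patient is adherent to, floored at 0. A score
#' strictly below 4 is good relief (`"mild"`); 4 or above is
#' `"moderate_severe"`.
#'
#' @param baseline Baseline pain on the 0-10 scale.
#' @param active_reductions Numeric vector of reductions contributed by the
#'   active, adhered-to components (may be empty).
#' @return `"mild"` or `"moderate_severe"`.
#' @export
classify_pain_state <- function(baseline, active_reductions = numeric()) {
  if (any(baseline < 0 | baseline > 10)) stop("baseline pain must lie in [0, 10]")
  achieved <- max(0, baseline - sum(active_reductions))
  if (achieved < 4) "mild" else "moderate_severe"
}

# Effective per-cycle adverse-event probabilities (serious, intolerable,
# nonserious) for each patient given the regimen branch:
#   agent alone            -> the agent's published probabilities
#   agent + cannabis       -> nonserious/serious odds-modified; intolerable
#                             combined as 1 - (1-p_agent)(1-p_cannabis)
#   cannabis alone         -> cannabis "monotherapy" probabilities
#   neither (nonadherent)  -> zero (nonadherence disqualifies AEs)
effective_ae_probs <- function(on_agent, agent_idx, on_cannabis, params) {
  n <- length(on_agent)
  p_ser <- numeric(n); p_int <- numeric(n); p_ns <- numeric(n)
  pa_ser <- params$p_serious[agent_idx]
  pa_int <- params$p_intolerable[agent_idx]
  pa_ns <- params$p_nonserious[agent_idx]
  both <- on_agent & on_cannabis
  a_only <- on_agent & !on_cannabis
  c_only <- !on_agent & on_cannabis
  p_ser[a_only] <- pa_ser[a_only]
  p_int[a_only] <- pa_int[a_only]
  p_ns[a_only] <- pa_ns[a_only]
  if (any(both)) {
    p_ser[both] <- apply_odds_ratio(pa_ser[both], params$or_serious)
    p_ns[both] <- apply_odds_ratio(pa_ns[both], params$or_nonserious)
    p_int[both] <- 1 - (1 - pa_int[both]) * (1 - params$cannabis_p_intolerable_mono)
  }
  p_ser[c_only] <- params$cannabis_p_serious_mono
  p_int[c_only] <- params$cannabis_p_intolerable_mono
  p_ns[c_only] <- params$cannabis_p_nonserious_mono
  list(serious = p_ser, intolerable = p_int, nonserious = p_ns)
}

# Severity classification from three independent Bernoulli trials with
# precedence serious > intolerable > tolerable.
classify_ae <- function(u_ser, u_int, u_tol, probs) {
  ser <- u_ser < probs$serious
  int_ev <- !ser & (u_int < probs$intolerable)
  tol <- !ser & !int_ev & (u_tol < probs$nonserious)
  list(serious = ser, intolerable = int_ev, tolerable = tol)
}

#' Draw adverse-event classes for a homogeneous regimen
#'
#' Samples `n` per-cycle adverse-event outcomes for patients on the given
#' regimen: a standard agent alone, a standard agent with adjunctive
#' cannabis, cannabis alone (nonadherent to the agent), or nothing (fully
#' nonadherent patients experience no adverse events). Severity classes fire
#' as independent Bernoulli trials with precedence
#' serious > intolerable > tolerable.
#'
#' @param params A `cea_parameters` object.
#' @param agent Standard-agent name, or `NULL` if nonadherent to it.
#' @param cannabis `TRUE` if adherent to active adjunctive cannabis.
#' @param n Number of draws.
#' @return Character vector in `{"none","tolerable","intolerable","serious"}`.
#' @export
draw_adverse_events <- function(params, agent = NULL, cannabis = FALSE, n = 1) {
  on_agent <- rep(!is.null(agent), n)
  idx <- if (is.null(agent)) rep(1L, n) else {
    i <- match(agent, params$agents)
    if (is.na(i)) stop("unknown agent: ", agent)
    rep(i, n)
  }
  probs <- effective_ae_probs(on_agent, idx, rep(isTRUE(cannabis), n), params)
  cls <- classify_ae(stats::runif(n), stats::runif(n), stats::runif(n), probs)
  out <- rep("none", n)
  out[cls$tolerable] <- "tolerable"
  out[cls$intolerable] <- "intolerable"
  out[cls$serious] <- "serious"
  out
}

# Initial cohort state for one strategy arm.
init_cohort_state <- function(cohort, params, strategy,
                              redraw_response = FALSE) {
  n <- cohort$n
  tau <- params$adherence_threshold
  state <- list(
    n = n,
    pain = cohort$pain,
    band = cohort$band,
    seq_mat = cohort$seq_mat,
    resp = cohort$resp,
    resp_cannabis = cohort$resp_cannabis,
    adh_flag = cohort$adh >= tau,
    adh_flag_cannabis = cohort$adh_cannabis >= tau,
    alive = rep(TRUE, n),
    line = rep(1L, n),
    cann_state = rep(0L, n),  # 0 not_started, 1 active, 2 failed
    poor = rep(0L, n),
    mild = rep(FALSE, n),
    cycles = rep(0L, n),
    redraw_response = isTRUE(redraw_response),
    qaly = numeric(n),
    cost_drug_wholesale = numeric(n),
    cost_drug_oop = numeric(n),
    cost_cannabis = numeric(n),
    cost_visits = numeric(n),
    cost_sae_hospital = numeric(n))
  class(state) <- "cea_cohort_state"
  state
}

#' Advance a cohort one 6-week cycle
#'
#' Executes the per-cycle node logic for every living patient: adjunctive
#' cannabis is started when the patient's treatment line first reaches the
#' strategy's start line; adverse events are drawn for the components the
#' patient is adherent to (serious events carry an age-band death risk;
#' decedents exit the simulation); pain relief is evaluated from the
#' adhered-to response draws; background discontinuation is drawn per
#' component; patients switch to the next agent after two consecutive
#' poor-relief cycles, an intolerable or serious adverse event, or a
#' discontinuation draw (the fourth line is absorbing: patients failing it
#' remain on that agent, so treatment - and its costs, relief and risks -
#' continues through extended horizons). Cannabis fails permanently - it can
#' never restart - on intolerable/serious adverse events or its own
#' discontinuation draw while adherent ("while taking" the drug), or on two
#' regimen-level poor-relief cycles; nonadherence disqualifies relief and
#' adverse events but does not by itself end the prescription, so a
#' nonadherent patient whose standard agent controls the pain keeps
#' purchasing cannabis without benefiting. Costs and QALYs for the cycle are
#' accrued via [accrue_cycle()].
#'
#' @param state A `cea_cohort_state` from the internal initializer (see
#'   [run_cohort()]).
#' @param strategy A strategy (name or definition, see [cea_strategies()]).
#' @param params A `cea_parameters` object.
#' @param cycle_index Zero-based cycle counter (discounting uses it).
#' @param weight Accrual weight in (0, 1]; the final calendar-year cycle is
#'   fractional.
#' @return The updated state, with the cycle's outcome vectors in
#'   `$last_outcome`.
#' @export
advance_cycle <- function(state, strategy, params, cycle_index, weight = 1) {
  if (!any(state$alive)) stop("cannot advance: no living patients remain")
  strategy <- as_strategy(strategy)
  n <- state$n
  # fixed per-cycle random block (drawn for every patient, alive or not)
  u_ser <- stats::runif(n); u_int <- stats::runif(n); u_tol <- stats::runif(n)
  u_death <- stats::runif(n)
  u_disc_a <- stats::runif(n); u_disc_c <- stats::runif(n)
  if (state$redraw_response) {
    state$resp <- matrix(stats::qnorm(stats::runif(4L * n)), n, 4L) *
      rep(params$reduction_sd, each = n) + rep(params$reduction_mean, each = n)
    state$resp_cannabis <- params$cannabis_reduction_mean +
      params$cannabis_reduction_sd * stats::qnorm(stats::runif(n))
  }

  alive <- state$alive
  # cannabis initiation at the start of the cycle in which the start line begins
  if (strategy$cannabis_start_line > 0L) {
    starts <- alive & state$cann_state == 0L &
      state$line >= strategy$cannabis_start_line
    state$cann_state[starts] <- 1L
  }

  on_line <- alive
  cur <- state$seq_mat[cbind(seq_len(n), state$line)]
  agent_ok <- on_line & state$adh_flag[cbind(seq_len(n), cur)]
  cann_active <- alive & state$cann_state == 1L
  cann_on <- cann_active & state$adh_flag_cannabis

  probs <- effective_ae_probs(agent_ok, cur, cann_on, params)
  ae <- classify_ae(u_ser, u_int, u_tol, probs)
  died <- ae$serious & (u_death < params$death_risk[state$band])

  red <- state$resp[cbind(seq_len(n), cur)] * agent_ok +
    state$resp_cannabis * cann_on
  mild <- alive & (pmax(0, state$pain - red) < 4)

  disc_a <- agent_ok & (u_disc_a < params$discontinuation[cur])
  disc_c <- cann_on & (u_disc_c < params$cannabis_discontinuation)

  poor <- (state$poor + 1L) * as.integer(alive & !mild)
  ae_switch <- ae$serious | ae$intolerable

  outcome <- list(
    alive = alive, died = died, serious = ae$serious,
    intolerable = ae$intolerable, tolerable = ae$tolerable,
    mild = mild, on_line = on_line, agent_ok = agent_ok, agent_idx = cur,
    cannabis_active = cann_active, cannabis_on = cann_on)
  acc <- accrue_cycle(state, outcome, params, cycle_index, weight)
  state$qaly <- state$qaly + acc$qaly
  state$cost_drug_wholesale <- state$cost_drug_wholesale + acc$costs$drug_wholesale
  state$cost_drug_oop <- state$cost_drug_oop + acc$costs$drug_oop
  state$cost_cannabis <- state$cost_cannabis + acc$costs$cannabis
  state$cost_visits <- state$cost_visits + acc$costs$visits
  state$cost_sae_hospital <- state$cost_sae_hospital + acc$costs$sae_hospital

  survivor <- alive & !died
  switch_a <- survivor & on_line & (poor >= 2L | ae_switch | disc_a)
  # cannabis fails - permanently - on intolerable/serious events or its
  # discontinuation draw while being taken (adherent), or on two regimen-level
  # poor-relief cycles; nonadherence alone removes relief and AE exposure,
  # not the prescription
  cann_fail <- cann_active & !died &
    ((ae_switch & cann_on) | poor >= 2L | disc_c)

  state$cycles <- state$cycles + as.integer(alive)
  state$alive <- survivor
  # the fourth line is absorbing: a "switch" there restarts the same agent
  state$line <- pmin(state$line + as.integer(switch_a), 4L)
  poor[switch_a | poor >= 2L] <- 0L
  state$poor <- poor
  state$cann_state[cann_fail] <- 2L
  state$mild <- mild & survivor
  outcome$switched <- switch_a
  outcome$cannabis_failed <- cann_fail
  state$last_outcome <- outcome
  state
}

# Calendar discretization: one year is 52/6 six-week cycles, i.e. 8 full
# cycles plus a final fractional cycle whose accrual weight is 2/3.
cycle_schedule <- function(horizon_years, horizon_cycles = NULL) {
  if (!is.null(horizon_cycles)) {
    if (horizon_cycles < 1) stop("horizon_cycles must be >= 1")
    return(list(weights = rep(1, horizon_cycles)))
  }
  n_real <- horizon_years * 52 / 6
  full <- floor(n_real + 1e-9)
  frac <- n_real - full
  w <- rep(1, full)
  if (frac > 1e-6) w <- c(w, frac)
  list(weights = w)
}

#' Simulate one strategy arm over a cohort
#'
#' Draws a cohort and advances it cycle by cycle to the horizon, accruing
#' discounted costs and QALYs. Runs of different strategies (or of
#' sensitivity-analysis variants) that share a seed share every random draw
#' - cohort and per-cycle - so comparisons are paired (common random
#' numbers).
#'
#' @param strategy Strategy name or definition (see [cea_strategies()]).
#' @param n_patients Cohort size.
#' @param params A `cea_parameters` object.
#' @param horizon_years Time horizon in years (1, 5 and 10 in the analyses).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param horizon_cycles Optional override: simulate exactly this many full
#'   cycles instead of the calendar discretization.
#' @param redraw_response If `TRUE`, pain-response draws are redrawn every
#'   cycle instead of being fixed per agent episode (exploratory option; the
#'   default fixed-draw behaviour makes the two-cycle poor-relief rule fire
#'   deterministically for non-responders).
#' @param keep_patients If `TRUE`, attach the per-patient ledger data frame.
#' @param cohort Optional prebuilt cohort from [draw_cohort()]; when several
#'   arms share one cohort (as in the probabilistic sensitivity analysis)
#'   this avoids regenerating identical draws. The cohort's position in the
#'   random stream is skipped over, so results are identical to drawing
#'   inline under the same seed.
#' @return A `cea_strategy_result`: cohort means and Monte-Carlo standard
#'   errors of discounted cost and QALYs, plus mean cost components.
#' @export
run_cohort <- function(strategy, n_patients, params, horizon_years = 1,
                       seed = NULL, horizon_cycles = NULL,
                       redraw_response = FALSE, keep_patients = FALSE,
                       cohort = NULL) {
  strategy <- as_strategy(strategy)
  if (!is.null(seed)) set.seed(seed)
  sched <- cycle_schedule(horizon_years, horizon_cycles)
  if (is.null(cohort)) {
    cohort <- draw_cohort(n_patients, params)
  } else {
    stopifnot(cohort$n == n_patients)
    # discard the draws the cohort would have consumed: results are then
    # identical whether the cohort is drawn inline or supplied
    invisible(stats::runif(COHORT_RUNIF_BLOCKS * n_patients))
  }
  state <- init_cohort_state(cohort, params, strategy, redraw_response)
  for (k in seq_along(sched$weights)) {
    if (!any(state$alive)) break
    state <- advance_cycle(state, strategy, params, k - 1L, sched$weights[k])
  }
  summarize_state(state, strategy, n_patients, horizon_years, keep_patients)
}

summarize_state <- function(state, strategy, n_patients, horizon_years,
                            keep_patients = FALSE) {
  total <- state$cost_drug_wholesale + state$cost_drug_oop +
    state$cost_cannabis + state$cost_visits + state$cost_sae_hospital
  res <- list(
    strategy = strategy$name,
    n = n_patients,
    horizon_years = horizon_years,
    mean_cost = mean(total),
    mean_qaly = mean(state$qaly),
    se_cost = stats::sd(total) / sqrt(n_patients),
    se_qaly = stats::sd(state$qaly) / sqrt(n_patients),
    mean_components = c(
      drug_wholesale = mean(state$cost_drug_wholesale),
      drug_oop = mean(state$cost_drug_oop),
      cannabis = mean(state$cost_cannabis),
      visits = mean(state$cost_visits),
      sae_hospital = mean(state$cost_sae_hospital)),
    deaths = sum(!state$alive))
  if (keep_patients) {
    res$patients <- data.frame(
      cost_total = total,
      drug_wholesale = state$cost_drug_wholesale,
      drug_oop = state$cost_drug_oop,
      cannabis = state$cost_cannabis,
      visits = state$cost_visits,
      sae_hospital = state$cost_sae_hospital,
      qaly = state$qaly,
      cycles = state$cycles,
      alive = state$alive)
  }
  class(res) <- "cea_strategy_result"
  res
}

#' Simulate a single patient and return their ledger
#'
#' Runs the cycle engine for one patient, stopping at death or the horizon.
#'
#' @inheritParams run_cohort
#' @return A `PatientLedger`-style list: total discounted cost, its
#'   components, discounted QALYs and cycles survived.
#' @export
simulate_patient <- function(strategy, params, horizon_years = 1,
                             seed = NULL, horizon_cycles = NULL) {
  res <- run_cohort(strategy, 1L, params, horizon_years = horizon_years,
                    seed = seed, horizon_cycles = horizon_cycles,
                    keep_patients = TRUE)
  p <- res$patients
  list(discounted_cost_total = p$cost_total,
       cost_components = c(drug_wholesale = p$drug_wholesale,
                           drug_oop = p$drug_oop,
                           cannabis = p$cannabis,
                           visits = p$visits,
                           sae_hospital = p$sae_hospital),
       discounted_qalys = p$qaly,
       cycles_survived = p$cycles,
       alive = p$alive)
}

#' @export
print.cea_strategy_result <- function(x, ...) {
  cat(sprintf("%s: mean cost $%.2f (SE %.2f), mean QALYs %.4f (SE %.5f), n = %d, %g y\n",
              x$strategy, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly,
              x$n, x$horizon_years))
  invisible(x)
}
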
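# Synthetic cohort generation: treatment-naive patients with the joint
# structure the engine assumes. All sampling is by inverse-CDF transforms of
# runif() so the random-number layout is identical for any parameter values
# (common random numbers across strategies and sensitivity endpoints).

# Number of length-n uniform blocks one draw_cohort() call consumes (age,
# pain, 2 permutation draws, 5 adherence, 5 response); run_cohort() skips
# exactly this many when handed a prebuilt cohort so the per-cycle stream
# stays aligned with the inline path.
COHORT_RUNIF_BLOCKS <- 14L

# Truncated-normal draw via the inverse CDF.
qnorm_trunc <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Age bands 18-44, 45-64, 65-84, >=85 (ages below 18 never occur).
age_band_index <- function(age) findInterval(age, c(45, 65, 85)) + 1L

#' Draw a synthetic patient cohort
#'
#' Samples `n` treatment-naive patients: age from a normal distribution
#' truncated to 18+, baseline pain from a normal truncated to the
#' moderate-to-severe range 4-10 (every patient starts in moderate-to-severe
#' pain), an agent sequence starting with duloxetine followed by a uniform
#' random permutation of the other three standard agents, one adherence draw
#' per patient-agent (and for cannabis) from the agent's beta distribution,
#' and one pain-reduction response draw per patient-agent (and for cannabis)
#' from the agent's normal distribution. Response and adherence draws are
#' fixed at generation and reused for the whole episode on that agent.
#'
#' Consumes the current RNG stream; seed beforehand for reproducibility.
#'
#' @param n Number of patients.
#' @param params A `cea_parameters` object.
#' @return A list of patient-level vectors/matrices: `age`, `band`, `pain`,
#'   `seq_mat` (n x 4 agent indices), `adh`/`adh_cannabis` (adherence draws),
#'   `resp`/`resp_cannabis` (pain-score reduction draws).
#' @export
draw_cohort <- function(n, params) {
  stopifnot(n >= 1)
  age <- qnorm_trunc(stats::runif(n), params$age_mean, params$age_sd, lo = 18)
  pain <- qnorm_trunc(stats::runif(n), params$pain_mean, params$pain_sd,
                      lo = 4, hi = 10)
  # positions 2-4: uniform permutation of agents 2,3,4 in two fixed draws
  i1 <- pmin(floor(stats::runif(n) * 3) + 1L, 3L)
  first <- i1 + 1L
  rem_a <- ifelse(i1 == 1L, 3L, 2L)
  rem_b <- ifelse(i1 == 3L, 3L, 4L)
  swap <- stats::runif(n) < 0.5
  second <- ifelse(swap, rem_b, rem_a)
  third <- ifelse(swap, rem_a, rem_b)
  seq_mat <- cbind(rep(1L, n), first, second, third)
  colnames(seq_mat) <- NULL

  adh <- matrix(0, n, 4L)
  resp <- matrix(0, n, 4L)
  # near-degenerate beta shapes (sensitivity endpoints pushing a mean toward
  # 0/1) trip qbeta's accuracy warning; the clamped draws are still valid
  for (j in 1:4) {
    ab <- beta_pars_clamped(params$adherence_mean[j], params$adherence_sd[j],
                            paste0("adherence_", params$agents[j]))
    adh[, j] <- suppressWarnings(stats::qbeta(stats::runif(n), ab[1], ab[2]))
    resp[, j] <- params$reduction_mean[j] +
      params$reduction_sd[j] * stats::qnorm(stats::runif(n))
  }
  ab <- beta_pars_clamped(params$cannabis_adherence_mean,
                          params$cannabis_adherence_sd, "adherence_cannabis")
  adh_c <- suppressWarnings(stats::qbeta(stats::runif(n), ab[1], ab[2]))
  resp_c <- params$cannabis_reduction_mean +
    params$cannabis_reduction_sd * stats::qnorm(stats::runif(n))

  list(n = n, age = age, band = age_band_index(age), pain = pain,
       seq_mat = seq_mat, adh = adh, adh_cannabis = adh_c,
       resp = resp, resp_cannabis = resp_c)
}

#' Draw a single patient
#'
#' Convenience wrapper around [draw_cohort()] returning one patient in
#' record form, with adherence flags resolved against the adherence
#' threshold.
#'
#' @param params A `cea_parameters` object.
#' @return A list describing one patient: demographics, agent sequence (by
#'   name), per-agent response draws and adherence flags, and initial
#'   simulation state (alive, line 1, cannabis not started,
#'   moderate-to-severe pain).
#' @export
draw_patient <- function(params) {
  coh <- draw_cohort(1L, params)
  tau <- params$adherence_threshold
  band_labels <- c("18-44", "45-64", "65-84", ">=85")
  list(
    age = coh$age[1],
    age_band = band_labels[coh$band[1]],
    baseline_pain = coh$pain[1],
    agent_sequence = params$agents[coh$seq_mat[1, ]],
    response = stats::setNames(coh$resp[1, coh$seq_mat[1, ]],
                               params$agents[coh$seq_mat[1, ]]),
    adherent = stats::setNames(coh$adh[1, coh$seq_mat[1, ]] >= tau,
                               params$agents[coh$seq_mat[1, ]]),
    cannabis_response = coh$resp_cannabis[1],
    cannabis_adherent = coh$adh_cannabis[1] >= tau,
    alive = TRUE,
    current_line = 1L,
    cannabis_state = "not_started",
    poor_relief_cycles = 0L,
    pain_state = "moderate_severe")
}
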
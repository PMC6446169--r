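test_that("odds-ratio transform matches hand computations and fixed points", {
  expect_equal(unname(apply_odds_ratio(0.66, 1.74)), 0.771569, tolerance = 1e-5)
  expect_equal(apply_odds_ratio(0.66, 1), 0.66)
  expect_equal(apply_odds_ratio(0, 5), 0)
  expect_equal(apply_odds_ratio(1, 5), 1)
  expect_equal(apply_odds_ratio(0.024, 1.08), 0.025870, tolerance = 1e-4)
  expect_error(apply_odds_ratio(1.2, 1), "\\[0, 1\\]")
  expect_error(apply_odds_ratio(0.5, -1), "positive")
})

test_that("pain-state classification floors at zero and uses a strict cut", {
  expect_identical(classify_pain_state(6.20, 2.57), "mild")
  expect_identical(classify_pain_state(6.20), "moderate_severe")
  expect_identical(classify_pain_state(4.0, 0), "moderate_severe")  # boundary
  expect_identical(classify_pain_state(3.99), "mild")
  expect_identical(classify_pain_state(6, c(1, 0.5)), "moderate_severe")
  expect_identical(classify_pain_state(6, c(1, 0.5, 0.6)), "mild")
  expect_error(classify_pain_state(11), "\\[0, 10\\]")
})

test_that("adverse-event draws match closed-form probabilities by regimen", {
  n <- 1e5
  # fully nonadherent: never any adverse event
  set.seed(1)
  expect_true(all(draw_adverse_events(params_point, NULL, FALSE, n) == "none"))
  # agent + cannabis: serious frequency equals the odds-modified probability
  set.seed(2)
  cls <- draw_adverse_events(params_point, "duloxetine", TRUE, n)
  p_ser <- apply_odds_ratio(0.024, 1.08)
  expect_lt(abs(mean(cls == "serious") - p_ser),
            3 * sqrt(p_ser * (1 - p_ser) / n))
  # cannabis alone: the "monotherapy" serious rate
  set.seed(3)
  cls <- draw_adverse_events(params_point, NULL, TRUE, n)
  expect_lt(abs(mean(cls == "serious") - 0.005),
            3 * sqrt(0.005 * 0.995 / n))
  # precedence: intolerable frequency = P(intolerable fires, serious does not)
  set.seed(4)
  cls <- draw_adverse_events(params_point, "duloxetine", FALSE, n)
  p_int <- 0.157 * (1 - 0.024)
  expect_lt(abs(mean(cls == "intolerable") - p_int),
            3 * sqrt(p_int * (1 - p_int) / n))
})

test_that("two poor-relief cycles switch agents and time cannabis initiation", {
  # deterministic non-responder: duloxetine reduction 0, so the patient is
  # poor for cycles 0-1, switches at the end of cycle 1, and (second-line
  # arm) starts cannabis exactly when the second agent starts (cycle 2)
  p <- deterministic_params(means = c(reduction_duloxetine = 0,
                                      reduction_cannabis = 0))
  set.seed(6)
  coh <- draw_cohort(1L, p)
  st <- canncea:::init_cohort_state(coh, p, as_strategy("second_line_cannabis"))
  st <- advance_cycle(st, "second_line_cannabis", p, 0L)
  expect_identical(st$line, 1L)
  expect_identical(st$cann_state, 0L)
  expect_false(st$last_outcome$switched)
  st <- advance_cycle(st, "second_line_cannabis", p, 1L)
  expect_true(st$last_outcome$switched)      # two-cycle poor-relief rule
  expect_identical(st$line, 2L)
  expect_identical(st$cann_state, 0L)        # never earlier than line 2
  st <- advance_cycle(st, "second_line_cannabis", p, 2L)
  expect_identical(st$cann_state, 1L)        # active with the second agent
  expect_true(st$last_outcome$cannabis_active)

  # usual care never starts cannabis
  set.seed(6)
  coh <- draw_cohort(1L, p)
  st <- canncea:::init_cohort_state(coh, p, as_strategy("usual_care"))
  for (k in 0:8) st <- advance_cycle(st, "usual_care", p, k)
  expect_identical(st$cann_state, 0L)
})

test_that("a responding patient accrues the closed-form QALYs and costs", {
  # sure adherence, no adverse events, duloxetine reduction 3 on baseline 6:
  # mild from cycle 0 onward; QALYs and costs follow in closed form
  p <- deterministic_params()
  led <- simulate_patient("usual_care", p, horizon_years = 1, seed = 3)
  w <- c(rep(1, 8), 52 / 6 - 8)
  f <- (1.03)^(-(0:8) * 42 / 365.25)
  expect_equal(led$discounted_qalys,
               sum(w * f * 0.7 * 42 / 365.25), tolerance = 1e-9)
  expect_equal(led$cost_components[["drug_wholesale"]],
               sum(w * f) * 254 * 42 / 30.4375, tolerance = 1e-9)
  expect_equal(led$cost_components[["visits"]],
               sum(w * f) * (111 + 51), tolerance = 1e-9)
  expect_equal(led$cost_components[["sae_hospital"]], 0)
  expect_equal(led$cost_components[["cannabis"]], 0)
  expect_identical(led$cycles_survived, 9L)
})

test_that("horizon overrides validate and a single cycle accrues once", {
  p <- deterministic_params()
  expect_error(simulate_patient("usual_care", p, horizon_cycles = 0), ">= 1")
  led <- simulate_patient("usual_care", p, horizon_cycles = 1, seed = 3)
  expect_identical(led$cycles_survived, 1L)
  expect_equal(led$discounted_qalys, 0.7 * 42 / 365.25, tolerance = 1e-9)
})

test_that("a fully nonadherent patient churns without relief or AE costs", {
  adh <- c(paste0("adherence_", c("duloxetine", "desipramine", "gabapentin",
                                  "pregabalin")), "adherence_cannabis")
  p <- deterministic_params(means = stats::setNames(rep(0.01, 5), adh))
  led <- simulate_patient("usual_care", p, horizon_years = 1, seed = 8)
  w <- c(rep(1, 8), 52 / 6 - 8)
  f <- (1.03)^(-(0:8) * 42 / 365.25)
  # never mild: moderate-to-severe utility throughout
  expect_equal(led$discounted_qalys, sum(w * f * 0.39 * 42 / 365.25),
               tolerance = 1e-9)
  expect_equal(led$cost_components[["sae_hospital"]], 0)
  # prescriptions still fill: the poor-relief rule switches the line at the
  # end of every second cycle until the absorbing fourth line
  set.seed(8)
  coh <- draw_cohort(1L, p)
  st <- canncea:::init_cohort_state(coh, p, as_strategy("usual_care"))
  lines <- integer(9)
  for (k in 0:8) {
    st <- advance_cycle(st, "usual_care", p, k, if (k < 8) 1 else 52 / 6 - 8)
    lines[k + 1] <- st$line
  }
  expect_identical(lines, c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L))
})

test_that("cohort runs are deterministic under a seed and consistent across n", {
  a <- run_cohort("usual_care", 5000, params_point, seed = 123)
  b <- run_cohort("usual_care", 5000, params_point, seed = 123)
  expect_identical(a$mean_cost, b$mean_cost)
  expect_identical(a$mean_qaly, b$mean_qaly)
  big <- run_cohort("usual_care", 50000, params_point, seed = 124)
  expect_lt(abs(a$mean_cost - big$mean_cost),
            4 * sqrt(a$se_cost^2 + big$se_cost^2))
  expect_lt(abs(a$mean_qaly - big$mean_qaly),
            4 * sqrt(a$se_qaly^2 + big$se_qaly^2))
})

test_that("ledgers conserve cost components and respect the QALY ceiling", {
  r <- run_cohort("second_line_cannabis", 20000, params_point, seed = 31,
                  keep_patients = TRUE)
  p <- r$patients
  expect_equal(p$cost_total,
               p$drug_wholesale + p$drug_oop + p$cannabis + p$visits +
                 p$sae_hospital, tolerance = 1e-12)
  expect_true(all(p$qaly >= 0))
  expect_true(all(p$qaly <= 1 * 0.7 + 1e-12))
  expect_true(all(p$cost_total >= 0))
})

test_that("mortality flows only through the serious-AE pathway", {
  ser <- c(paste0("p_serious_", c("duloxetine", "desipramine", "gabapentin",
                                  "pregabalin")), "p_serious_cannabis_mono")
  p <- make_params(means = stats::setNames(rep(0, 5), ser))
  r <- run_cohort("first_line_cannabis", 20000, p, seed = 17,
                  keep_patients = TRUE)
  expect_true(all(r$patients$alive))
  expect_identical(r$deaths, 0L)
  expect_true(all(r$patients$sae_hospital == 0))
})

test_that("costs rise with cannabis price and QALYs with cannabis efficacy", {
  costs <- vapply(c(5.53, 11.06, 22.12), function(pr) {
    p <- set_parameter_values(params_point, c(price_per_gram = pr))
    run_cohort("first_line_cannabis", 20000, p, seed = 21)$mean_cost
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
  qalys <- vapply(c(0, 1.11, 3), function(rc) {
    p <- set_parameter_values(params_point, c(reduction_cannabis = rc))
    run_cohort("first_line_cannabis", 20000, p, seed = 22)$mean_qaly
  }, numeric(1))
  expect_true(all(diff(qalys) > 0))
})

test_that("advancing an extinct cohort errors", {
  p <- deterministic_params()
  set.seed(12)
  coh <- draw_cohort(1L, p)
  st <- canncea:::init_cohort_state(coh, p, as_strategy("usual_care"))
  st$alive <- FALSE
  expect_error(advance_cycle(st, "usual_care", p, 0L), "no living patients")
})
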
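pairwise <- function(params, n = 20000, seed = 71) {
  u <- run_cohort("usual_care", n, params, seed = seed)
  s <- run_cohort("second_line_cannabis", n, params, seed = seed)
  (s$mean_cost - u$mean_cost) / (s$mean_qaly - u$mean_qaly)
}

test_that("common random numbers make null overrides exactly reproducible", {
  base <- pairwise(params_point)
  # overriding a parameter with its own base value must reproduce the base
  # ICER bit for bit
  same <- pairwise(set_parameter_values(params_point, c(daily_thc_g = 0.067)))
  expect_identical(base, same)
  # a parameter with no pathway into the base-case model
  off <- pairwise(set_parameter_values(params_point, c(or_serious_nonuser = 4)))
  expect_identical(base, off)
})

test_that("one-way endpoints move the ICER in the documented directions", {
  base <- pairwise(params_point)
  lo_adh <- pairwise(set_parameter_values(params_point,
                                          c(adherence_cannabis = 0.78)))
  expect_gt(lo_adh, 1.5 * base)  # sharp rise at the CI lower bound
  hi_thc <- pairwise(set_parameter_values(params_point,
                                          c(daily_thc_g = 0.101)))
  expect_gt(hi_thc, base)
  expect_lt(hi_thc, 100000)      # stays cost-effective across the dose range
})

test_that("the tornado reports ranges per published rule and sorts by span", {
  tor <- one_way_tornado(specs_default, n_patients = 4000, seed = 5,
                         parameters = c("or_nonserious", "u_mild",
                                        "price_per_gram", "adherence_threshold",
                                        "p_nonserious_duloxetine",
                                        "cost_visit_regular"))
  expect_s3_class(tor, "cea_tornado")
  expect_true(all(tor$low_value < tor$high_value))
  r <- tor[tor$parameter == "or_nonserious", ]
  expect_equal(c(r$low_value, r$high_value), c(1.42, 2.14))
  r <- tor[tor$parameter == "u_mild", ]
  expect_equal(c(r$low_value, r$high_value), c(0.5, 0.9))
  r <- tor[tor$parameter == "p_nonserious_duloxetine", ]
  expect_equal(c(r$low_value, r$high_value), 0.66 * c(0.75, 1.25))
  r <- tor[tor$parameter == "adherence_threshold", ]
  expect_equal(c(r$low_value, r$high_value), c(0.5, 1.0))
  r <- tor[tor$parameter == "cost_visit_regular", ]
  expect_equal(c(r$low_value, r$high_value), 111 * c(0.5, 1.5))
})

test_that("degenerate specifications collapse the PSA onto the point run", {
  sp <- specs_default
  sp$family <- "point"
  psa <- run_psa(sp, n_iterations = 3, n_patients = 500,
                 wtp_grid = c(0, 1e5), seed = 9)
  for (s in colnames(psa$cost)) {
    expect_true(all(psa$cost[, s] == psa$cost[1, s]))
    expect_true(all(psa$qaly[, s] == psa$qaly[1, s]))
  }
  direct <- run_cohort("usual_care", 500, params_point,
                       seed = psa$cohort_seed)
  expect_equal(unname(psa$cost[1, "usual_care"]), direct$mean_cost)
  expect_equal(unname(psa$qaly[1, "usual_care"]), direct$mean_qaly)
})

test_that("PSA is reproducible and its CEAC is coherent", {
  a <- run_psa(specs_default, n_iterations = 5, n_patients = 400,
               wtp_grid = c(0, 5e4, 1e5), seed = 33)
  b <- run_psa(specs_default, n_iterations = 5, n_patients = 400,
               wtp_grid = c(0, 5e4, 1e5), seed = 33)
  expect_identical(a$cost, b$cost)
  pm <- as.matrix(a$ceac[, -1])
  expect_equal(unname(rowSums(pm)), rep(1, 3))
})

test_that("the base scenario is the identity and others override as named", {
  sc <- run_scenario("base", specs_default, n_patients = 5000, seed = 55)
  direct <- run_cea(params_point, n_patients = 5000, seed = 55)
  expect_equal(sc$frontier$mean_cost, direct$frontier$mean_cost)
  expect_equal(sc$frontier$mean_qaly, direct$frontier$mean_qaly)
  expect_error(run_scenario("no_such", specs_default, 100, 1), "unknown scenario")
})

test_that("wastage raises cannabis-arm costs and leaves usual care untouched", {
  n <- 10000
  base <- run_cea(params_point, n_patients = n, seed = 61)
  was <- run_scenario("wastage", specs_default, n_patients = n, seed = 61)
  bf <- base$frontier; wf <- was$frontier
  expect_identical(wf$mean_cost[wf$strategy == "usual_care"],
                   bf$mean_cost[bf$strategy == "usual_care"])
  for (s in c("first_line_cannabis", "second_line_cannabis",
              "third_line_cannabis"))
    expect_gt(wf$mean_cost[wf$strategy == s], bf$mean_cost[bf$strategy == s])
})

test_that("non-user odds ratios shrink the QALY gain and raise the cost gap", {
  n <- 50000
  base <- run_cea(params_point, n_patients = n, seed = 63)
  alt <- run_scenario("nonuser_ors", specs_default, n_patients = n, seed = 63)
  gap <- function(x, col) {
    fr <- x$frontier
    fr[[col]][fr$strategy == "second_line_cannabis"] -
      fr[[col]][fr$strategy == "usual_care"]
  }
  expect_lt(gap(alt, "mean_qaly"), gap(base, "mean_qaly"))
  expect_gt(gap(alt, "mean_cost"), gap(base, "mean_cost"))
})

test_that("the calendar discretization yields the documented cycle counts", {
  s1 <- canncea:::cycle_schedule(1)
  expect_length(s1$weights, 9)
  expect_equal(s1$weights[9], 52 / 6 - 8)
  s5 <- canncea:::cycle_schedule(5)
  expect_length(s5$weights, 44)
  expect_equal(s5$weights[44], 5 * 52 / 6 - 43)
  s10 <- canncea:::cycle_schedule(10)
  expect_length(s10$weights, 87)
  expect_equal(sum(s10$weights), 10 * 52 / 6)
})
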
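test_that("point mode reproduces the published means field for field", {
  p <- params_point
  expect_identical(unname(attr(p, "values")), specs_default$mean)
  # spot checks of structured fields against the published table
  expect_equal(p$age_mean, 59.72)
  expect_equal(p$pain_mean, 6.20)
  expect_equal(unname(p$reduction_mean),
               c(2.57, 1.99, 2.42, 2.59))
  expect_equal(p$cannabis_reduction_mean, 1.11)
  expect_equal(unname(p$p_nonserious["duloxetine"]), 0.660)
  expect_equal(p$cannabis_p_serious_mono, 0.005)
  expect_equal(p$or_nonserious, 1.74)
  expect_equal(p$or_serious_nonuser, 1.77)
  expect_equal(unname(p$adherence_mean), c(0.86, 0.76, 0.74, 0.69))
  expect_equal(p$cannabis_adherence_mean, 0.84)
  expect_equal(p$adherence_threshold, 0.8)
  expect_equal(c(p$u_mild, p$u_modsev), c(0.7, 0.39))
  expect_equal(c(p$dec_tolerable, p$dec_intolerable, p$dec_serious),
               c(0.05, 0.11, 0.12))
  expect_equal(unname(p$hosp_cost), c(7387, 9447, 9664, 8658))
  expect_equal(unname(p$wholesale_month), c(254, 236, 305, 485))
  expect_equal(p$price_per_gram, 11.06)
  expect_equal(p$daily_thc_g, 0.067)
  expect_equal(p$thc_fraction, 0.125)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$cycle_days, 42)
})

test_that("PSA draws are seed-reproducible and statistically match their specs", {
  set.seed(99)
  a <- sample_parameter_set(specs_default, "psa")
  set.seed(99)
  b <- sample_parameter_set(specs_default, "psa")
  expect_identical(attr(a, "values"), attr(b, "values"))

  n <- 20000
  draws <- matrix(0, n, nrow(specs_default))
  set.seed(7)
  for (k in seq_len(n))
    draws[k, ] <- canncea:::draw_spec_values(specs_default,
                                             runif(nrow(specs_default)))
  colnames(draws) <- specs_default$name
  # moment recovery for a redrawn beta and gamma entry
  expect_equal(mean(draws[, "discontinuation_cannabis"]), 0.107,
               tolerance = 0.002)
  expect_equal(sd(draws[, "discontinuation_cannabis"]), 0.021,
               tolerance = 0.002)
  expect_equal(mean(draws[, "price_per_gram"]), 11.06, tolerance = 0.1)
  expect_equal(sd(draws[, "price_per_gram"]), 3.78, tolerance = 0.1)
  # odds ratio quantiles recover the published 95% CI
  q <- quantile(draws[, "or_nonserious"], c(0.025, 0.975))
  expect_equal(unname(q), c(1.42, 2.14), tolerance = 0.03)
  # probabilities stay in the unit interval; threshold stays in its triangle
  prob_cols <- grep("^(p_|discontinuation_|adherence_[a-z])", specs_default$name)
  expect_true(all(draws[, prob_cols] >= 0 & draws[, prob_cols] <= 1))
  expect_true(all(draws[, "adherence_threshold"] >= 0.5 &
                    draws[, "adherence_threshold"] <= 1.0))
})

test_that("PSA pins heterogeneity entries and orders the two utilities", {
  set.seed(3)
  reps <- replicate(50, {
    p <- sample_parameter_set(specs_default, "psa")
    c(p$cannabis_reduction_mean, p$age_mean, p$u_mild - p$u_modsev,
      p$adherence_threshold, p$cannabis_adherence_mean)
  })
  expect_true(all(reps[1, ] == 1.11))   # efficacy mean not redrawn
  expect_true(all(reps[2, ] == 59.72))  # baseline age mean not redrawn
  expect_true(all(reps[3, ] >= 0))      # u_mild >= u_modsev in every draw
  expect_gt(sd(reps[4, ]), 0)           # threshold is redrawn
  expect_gt(sd(reps[5, ]), 0)           # cannabis adherence is redrawn
})

test_that("missing specification entries are reported by name", {
  vals <- stats::setNames(specs_default$mean, specs_default$name)
  vals <- vals[names(vals) != "u_mild"]
  expect_error(as_parameter_set(vals, specs_default), "u_mild")
})

test_that("parameter overrides rebuild a valid set and reject unknown names", {
  p2 <- set_parameter_values(params_point, c(adherence_cannabis = 0.78))
  expect_equal(p2$cannabis_adherence_mean, 0.78)
  expect_equal(p2$price_per_gram, 11.06)
  expect_error(set_parameter_values(params_point, c(not_a_param = 1)),
               "not_a_param")
})

test_that("VAS-to-Likert conversion is a division by ten with range checks", {
  expect_equal(convert_vas100_to_likert11(0), 0)
  expect_equal(convert_vas100_to_likert11(100), 10)
  expect_equal(convert_vas100_to_likert11(11.1), 1.11)
  expect_error(convert_vas100_to_likert11(101), "\\[0, 100\\]")
  expect_error(convert_vas100_to_likert11(-1), "\\[0, 100\\]")
})
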
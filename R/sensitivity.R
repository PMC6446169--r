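# Sensitivity machinery: one-way (tornado) analysis, probabilistic
# sensitivity analysis with acceptability curves, and the named scenario
# analyses (alternate horizons, non-user odds ratios, cannabis wastage).

# Pairwise incremental comparison of two strategy results (b vs a).
pairwise_icer <- function(res_ref, res_alt) {
  dc <- res_alt$mean_cost - res_ref$mean_cost
  dq <- res_alt$mean_qaly - res_ref$mean_qaly
  dominated <- dq <= 0 && dc >= 0
  list(incr_cost = dc, incr_qaly = dq,
       icer = if (dominated || dq == 0) NA_real_ else dc / dq,
       dominated = dominated)
}

# One-way range for a spec row under the published per-class rules.
sa_range <- function(spec_row) {
  s <- spec_row
  r <- switch(s$sa_rule,
    ci = c(s$ci_low, s$ci_high),
    pm_sd = s$mean + c(-1, 1) * s$dispersion,
    pm_25 = s$mean * c(0.75, 1.25),
    pm_50 = s$mean * c(0.5, 1.5),
    range = c(s$lo, s$hi),
    none = return(NULL))
  # clip to the parameter's natural support (open interval for beta means)
  if (s$family == "beta" && (r[1] < 0.001 || r[2] > 0.999)) {
    warning(sprintf("'%s': one-way endpoints clipped to the unit interval",
                    s$name))
    r <- pmin(pmax(r, 0.001), 0.999)
  }
  if (s$family %in% c("gamma", "log_odds_normal") && r[1] < 0) {
    warning(sprintf("'%s': one-way lower endpoint clipped to 0", s$name))
    r[1] <- max(r[1], 0)
  }
  r
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies one parameter at a time over its published sensitivity range -
#' odds ratios and cannabis adherence over their 95% CIs; mild-pain utility,
#' cannabis price, daily THC dose and standard-agent adherence over +/- 1
#' SD; the adherence threshold over 0.5-1.0; nonserious adverse-event
#' probabilities over +/- 25%; everything else over +/- 50% - holding all
#' other parameters at their point estimates, and reports the pairwise ICER
#' of second-line adjunctive cannabis versus usual care at each endpoint.
#' All runs share the same seed (common random numbers), so endpoint ICERs
#' differ only through the varied parameter.
#'
#' @param specs A `cea_spec_table`.
#' @param n_patients Cohort size per run.
#' @param seed Integer seed shared by every run.
#' @param parameters Names of parameters to vary; defaults to every entry
#'   with a sensitivity rule.
#' @param horizon_years Time horizon.
#' @return A `cea_tornado` data frame sorted by decreasing ICER span:
#'   parameter, endpoint values, ICER at each endpoint (NA when second-line
#'   cannabis is dominated at that endpoint), and the base-case ICER as an
#'   attribute.
#' @export
one_way_tornado <- function(specs, n_patients = 20000, seed = 1,
                            parameters = NULL, horizon_years = 1) {
  base_params <- sample_parameter_set(specs, "point")
  pair <- function(params) {
    ref <- run_cohort("usual_care", n_patients, params, horizon_years, seed = seed)
    alt <- run_cohort("second_line_cannabis", n_patients, params, horizon_years,
                      seed = seed)
    pairwise_icer(ref, alt)
  }
  base <- pair(base_params)
  if (is.null(parameters))
    parameters <- specs$name[specs$sa_rule != "none"]
  rows <- list()
  for (nm in parameters) {
    i <- match(nm, specs$name)
    if (is.na(i)) stop("unknown parameter: ", nm)
    r <- sa_range(specs[i, ])
    if (is.null(r)) next
    ends <- lapply(r, function(v) {
      pair(set_parameter_values(base_params, stats::setNames(v, nm)))
    })
    rows[[nm]] <- data.frame(
      parameter = nm, low_value = r[1], high_value = r[2],
      icer_at_low = ends[[1]]$icer, icer_at_high = ends[[2]]$icer,
      dominated_at_low = ends[[1]]$dominated,
      dominated_at_high = ends[[2]]$dominated,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  span <- abs(ifelse(out$dominated_at_high, Inf, out$icer_at_high) -
                ifelse(out$dominated_at_low, -Inf, out$icer_at_low))
  out <- out[order(-span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  attr(out, "n_patients") <- n_patients
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Reruns the model `n_iterations` times, redrawing every parameter from its
#' sampling distribution at each iteration (the adherence threshold from
#' Triangular(0.5, 0.8, 1.0)); within an iteration all four strategy arms
#' are simulated with common random numbers. The cohort random stream is
#' also shared across iterations, so between-iteration variation reflects
#' parameter uncertainty alone. Results feed the cost-effectiveness
#' acceptability curves via [ceac()].
#'
#' @param specs A `cea_spec_table`.
#' @param n_iterations Number of parameter draws (10,000 in the full
#'   analysis).
#' @param n_patients Cohort size per iteration per arm.
#' @param horizon_years Time horizon.
#' @param wtp_grid Willingness-to-pay thresholds for the acceptability
#'   curves, USD/QALY.
#' @param seed Master seed.
#' @return A `cea_psa`: iteration-by-strategy cost and QALY matrices, the
#'   acceptability curves, and run settings.
#' @export
run_psa <- function(specs, n_iterations = 10000, n_patients = 10000,
                    horizon_years = 1, wtp_grid = seq(0, 200000, by = 10000),
                    seed = 1) {
  stopifnot(n_iterations >= 1)
  set.seed(seed)
  par_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  cohort_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  strategies <- names(cea_strategies())
  cost <- matrix(0, n_iterations, length(strategies),
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (i in seq_len(n_iterations)) {
    set.seed(par_seeds[i])
    ps <- sample_parameter_set(specs, "psa")
    set.seed(cohort_seed)
    coh <- draw_cohort(n_patients, ps)
    for (s in strategies) {
      r <- run_cohort(s, n_patients, ps, horizon_years, seed = cohort_seed,
                      cohort = coh)
      cost[i, s] <- r$mean_cost
      qaly[i, s] <- r$mean_qaly
    }
  }
  out <- list(cost = cost, qaly = qaly,
              ceac = ceac(cost, qaly, wtp_grid),
              wtp_grid = wtp_grid, n_iterations = n_iterations,
              n_patients = n_patients, horizon_years = horizon_years,
              seed = seed, cohort_seed = cohort_seed)
  class(out) <- "cea_psa"
  out
}

scenario_names <- function() {
  c("base", "horizon_5y", "horizon_10y", "nonuser_ors", "wastage")
}

#' Run a named scenario analysis
#'
#' Scenarios: `base` (identity), `horizon_5y` / `horizon_10y` (extended
#' time horizons), `nonuser_ors` (adverse-event odds ratios estimated after
#' excluding active cannabis users: 2.07 nonserious, 1.77 serious),
#' `wastage` (cannabis purchase quantity inflated for the measured wastage
#' fraction). All four arms are rerun at point estimates and summarised as
#' a frontier.
#'
#' @param name Scenario name (see above).
#' @param specs A `cea_spec_table`.
#' @param n_patients Cohort size per arm.
#' @param seed Integer seed shared across arms.
#' @return A `cea_run` (see [run_cea()]) with a `scenario` element.
#' @export
run_scenario <- function(name, specs, n_patients = 100000, seed = 1) {
  if (!name %in% scenario_names())
    stop("unknown scenario '", name, "'; expected one of: ",
         paste(scenario_names(), collapse = ", "))
  params <- sample_parameter_set(specs, "point")
  horizon <- 1
  if (name == "horizon_5y") horizon <- 5
  if (name == "horizon_10y") horizon <- 10
  if (name == "nonuser_ors") {
    vals <- attr(params, "values")
    params <- set_parameter_values(params, c(
      or_nonserious = unname(vals[["or_nonserious_nonuser"]]),
      or_serious = unname(vals[["or_serious_nonuser"]])))
  }
  if (name == "wastage") params$wastage_applied <- params$cannabis_wastage
  out <- run_cea(params, n_patients = n_patients, horizon_years = horizon,
                 seed = seed)
  out$scenario <- name
  out
}

#' @export
print.cea_tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%.0f/QALY, n = %d per run)\n",
              attr(x, "base_icer"), attr(x, "n_patients")))
  y <- data.frame(
    parameter = x$parameter,
    low = signif(x$low_value, 4), high = signif(x$high_value, 4),
    icer_low = ifelse(x$dominated_at_low, "dominated",
                      sprintf("%.0f", x$icer_at_low)),
    icer_high = ifelse(x$dominated_at_high, "dominated",
                       sprintf("%.0f", x$icer_at_high)))
  print(utils::head(y, 10), row.names = FALSE)
  if (nrow(y) > 10) cat("...", nrow(y) - 10, "more parameters\n")
  invisible(x)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations x %d patients, %g y\n",
              x$n_iterations, x$n_patients, x$horizon_years))
  i100 <- which.min(abs(x$ceac$wtp - 100000))
  probs <- unlist(x$ceac[i100, -1])
  cat(sprintf("  at $%s/QALY most likely cost-effective: %s (%.0f%%)\n",
              format(x$ceac$wtp[i100], big.mark = ","),
              names(probs)[which.max(probs)], 100 * max(probs)))
  invisible(x)
}

#' @export
plot.cea_psa <- function(x, ...) {
  k <- ncol(x$ceac) - 1
  cols <- grDevices::hcl.colors(k, "Dark 2")
  graphics::matplot(x$ceac$wtp / 1000, as.matrix(x$ceac[, -1]), type = "l",
                    lty = 1, lwd = 2, col = cols,
                    xlab = "Willingness to pay ($1,000/QALY)",
                    ylab = "Probability most cost-effective",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = names(x$ceac)[-1], col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.cea_tornado <- function(x, top = 8, ...) {
  y <- utils::head(x, top)
  base <- attr(x, "base_icer")
  lo <- ifelse(y$dominated_at_low, NA, y$icer_at_low)
  hi <- ifelse(y$dominated_at_high, NA, y$icer_at_high)
  rng <- range(c(lo, hi, base), na.rm = TRUE)
  n <- nrow(y)
  graphics::plot(NULL, xlim = rng, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER, second-line cannabis vs usual care ($/QALY)",
                 ylab = "", ...)
  graphics::axis(2, at = rev(seq_len(n)), labels = y$parameter, las = 1,
                 cex.axis = 0.7)
  for (i in seq_len(n)) {
    a <- if (is.na(lo[i])) rng[1] else lo[i]
    b <- if (is.na(hi[i])) rng[2] else hi[i]
    graphics::rect(min(a, b), rev(seq_len(n))[i] - 0.3,
                   max(a, b), rev(seq_len(n))[i] + 0.3, col = "steelblue")
  }
  graphics::abline(v = base, lty = 2)
  invisible(x)
}
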
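#' Run the full cost-effectiveness comparison
#'
#' Simulates every strategy arm over the same cohort random stream (common
#' random numbers) and summarises the result as an incremental
#' cost-effectiveness frontier.
#'
#' @param params A `cea_parameters` object, e.g.
#'   `sample_parameter_set(load_parameter_specs(), "point")`.
#' @param n_patients Cohort size per arm (the headline analysis uses
#'   1,000,000).
#' @param horizon_years Time horizon in years.
#' @param seed Integer seed shared across arms.
#' @param strategies Strategy definitions; defaults to all four arms.
#' @return A `cea_run`: per-strategy results, the frontier, and run
#'   settings.
#' @examples
#' \donttest{
#' specs <- load_parameter_specs()
#' params <- sample_parameter_set(specs, "point")
#' fit <- run_cea(params, n_patients = 20000, seed = 1)
#' fit
#' }
#' @export
run_cea <- function(params, n_patients = 1000000, horizon_years = 1,
                    seed = 1, strategies = cea_strategies()) {
  results <- lapply(strategies, function(s) {
    run_cohort(s, n_patients, params, horizon_years = horizon_years,
               seed = seed)
  })
  out <- list(results = results,
              frontier = build_frontier(results),
              n_patients = n_patients, horizon_years = horizon_years,
              seed = seed)
  class(out) <- "cea_run"
  out
}

#' @export
print.cea_run <- function(x, ...) {
  cat(sprintf("Cost-effectiveness microsimulation: %s patients/arm, %g-year horizon\n",
              format(x$n_patients, big.mark = ","), x$horizon_years))
  if (!is.null(x$scenario)) cat("  scenario:", x$scenario, "\n")
  print(x$frontier)
  invisible(x)
}

#' @export
summary.cea_run <- function(object, ...) {
  fr <- object$frontier
  se <- do.call(rbind, lapply(object$results, function(r) {
    data.frame(strategy = r$strategy, se_cost = r$se_cost, se_qaly = r$se_qaly)
  }))
  out <- merge(as.data.frame(fr), se, by = "strategy", sort = FALSE)
  out <- out[match(fr$strategy, out$strategy), ]
  rownames(out) <- NULL
  out
}

#' @export
plot.cea_run <- function(x, ...) {
  fr <- x$frontier
  graphics::plot(fr$mean_qaly, fr$mean_cost,
                 pch = 19, col = ifelse(fr$status %in% c("reference", "on_frontier"),
                                        "firebrick", "grey40"),
                 xlab = "Mean QALYs per patient",
                 ylab = "Mean cost per patient ($)", ...)
  on <- fr[fr$status %in% c("reference", "on_frontier"), ]
  on <- on[order(on$mean_cost), ]
  graphics::lines(on$mean_qaly, on$mean_cost, col = "firebrick")
  graphics::text(fr$mean_qaly, fr$mean_cost, labels = fr$strategy,
                 pos = 3, cex = 0.7)
  invisible(x)
}
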
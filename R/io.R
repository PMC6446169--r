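# Configuration and serialization: validated YAML run configuration,
# orchestration of the four run modes, and CSV/JSON result writers.

config_defaults <- function() {
  list(parameter_file = default_parameter_file(),
       mode = "base",
       n_patients = 100000,
       n_iterations = 1000,
       horizon_years = 1,
       seed = NULL,
       out_dir = NULL,
       scenario = NULL,
       wtp_grid = seq(0, 200000, by = 10000),
       overwrite = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration. Recognised keys: `parameter_file`,
#' `mode` (`base`, `tornado`, `psa`, `scenario`), `n_patients`,
#' `n_iterations`, `horizon_years`, `seed` (mandatory - every mode is
#' stochastic), `out_dir`, `scenario`, `wtp_grid`, `overwrite`. Unknown
#' keys are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cea_run_config` list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$mode %in% c("base", "tornado", "psa", "scenario"))
    stop("mode: must be one of base, tornado, psa, scenario")
  if (is.null(cfg$seed))
    stop("seed: a seed is mandatory for every (stochastic) run mode")
  cfg$seed <- as.integer(cfg$seed)
  for (nm in c("n_patients", "n_iterations"))
    if (cfg[[nm]] < 1) stop(nm, ": must be a positive integer")
  if (cfg$horizon_years <= 0) stop("horizon_years: must be positive")
  if (cfg$mode == "scenario") {
    if (is.null(cfg$scenario) || !cfg$scenario %in% scenario_names())
      stop("scenario: must name one of: ",
           paste(scenario_names(), collapse = ", "))
  }
  if (!file.exists(cfg$parameter_file))
    stop("parameter_file: not found: ", cfg$parameter_file)
  cfg$wtp_grid <- as.numeric(unlist(cfg$wtp_grid))
  class(cfg) <- "cea_run_config"
  cfg
}

#' Execute a configured run
#'
#' Dispatches on the configuration's `mode`, runs the corresponding
#' analysis, and (when `out_dir` is set) writes results via
#' [write_results()].
#'
#' @param config A `cea_run_config` from [load_config()].
#' @return The analysis result object (`cea_run`, `cea_tornado` or
#'   `cea_psa`), invisibly when written to disk.
#' @export
execute_run <- function(config) {
  stopifnot(inherits(config, "cea_run_config"))
  specs <- load_parameter_specs(config$parameter_file)
  res <- switch(config$mode,
    base = run_cea(sample_parameter_set(specs, "point"),
                   n_patients = config$n_patients,
                   horizon_years = config$horizon_years, seed = config$seed),
    tornado = one_way_tornado(specs, n_patients = config$n_patients,
                              seed = config$seed,
                              horizon_years = config$horizon_years),
    psa = run_psa(specs, n_iterations = config$n_iterations,
                  n_patients = config$n_patients,
                  horizon_years = config$horizon_years,
                  wtp_grid = config$wtp_grid, seed = config$seed),
    scenario = run_scenario(config$scenario, specs,
                            n_patients = config$n_patients,
                            seed = config$seed))
  if (!is.null(config$out_dir)) {
    write_results(res, config$out_dir, overwrite = isTRUE(config$overwrite),
                  config = config)
    return(invisible(res))
  }
  res
}

check_writable <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file (use overwrite = TRUE): ", path)
  invisible(path)
}

frontier_table <- function(x) {
  fr <- as.data.frame(x$frontier)
  data.frame(
    strategy = fr$strategy,
    avg_cost = sprintf("%.2f", fr$mean_cost),
    avg_qaly = sprintf("%.4f", fr$mean_qaly),
    incr_cost = ifelse(is.na(fr$incr_cost), "", sprintf("%.2f", fr$incr_cost)),
    incr_qaly = ifelse(is.na(fr$incr_qaly), "", sprintf("%.4f", fr$incr_qaly)),
    icer = ifelse(is.na(fr$icer), "", sprintf("%.2f", fr$icer)),
    status = fr$status,
    stringsAsFactors = FALSE)
}

#' Write analysis results to disk
#'
#' Serialises a result object as plain CSV files (costs to cents, QALYs to
#' four decimals) plus a JSON run manifest recording the seed, settings and
#' package version. Existing files are never overwritten unless
#' `overwrite = TRUE`. Identical runs produce byte-identical files.
#'
#' @param x A `cea_run`, `cea_tornado` or `cea_psa` object.
#' @param dir Output directory (created if missing).
#' @param overwrite Allow replacing existing files.
#' @param config Optional `cea_run_config` echoed into the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, overwrite = FALSE, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    check_writable(path, overwrite)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  if (inherits(x, "cea_run")) {
    wcsv(frontier_table(x), "frontier.csv")
  } else if (inherits(x, "cea_tornado")) {
    df <- as.data.frame(x)
    df$icer_at_low <- ifelse(df$dominated_at_low, "", sprintf("%.2f", df$icer_at_low))
    df$icer_at_high <- ifelse(df$dominated_at_high, "", sprintf("%.2f", df$icer_at_high))
    wcsv(df, "tornado.csv")
  } else if (inherits(x, "cea_psa")) {
    cc <- as.data.frame(x$ceac)
    cc[-1] <- lapply(cc[-1], function(p) sprintf("%.6f", p))
    wcsv(cc, "ceac.csv")
    draws <- data.frame(iteration = seq_len(nrow(x$cost)))
    for (s in colnames(x$cost)) {
      draws[[paste0("cost_", s)]] <- sprintf("%.2f", x$cost[, s])
      draws[[paste0("qaly_", s)]] <- sprintf("%.4f", x$qaly[, s])
    }
    wcsv(draws, "psa_draws.csv")
  } else stop("no writer for objects of class ", class(x)[1])

  config_hash <- if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    saveRDS(unclass(config), tf)
    unname(tools::md5sum(tf))
  }
  manifest <- list(
    package = "canncea",
    version = as.character(utils::packageVersion("canncea")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    result_class = class(x)[1],
    seed = if (!is.null(config)) config$seed else x$seed,
    config_hash = config_hash,
    settings = if (!is.null(config)) unclass(config) else NULL)
  path <- file.path(dir, "manifest.json")
  check_writable(path, overwrite)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  written <- c(written, path)
  invisible(written)
}
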
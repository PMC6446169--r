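# Parameter specification table and realized parameter sets.
#
# Every model input lives in a YAML file as a (name, family, mean, dispersion)
# entry; the package ships a default file transcribing the published inputs.
# `sample_parameter_set()` turns the table into a realized parameter set,
# either at the point estimates or as one probabilistic-sensitivity draw.

STANDARD_AGENTS <- c("duloxetine", "desipramine", "gabapentin", "pregabalin")
AGE_BANDS <- c("18_44", "45_64", "65_84", "85_plus")
DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25

#' Path to the default parameter file
#'
#' @return Path of the YAML file shipped with the package that transcribes the
#'   published model inputs (baseline cohort moments, per-agent efficacy and
#'   adverse-event probabilities, odds-ratio modifiers, adherence, utilities,
#'   costs and cannabis pricing).
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_parameters.yaml", package = "canncea",
              mustWork = TRUE)
}

#' Load a parameter specification table
#'
#' Reads and validates a YAML parameter file. Each entry defines a named
#' model input with a sampling family (`normal`, `beta`, `gamma`,
#' `triangular`, `log_odds_normal` or `point`), a point estimate, a
#' dispersion (SD or SE as published), optional 95% CI or triangular bounds,
#' and a one-way sensitivity range rule.
#'
#' @param file Path to a YAML parameter file; defaults to the shipped file.
#' @return A `cea_spec_table` data frame, one row per parameter.
#' @export
load_parameter_specs <- function(file = default_parameter_file()) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw$parameters))
    stop("parameter file has no top-level 'parameters' list: ", file)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr_or <- function(x, default) if (is.null(x)) default else as.character(x)
  rows <- lapply(raw$parameters, function(e) {
    if (is.null(e$name) || is.null(e$family) || is.null(e$mean))
      stop("parameter entry missing 'name', 'family' or 'mean'")
    data.frame(
      name = as.character(e$name),
      family = as.character(e$family),
      mean = as.numeric(e$mean),
      dispersion = num_or_na(e$dispersion),
      ci_low = num_or_na(e$ci_low),
      ci_high = num_or_na(e$ci_high),
      lo = num_or_na(e$lo),
      hi = num_or_na(e$hi),
      mode = num_or_na(e$mode),
      sa_rule = chr_or(e$sa_rule, "none"),
      patient_level = isTRUE(e$patient_level),
      psa = !isFALSE(e$psa),
      stringsAsFactors = FALSE)
  })
  specs <- do.call(rbind, rows)
  validate_spec_table(specs)
  class(specs) <- c("cea_spec_table", "data.frame")
  specs
}

validate_spec_table <- function(specs) {
  fams <- c("normal", "beta", "gamma", "triangular", "log_odds_normal", "point")
  bad <- setdiff(specs$family, fams)
  if (length(bad)) stop("unknown distribution families: ", paste(bad, collapse = ", "))
  if (anyDuplicated(specs$name))
    stop("duplicated parameter names: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  rules <- c("ci", "pm_sd", "pm_25", "pm_50", "range", "none")
  bad <- setdiff(specs$sa_rule, rules)
  if (length(bad)) stop("unknown sa_rule values: ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (s$family == "beta" && (s$mean <= 0 || s$mean >= 1))
      stop(sprintf("'%s': beta mean must lie in (0,1)", s$name))
    if (s$family == "gamma" && s$mean <= 0)
      stop(sprintf("'%s': gamma mean must be positive", s$name))
    if (s$family == "beta")
      fit_beta_from_moments(s$mean, s$dispersion, s$name)  # feasibility check
    if (s$family == "log_odds_normal" && (is.na(s$ci_low) || is.na(s$ci_high)))
      stop(sprintf("'%s': log_odds_normal requires ci_low and ci_high", s$name))
    if (!is.na(s$ci_low) && !is.na(s$ci_high) &&
        !(s$ci_low < s$mean && s$mean < s$ci_high))
      stop(sprintf("'%s': requires ci_low < mean < ci_high", s$name))
    if (s$family == "triangular" && (is.na(s$lo) || is.na(s$hi) || is.na(s$mode)))
      stop(sprintf("'%s': triangular requires lo, hi and mode", s$name))
  }
  invisible(specs)
}

# One inverse-CDF draw per spec row. Quantile transforms of a single uniform
# stream keep the random-number layout identical whatever the parameter
# values, which is what makes common-random-number comparisons exact.
draw_spec_values <- function(specs, u) {
  vals <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    vals[i] <- switch(s$family,
      point = s$mean,
      normal = stats::qnorm(u[i], s$mean, s$dispersion),
      beta = {
        ab <- fit_beta_from_moments(s$mean, s$dispersion, s$name)
        stats::qbeta(u[i], ab[1], ab[2])
      },
      gamma = {
        gp <- fit_gamma_from_moments(s$mean, s$dispersion, s$name)
        stats::qgamma(u[i], shape = gp[1], scale = gp[2])
      },
      log_odds_normal = exp(stats::qnorm(
        u[i], log(s$mean), lognormal_sigma_from_ci(s$ci_low, s$ci_high))),
      triangular = qtriangular(u[i], s$lo, s$mode, s$hi))
  }
  names(vals) <- specs$name
  vals
}

#' Realize a parameter set from a specification table
#'
#' In `point` mode every parameter equals its published mean. In `psa` mode
#' each parameter flagged for probabilistic redrawing is drawn independently
#' from its sampling family (odds ratios on the log scale; the adherence
#' threshold from its triangular distribution); entries whose dispersion
#' describes between-patient heterogeneity rather than parameter
#' uncertainty keep their point estimates (see the parameter file schema).
#' Draws consume the current RNG stream, so seed beforehand for
#' reproducibility.
#'
#' @param specs A `cea_spec_table`, from [load_parameter_specs()].
#' @param mode `"point"` or `"psa"`.
#' @return A `cea_parameters` object (see [as_parameter_set()]).
#' @export
sample_parameter_set <- function(specs, mode = c("point", "psa")) {
  mode <- match.arg(mode)
  vals <- if (mode == "point") {
    stats::setNames(specs$mean, specs$name)
  } else {
    # draw for every row (fixed RNG layout), then pin the non-PSA entries
    v <- draw_spec_values(specs, stats::runif(nrow(specs)))
    v[!specs$psa] <- specs$mean[!specs$psa]
    v
  }
  # probabilities and utilities are already support-respecting via their
  # families; normal efficacy draws may legitimately be negative. Independent
  # utility draws can invert the state ordering: cap the moderate-to-severe
  # utility at the mild-pain utility.
  if (all(c("u_mild", "u_modsev") %in% names(vals)))
    vals[["u_modsev"]] <- min(vals[["u_modsev"]], vals[["u_mild"]])
  as_parameter_set(vals, specs)
}

required_parameter_names <- function() {
  c("age", "pain",
    paste0("reduction_", STANDARD_AGENTS), "reduction_cannabis",
    paste0("p_nonserious_", STANDARD_AGENTS), "p_nonserious_cannabis_mono",
    paste0("p_intolerable_", STANDARD_AGENTS), "p_intolerable_cannabis_mono",
    paste0("p_serious_", STANDARD_AGENTS), "p_serious_cannabis_mono",
    "or_nonserious", "or_nonserious_nonuser", "or_serious", "or_serious_nonuser",
    paste0("p_death_sae_", AGE_BANDS),
    paste0("adherence_", STANDARD_AGENTS), "adherence_cannabis",
    "adherence_threshold",
    paste0("discontinuation_", STANDARD_AGENTS), "discontinuation_cannabis",
    "u_mild", "u_modsev", "dec_tolerable", "dec_intolerable", "dec_serious",
    "cost_visit_regular", "cost_visit_sae",
    "cost_visit_regular_oop", "cost_visit_sae_oop",
    paste0("cost_hosp_", AGE_BANDS), "cost_hosp_oop",
    paste0("cost_wholesale_", STANDARD_AGENTS),
    paste0("cost_oop_", STANDARD_AGENTS),
    "price_per_gram", "daily_thc_g", "thc_fraction", "cannabis_wastage",
    "discount_rate", "cycle_days")
}

#' Assemble a realized parameter set
#'
#' Builds the structured parameter object the simulation engine consumes from
#' a named vector of realized values (one per specification entry).
#' Patient-level dispersions (baseline moments, response SDs, adherence SDs)
#' are carried over from the specification table; realized means may differ
#' from the printed ones (PSA draws, sensitivity overrides).
#'
#' @param values Named numeric vector of realized parameter values.
#' @param specs The `cea_spec_table` the values were realized from.
#' @return A `cea_parameters` list with per-agent vectors (ordered
#'   duloxetine, desipramine, gabapentin, pregabalin), cannabis scalars,
#'   age-band vectors, utilities, costs and run structure. Cannabis wastage
#'   starts at 0 (`wastage_applied`); the wastage scenario switches it on.
#' @export
as_parameter_set <- function(values, specs) {
  req <- required_parameter_names()
  missing <- setdiff(req, names(values))
  if (length(missing))
    stop("missing parameter spec(s): ", paste(missing, collapse = ", "))
  g <- function(nm) unname(values[[nm]])
  gv <- function(prefix, suffixes) {
    stats::setNames(vapply(paste0(prefix, suffixes), g, numeric(1)), suffixes)
  }
  disp <- function(nm) {
    i <- match(nm, specs$name)
    if (is.na(i)) stop("no specification entry for '", nm, "'")
    specs$dispersion[i]
  }
  dv <- function(prefix, suffixes) {
    stats::setNames(vapply(paste0(prefix, suffixes), disp, numeric(1)), suffixes)
  }
  p <- list(
    agents = STANDARD_AGENTS,
    age_mean = g("age"), age_sd = disp("age"),
    pain_mean = g("pain"), pain_sd = disp("pain"),
    reduction_mean = gv("reduction_", STANDARD_AGENTS),
    reduction_sd = dv("reduction_", STANDARD_AGENTS),
    p_nonserious = gv("p_nonserious_", STANDARD_AGENTS),
    p_intolerable = gv("p_intolerable_", STANDARD_AGENTS),
    p_serious = gv("p_serious_", STANDARD_AGENTS),
    adherence_mean = gv("adherence_", STANDARD_AGENTS),
    adherence_sd = dv("adherence_", STANDARD_AGENTS),
    discontinuation = gv("discontinuation_", STANDARD_AGENTS),
    wholesale_month = gv("cost_wholesale_", STANDARD_AGENTS),
    oop_month = gv("cost_oop_", STANDARD_AGENTS),
    cannabis_reduction_mean = g("reduction_cannabis"),
    cannabis_reduction_sd = disp("reduction_cannabis"),
    cannabis_p_nonserious_mono = g("p_nonserious_cannabis_mono"),
    cannabis_p_intolerable_mono = g("p_intolerable_cannabis_mono"),
    cannabis_p_serious_mono = g("p_serious_cannabis_mono"),
    cannabis_adherence_mean = g("adherence_cannabis"),
    cannabis_adherence_sd = disp("adherence_cannabis"),
    cannabis_discontinuation = g("discontinuation_cannabis"),
    or_nonserious = g("or_nonserious"),
    or_serious = g("or_serious"),
    or_nonserious_nonuser = g("or_nonserious_nonuser"),
    or_serious_nonuser = g("or_serious_nonuser"),
    price_per_gram = g("price_per_gram"),
    daily_thc_g = g("daily_thc_g"),
    thc_fraction = g("thc_fraction"),
    cannabis_wastage = g("cannabis_wastage"),
    wastage_applied = 0,
    death_risk = gv("p_death_sae_", AGE_BANDS),
    hosp_cost = gv("cost_hosp_", AGE_BANDS),
    hosp_oop = g("cost_hosp_oop"),
    u_mild = g("u_mild"), u_modsev = g("u_modsev"),
    dec_tolerable = g("dec_tolerable"),
    dec_intolerable = g("dec_intolerable"),
    dec_serious = g("dec_serious"),
    visit_regular = g("cost_visit_regular"),
    visit_sae = g("cost_visit_sae"),
    visit_regular_oop = g("cost_visit_regular_oop"),
    visit_sae_oop = g("cost_visit_sae_oop"),
    adherence_threshold = g("adherence_threshold"),
    discount_rate = g("discount_rate"),
    cycle_days = g("cycle_days"))
  validate_parameter_set(p)
  attr(p, "values") <- values
  attr(p, "specs") <- specs
  class(p) <- "cea_parameters"
  p
}

validate_parameter_set <- function(p) {
  probs <- c(p$p_nonserious, p$p_intolerable, p$p_serious,
             p$cannabis_p_nonserious_mono, p$cannabis_p_intolerable_mono,
             p$cannabis_p_serious_mono, p$discontinuation,
             p$cannabis_discontinuation, p$death_risk,
             p$adherence_mean, p$cannabis_adherence_mean)
  if (any(probs < 0 | probs > 1))
    stop("probabilities/adherence must lie in [0, 1]")
  costs <- c(p$wholesale_month, p$oop_month, p$hosp_cost, p$hosp_oop,
             p$visit_regular, p$visit_sae, p$visit_regular_oop, p$visit_sae_oop,
             p$price_per_gram)
  if (any(costs < 0)) stop("costs must be nonnegative")
  if (p$u_mild < p$u_modsev)
    stop("mild-pain utility must be at least the moderate-to-severe utility")
  if (p$adherence_threshold < 0.5 || p$adherence_threshold > 1.0)
    stop("adherence threshold must lie in [0.5, 1.0]")
  if (p$thc_fraction <= 0 || p$thc_fraction >= 1)
    stop("thc_fraction must lie in (0, 1)")
  if (p$wastage_applied < 0 || p$wastage_applied >= 1)
    stop("wastage must lie in [0, 1)")
  if (any(c(p$or_nonserious, p$or_serious,
            p$or_nonserious_nonuser, p$or_serious_nonuser) <= 0))
    stop("odds ratios must be positive")
  invisible(p)
}

#' Override realized parameter values
#'
#' Rebuilds a parameter set with some entries replaced, keeping everything
#' else at its current realized value. Used by the one-way sensitivity and
#' scenario runners.
#'
#' @param params A `cea_parameters` object.
#' @param updates Named numeric vector of replacement values, keyed by
#'   specification-entry names (e.g. `c(adherence_cannabis = 0.78)`).
#' @return A new `cea_parameters` object.
#' @export
set_parameter_values <- function(params, updates) {
  values <- attr(params, "values")
  specs <- attr(params, "specs")
  if (is.null(values) || is.null(specs))
    stop("parameter set lacks its specification attributes")
  unknown <- setdiff(names(updates), names(values))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  values[names(updates)] <- updates
  p <- as_parameter_set(values, specs)
  # wastage application status is engine state, not a spec value: preserve it
  p$wastage_applied <- params$wastage_applied
  validate_parameter_set(p)
  p
}

#' Convert a 100-point VAS pain score to the 11-point Likert scale
#'
#' Linear rescaling (division by 10) aligning visual-analog-scale pain
#' reductions with the 0-10 Likert scale the model state uses.
#'
#' @param score Score on the 0-100 visual analog scale.
#' @return Score on the 0-10 scale.
#' @examples
#' convert_vas100_to_likert11(11.1)  # 1.11
#' @export
convert_vas100_to_likert11 <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100))
    stop("VAS scores must lie in [0, 100]")
  score / 10
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Realized cost-effectiveness model parameters\n")
  cat(sprintf("  baseline: age ~ N(%.2f, %.2f), pain ~ N(%.2f, %.2f) on 0-10\n",
              x$age_mean, x$age_sd, x$pain_mean, x$pain_sd))
  cat("  agents:", paste(x$agents, collapse = ", "), "\n")
  cat(sprintf("  cannabis: reduction %.2f, price $%.2f/g, %.3f g THC/day (%.1f%% THC)\n",
              x$cannabis_reduction_mean, x$price_per_gram, x$daily_thc_g,
              100 * x$thc_fraction))
  cat(sprintf("  adherence threshold %.2f; discount %.1f%%/yr; %g-day cycles\n",
              x$adherence_threshold, 100 * x$discount_rate, x$cycle_days))
  invisible(x)
}
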
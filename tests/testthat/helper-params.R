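# Shared fixtures: the shipped specification table, its point-estimate
# parameter set, and a constructor for controlled parameter sets (overriding
# realized means and, where a test needs a degenerate distribution, the
# dispersion column of the spec table itself).

specs_default <- load_parameter_specs()
params_point <- sample_parameter_set(specs_default, "point")

make_params <- function(means = NULL, disps = NULL) {
  sp <- specs_default
  if (!is.null(disps)) sp$dispersion[match(names(disps), sp$name)] <- disps
  vals <- stats::setNames(sp$mean, sp$name)
  if (!is.null(means)) vals[names(means)] <- means
  as_parameter_set(vals, sp)
}

# A fully deterministic patient pathway: sure adherence, no adverse events,
# no discontinuation, fixed baseline pain and fixed response draws.
deterministic_params <- function(means = NULL) {
  zero_names <- c(paste0("p_nonserious_", c("duloxetine", "desipramine",
                                            "gabapentin", "pregabalin")),
                  "p_nonserious_cannabis_mono",
                  paste0("p_intolerable_", c("duloxetine", "desipramine",
                                             "gabapentin", "pregabalin")),
                  "p_intolerable_cannabis_mono",
                  paste0("p_serious_", c("duloxetine", "desipramine",
                                         "gabapentin", "pregabalin")),
                  "p_serious_cannabis_mono",
                  paste0("discontinuation_", c("duloxetine", "desipramine",
                                               "gabapentin", "pregabalin")),
                  "discontinuation_cannabis",
                  paste0("p_death_sae_", c("18_44", "45_64", "65_84", "85_plus")))
  adh_names <- c(paste0("adherence_", c("duloxetine", "desipramine",
                                        "gabapentin", "pregabalin")),
                 "adherence_cannabis")
  m <- c(stats::setNames(rep(0, length(zero_names)), zero_names),
         stats::setNames(rep(0.99, length(adh_names)), adh_names),
         pain = 6, reduction_duloxetine = 3)
  if (!is.null(means)) m[names(means)] <- means
  d <- c(stats::setNames(rep(1e-4, length(adh_names)), adh_names),
         pain = 1e-9,
         reduction_duloxetine = 0, reduction_desipramine = 0,
         reduction_gabapentin = 0, reduction_pregabalin = 0,
         reduction_cannabis = 0)
  make_params(means = m, disps = d)
}

# Null-effect cannabis: no efficacy (mean and spread), identity odds ratios,
# free cannabis, no cannabis-attributable adverse events or discontinuation.
null_cannabis_params <- function() {
  make_params(
    means = c(reduction_cannabis = 0, or_nonserious = 1, or_serious = 1,
              price_per_gram = 0, p_nonserious_cannabis_mono = 0,
              p_intolerable_cannabis_mono = 0, p_serious_cannabis_mono = 0,
              discontinuation_cannabis = 0),
    disps = c(reduction_cannabis = 0))
}
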
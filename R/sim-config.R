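# Configuration of the synthetic claims generator.

#' Default Charlson condition prevalences
#'
#' Per-condition Bernoulli probabilities used for senior patients (younger
#' patients use `nonsenior_dx_scale` times these), chosen so that the
#' age-adjusted Charlson index of a typical senior lands around 4, the
#' magnitude reported for comparable senior claims populations.
#'
#' @return named numeric vector of probabilities.
#' @export
default_charlson_prevalence <- function() {
  c(mi = 0.10, chf = 0.12, pvd = 0.08, cvd = 0.10, dementia = 0.07,
    copd = 0.15, rheumatic = 0.04, ulcer = 0.04, mild_liver = 0.03,
    diabetes = 0.20, diabetes_comp = 0.07, hemiplegia = 0.02, renal = 0.10,
    malignancy = 0.10, severe_liver = 0.01, metastatic = 0.03, aids = 0.002)
}

#' Synthetic claims simulation configuration
#'
#' Parameters of the synthetic claims generator. Per-region parameters are
#' recycled to the number of regions. The defaults emulate the structure of
#' a two-region German claims study: an urban region with more practices and
#' patients and a smaller rural one, skewed practice panel sizes, a senior
#' share under 20%, community-structured patient sharing, overdispersed PIM
#' counts, and a steep negative centrality-to-PIM gradient.
#'
#' @param regions region labels (default two: `"urban"`, `"rural"`; the
#'   urban region is the reference in the models).
#' @param n_patients_per_region,n_practices_per_region counts per region.
#' @param pcp_fraction fraction of (non-excluded) practices that are primary
#'   care providers, per region.
#' @param senior_fraction fraction of patients aged 65+, per region.
#' @param senior_age_shape,senior_age_scale Gamma parameters of the senior
#'   age excess over the cutoff, per region (defaults target a median age in
#'   the low-to-mid 70s with an IQR near 11--12 years).
#' @param adult_age_range age range of younger patients (uniform).
#' @param female_fraction fraction of female patients.
#' @param mean_visits_per_patient mean number of distinct practices a
#'   younger patient visits during the year (>= 1); seniors attend a single
#'   primary practice (see Details).
#' @param encounter_rate mean number of claims a patient files per visited
#'   practice (>= 1).
#' @param panel_size_skew standard deviation of the log-normal practice
#'   attractiveness weights; larger values give heavier-tailed panel sizes.
#' @param n_communities number of practice communities per region. Typical
#'   shared-patient counts between two same-community practices scale as
#'   (young patients per practice) x (within-community visits)^2 /
#'   (practices per community), so the defaults keep communities small
#'   enough (15--25 practices) for ties to clear the default threshold of 8
#'   while hub practices also tie across communities.
#' @param within_community_odds odds that a younger patient's additional
#'   practice lies in their home community rather than elsewhere
#'   (odds / (odds + 1) is the within-community probability).
#' @param planted_quartile_irr length-4 positive vector: expected PIM rate
#'   ratio by realized degree quartile (Q1 = 1 reference). The default is a
#'   steep negative gradient of the size reported in regional claims
#'   analyses of this design.
#' @param base_pim_rate expected annual PIM events for a senior in a
#'   quartile-1 practice of average latent quality.
#' @param over_event_fraction fraction of planted PIM events realized as
#'   over-prescribing (the rest are under-prescribing events).
#' @param region_rate_ratio multiplicative PIM rate ratio per region
#'   (reference region first).
#' @param dispersion Gamma-Poisson overdispersion of practice-level PIM
#'   totals (variance of the practice latent quality; > 0).
#' @param charlson_prevalence named per-condition probabilities.
#' @param nonsenior_dx_scale multiplier on condition prevalences for
#'   younger patients.
#' @param excluded_specialty_fraction fraction of practices drawn from
#'   specialties excluded from network mapping.
#' @param emergency_fraction fraction of claims flagged as emergency visits.
#' @param off_year_fraction fraction of claims falling in the preceding
#'   calendar year.
#' @param tie_threshold shared-patient tie threshold used when planting the
#'   centrality effect (kept equal to the analysis default).
#' @param year calendar year of the simulated claims.
#' @param senior_age_cutoff senior age cutoff in years.
#' @param rule_table [pim_rules()] used to emit PIM-triggering
#'   diagnosis/prescription combinations.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   tables.
#'
#' @details Seniors are affiliated with exactly one primary practice, at
#' which all of their claims, diagnoses and prescriptions occur; network
#' ties are created by the younger, multi-practice population. This keeps
#' the planted quartile rate ratios identified on the scale the regression
#' estimates: the full annual score of a senior shared by several practices
#' is attributed to each of them, so senior sharing would blend practice
#' quality across quartiles. The senior panel attractiveness of a practice
#' is drawn independently of the younger-panel attractiveness that drives
#' its connectivity, so degree quartile is not mechanically confounded with
#' senior volume.
#'
#' @return a `sim_config` object.
#' @export
sim_config <- function(regions = c("urban", "rural"),
                       n_patients_per_region = c(28500, 21000),
                       n_practices_per_region = c(560, 350),
                       pcp_fraction = c(0.38, 0.30),
                       senior_fraction = c(0.19, 0.14),
                       senior_age_shape = c(1.2, 1.0),
                       senior_age_scale = c(11, 8.7),
                       adult_age_range = c(18, 64),
                       female_fraction = 0.53,
                       mean_visits_per_patient = 4.3,
                       encounter_rate = 1.8,
                       panel_size_skew = 0.55,
                       n_communities = c(25, 12),
                       within_community_odds = 4,
                       planted_quartile_irr = c(1, 0.21, 0.073, 0.040),
                       base_pim_rate = 2.5,
                       over_event_fraction = 0.7,
                       region_rate_ratio = c(1, 1.25),
                       dispersion = 0.5,
                       charlson_prevalence = default_charlson_prevalence(),
                       nonsenior_dx_scale = 0.25,
                       excluded_specialty_fraction = 0.07,
                       emergency_fraction = 0.05,
                       off_year_fraction = 0.04,
                       tie_threshold = 8,
                       year = 2016,
                       senior_age_cutoff = 65,
                       rule_table = default_pim_rules(),
                       seed = 1L) {
  k <- length(regions)
  stopifnot(k >= 1)
  rec <- function(v) rep_len(v, k)
  cfg <- list(
    regions = as.character(regions),
    n_patients_per_region = rec(as.integer(n_patients_per_region)),
    n_practices_per_region = rec(as.integer(n_practices_per_region)),
    pcp_fraction = rec(pcp_fraction),
    senior_fraction = rec(senior_fraction),
    senior_age_shape = rec(senior_age_shape),
    senior_age_scale = rec(senior_age_scale),
    adult_age_range = adult_age_range,
    female_fraction = female_fraction,
    mean_visits_per_patient = mean_visits_per_patient,
    encounter_rate = encounter_rate,
    panel_size_skew = panel_size_skew,
    n_communities = rec(as.integer(n_communities)),
    within_community_odds = within_community_odds,
    planted_quartile_irr = planted_quartile_irr,
    base_pim_rate = base_pim_rate,
    over_event_fraction = over_event_fraction,
    region_rate_ratio = rec(region_rate_ratio),
    dispersion = dispersion,
    charlson_prevalence = charlson_prevalence,
    nonsenior_dx_scale = nonsenior_dx_scale,
    excluded_specialty_fraction = excluded_specialty_fraction,
    emergency_fraction = emergency_fraction,
    off_year_fraction = off_year_fraction,
    tie_threshold = as.integer(tie_threshold),
    year = as.integer(year),
    senior_age_cutoff = senior_age_cutoff,
    rule_table = rule_table,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac <- c(cfg$pcp_fraction, cfg$senior_fraction, cfg$female_fraction,
            cfg$over_event_fraction, cfg$excluded_specialty_fraction,
            cfg$emergency_fraction, cfg$off_year_fraction,
            cfg$nonsenior_dx_scale, cfg$charlson_prevalence)
  if (any(frac < 0 | frac > 1))
    stop("parameter error: all fractions must lie in [0, 1]")
  if (any(cfg$n_patients_per_region < 0) || any(cfg$n_practices_per_region < 0))
    stop("parameter error: counts must be >= 0")
  if (cfg$dispersion <= 0)
    stop("parameter error: dispersion must be > 0")
  if (length(cfg$planted_quartile_irr) != 4 || any(cfg$planted_quartile_irr <= 0))
    stop("parameter error: planted_quartile_irr must be 4 positive values")
  if (cfg$mean_visits_per_patient < 1 || cfg$encounter_rate < 1)
    stop("parameter error: mean_visits_per_patient and encounter_rate must be >= 1")
  if (cfg$panel_size_skew <= 0)
    stop("parameter error: panel_size_skew must be > 0")
  if (!inherits(cfg$rule_table, "pim_rules"))
    stop("parameter error: rule_table must be a pim_rules object")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  regions: %s\n", paste(x$regions, collapse = ", ")))
  cat(sprintf("  patients/region: %s; practices/region: %s\n",
              paste(x$n_patients_per_region, collapse = "/"),
              paste(x$n_practices_per_region, collapse = "/")))
  cat(sprintf("  planted quartile IRR: %s; dispersion %.3g; seed %d\n",
              paste(x$planted_quartile_irr, collapse = ", "),
              x$dispersion, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' The rule table travels inside the file as a list of rules; all other
#' fields are plain keys. `read_sim_config()` rebuilds a validated
#' [sim_config()].
#'
#' @param config a `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config()` the path; `read_sim_config()` a
#'   `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$rule_table <- list(scoring_mode = config$rule_table$scoring_mode,
                         rules = config$rule_table$rules)
  # yaml drops names of atomic vectors; keep the prevalence map keyed
  lst$charlson_prevalence <- as.list(config$charlson_prevalence)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$rule_table)) {
    rules_df <- as.data.frame(lapply(lst$rule_table$rules, unlist),
                              stringsAsFactors = FALSE)
    lst$rule_table <- pim_rules(rules_df,
                                scoring_mode = lst$rule_table$scoring_mode)
  }
  lst$charlson_prevalence <- unlist(lst$charlson_prevalence)
  for (nm in setdiff(names(lst), c("regions", "rule_table",
                                   "charlson_prevalence"))) {
    lst[[nm]] <- unlist(lst[[nm]])
  }
  do.call(sim_config, lst)
}
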
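# Eligibility rules producing the network-mapping and analytic samples.

#' Cohort filter configuration
#'
#' @param year calendar year of the analysis (default 2016).
#' @param excluded_specialties specialty codes excluded from network mapping;
#'   defaults to disciplines not typically responsible for direct,
#'   coordinated patient care (anesthesiology, radiology, pathology,
#'   radiotherapy, nuclear medicine).
#' @param min_patients minimum unique patients a practice must have seen in
#'   the year to stay in the network sample (default 30).
#' @param min_patients_comparison `"geq"` (default: practices with >=
#'   `min_patients` retained) or `"gt"`.
#' @param senior_age_cutoff age defining a senior patient (default 65).
#' @param senior_comparison `"geq"` (senior means age >= cutoff, default) or
#'   `"gt"`.
#' @return a `filter_config` object.
#' @export
filter_config <- function(year = 2016,
                          excluded_specialties = default_excluded_specialties(),
                          min_patients = 30,
                          min_patients_comparison = c("geq", "gt"),
                          senior_age_cutoff = 65,
                          senior_comparison = c("geq", "gt")) {
  stopifnot(min_patients >= 0, senior_age_cutoff > 0)
  structure(list(year = as.integer(year),
                 excluded_specialties = as.character(excluded_specialties),
                 min_patients = as.integer(min_patients),
                 min_patients_comparison = match.arg(min_patients_comparison),
                 senior_age_cutoff = senior_age_cutoff,
                 senior_comparison = match.arg(senior_comparison)),
            class = "filter_config")
}

# Drop patients/practices left without encounters; prune prescriptions to
# surviving encounters.
prune_claims <- function(x) {
  keep_pat <- x$patients$patient_id %in% x$encounters$patient_id
  keep_pr <- x$practices$practice_id %in% x$encounters$practice_id
  x$patients <- x$patients[keep_pat, , drop = FALSE]
  x$practices <- x$practices[keep_pr, , drop = FALSE]
  x$prescriptions <- x$prescriptions[
    x$prescriptions$encounter_id %in% x$encounters$encounter_id, , drop = FALSE]
  rownames(x$patients) <- rownames(x$practices) <- NULL
  rownames(x$prescriptions) <- NULL
  x
}

flow_row <- function(step, x) {
  data.frame(step = step,
             n_practices = nrow(x$practices),
             n_patients = nrow(x$patients),
             n_claims = nrow(x$encounters),
             stringsAsFactors = FALSE)
}

#' Filter raw claims to the network-mapping sample
#'
#' Applies the eligibility rules sequentially, per region independently:
#' (1) drop practices with an excluded specialty; (2) drop emergency
#' encounters; (3) restrict encounters to the configured year; (4) drop
#' practices whose count of unique patients in the year falls below
#' `min_patients`. After each step, patients and practices left without any
#' encounter are removed. An ordered sample-flow report logging practice,
#' patient and claim counts after each step is attached as attribute
#' `"sample_flow"` (see [sample_flow()]).
#'
#' @param x a [claims_dataset()].
#' @param config a [filter_config()].
#' @return the filtered `claims_dataset` with a `sample_flow` attribute.
#' @export
filter_for_network <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "claims_dataset"), inherits(config, "filter_config"))
  flow <- flow_row("full claims record", x)

  keep <- !(x$practices$specialty %in% config$excluded_specialties)
  x$practices <- x$practices[keep, , drop = FALSE]
  x$encounters <- x$encounters[
    x$encounters$practice_id %in% x$practices$practice_id, , drop = FALSE]
  x <- prune_claims(x)
  flow <- rbind(flow, flow_row("exclude non-coordinating specialties", x))

  x$encounters <- x$encounters[!x$encounters$emergency, , drop = FALSE]
  x <- prune_claims(x)
  flow <- rbind(flow, flow_row("exclude emergency claims", x))

  if (!config$year %in% x$encounters$year && nrow(x$encounters) > 0) {
    warning(sprintf("year %d absent from dataset: result is empty", config$year))
  }
  x$encounters <- x$encounters[x$encounters$year == config$year, , drop = FALSE]
  x <- prune_claims(x)
  flow <- rbind(flow, flow_row(sprintf("restrict to calendar year %d", config$year), x))

  pp <- unique(x$encounters[c("patient_id", "practice_id")])
  n_unique <- table(factor(pp$practice_id, levels = x$practices$practice_id))
  ok <- if (config$min_patients_comparison == "geq") {
    n_unique >= config$min_patients
  } else n_unique > config$min_patients
  x$practices <- x$practices[ok[x$practices$practice_id], , drop = FALSE]
  x$encounters <- x$encounters[
    x$encounters$practice_id %in% x$practices$practice_id, , drop = FALSE]
  x <- prune_claims(x)
  flow <- rbind(flow, flow_row(
    sprintf("exclude practices with < %d unique patients", config$min_patients), x))

  rownames(x$encounters) <- NULL
  attr(x, "sample_flow") <- flow
  x
}

#' Sample-flow report of a filtered dataset
#'
#' @param x a dataset returned by [filter_for_network()] or
#'   [analytic_sample()].
#' @return data frame with one row per filtering step: step label and the
#'   practices, patients and claims remaining. Counts are non-increasing.
#' @export
sample_flow <- function(x) attr(x, "sample_flow")

#' Restrict the network sample to the analytic sample
#'
#' Retains only practices with at least one senior patient (per the
#' configured cutoff) among their encounter patients; the outcome is defined
#' for seniors only. Patients left without encounters are dropped. The
#' sample-flow report is extended with the analytic step.
#'
#' @param x a network-filtered [claims_dataset()].
#' @param config a [filter_config()].
#' @return the analytic `claims_dataset` (a practice subset of the input).
#' @export
analytic_sample <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "claims_dataset"))
  senior <- is_senior(x$patients$age, config$senior_age_cutoff,
                      config$senior_comparison)
  senior_ids <- x$patients$patient_id[senior]
  with_senior <- unique(x$encounters$practice_id[
    x$encounters$patient_id %in% senior_ids])
  flow <- attr(x, "sample_flow")
  x$practices <- x$practices[x$practices$practice_id %in% with_senior, ,
                             drop = FALSE]
  x$encounters <- x$encounters[
    x$encounters$practice_id %in% x$practices$practice_id, , drop = FALSE]
  x <- prune_claims(x)
  rownames(x$encounters) <- NULL
  if (!is.null(flow)) {
    attr(x, "sample_flow") <- rbind(flow,
      flow_row("exclude practices without senior patients", x))
  }
  x
}

#' Senior patient ids of a dataset
#'
#' @param x a [claims_dataset()].
#' @param config a [filter_config()] supplying the cutoff.
#' @return character vector of patient ids qualifying as senior.
#' @export
senior_ids <- function(x, config = filter_config()) {
  x$patients$patient_id[is_senior(x$patients$age, config$senior_age_cutoff,
                                  config$senior_comparison)]
}
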
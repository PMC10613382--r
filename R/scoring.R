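# Outcome scoring: per-patient annual PIM scores, practice-level summed
# scores, and practice covariates for the regression.

#' Annual PIM scores for senior patients
#'
#' For every senior patient, cross-references diagnoses with the rule table
#' and the year's prescriptions to count potentially inappropriate
#' medication events:
#'
#' * over-prescribing: in `per_encounter` mode, one point for each distinct
#'   (encounter, drug class) at which a class contraindicated by any of the
#'   patient's diagnoses is prescribed -- repeated prescribing across
#'   encounters keeps accruing points; in `per_year` mode each
#'   contraindicated class counts at most once.
#' * under-prescribing: one point per (diagnosis, indicated class) pair for
#'   which the class is never prescribed anywhere during the year.
#'
#' Diagnosis codes and drug classes not covered by the rule table are
#' ignored (tolerant matching); prescriptions of classes unknown to the
#' table trigger a single summary warning.
#'
#' @param x a [claims_dataset()] (typically the analytic sample).
#' @param rules a [pim_rules()] table.
#' @param config a [filter_config()] supplying year and senior cutoff.
#' @return data frame with columns `patient_id`, `over`, `under`, `score`
#'   covering every senior patient in the dataset.
#' @export
pim_scores <- function(x, rules = default_pim_rules(),
                       config = filter_config()) {
  stopifnot(inherits(x, "claims_dataset"), inherits(rules, "pim_rules"))
  sen <- x$patients[is_senior(x$patients$age, config$senior_age_cutoff,
                              config$senior_comparison), , drop = FALSE]
  out <- data.frame(patient_id = sen$patient_id,
                    over = 0L, under = 0L, stringsAsFactors = FALSE)
  if (nrow(sen) == 0) {
    out$score <- integer()
    return(out)
  }
  dl <- dx_long(sen)
  rx <- x$prescriptions[x$prescriptions$patient_id %in% sen$patient_id &
                          x$prescriptions$year == config$year, , drop = FALSE]
  unknown <- setdiff(unique(rx$drug_class), rule_classes(rules))
  if (length(unknown) > 0) {
    warning(sprintf("%d prescribed drug class(es) unknown to the rule table ignored (e.g. %s)",
                    length(unknown), unknown[1]))
  }

  # over-prescribing
  contra <- rules_long(rules, "contraindicated")
  cand <- merge(dl, contra, by.x = "code", by.y = "diagnosis")
  cand <- unique(cand[c("patient_id", "drug_class")])
  hits <- merge(rx[c("patient_id", "encounter_id", "drug_class")], cand,
                by = c("patient_id", "drug_class"))
  hits <- if (rules$scoring_mode == "per_encounter") {
    unique(hits[c("patient_id", "encounter_id", "drug_class")])
  } else {
    unique(hits[c("patient_id", "drug_class")])
  }
  if (nrow(hits) > 0) {
    n_over <- table(hits$patient_id)
    out$over[match(names(n_over), out$patient_id)] <- as.integer(n_over)
  }

  # under-prescribing: (diagnosis, indicated class) pairs with no
  # prescription of the class anywhere in the year
  ind <- rules_long(rules, "indicated")
  pairs <- merge(dl, ind, by.x = "code", by.y = "diagnosis")
  pairs <- unique(pairs[c("patient_id", "code", "drug_class")])
  got <- unique(rx[c("patient_id", "drug_class")])
  got$covered <- rep(TRUE, nrow(got))
  pairs <- merge(pairs, got, by = c("patient_id", "drug_class"), all.x = TRUE)
  unmet <- pairs[is.na(pairs$covered), , drop = FALSE]
  if (nrow(unmet) > 0) {
    n_under <- table(unmet$patient_id)
    out$under[match(names(n_under), out$patient_id)] <- as.integer(n_under)
  }
  out$score <- out$over + out$under
  out[order(out$patient_id), , drop = FALSE]
}

#' Annual PIM score for a single patient
#'
#' Single-patient convenience wrapper around the scoring engine.
#'
#' @param diagnoses character vector of diagnosis codes (or one
#'   `;`-separated string).
#' @param prescriptions data frame with columns `encounter_id`, `drug_class`
#'   (the patient's prescriptions for the year).
#' @param rules a [pim_rules()] table.
#' @return list with `over`, `under`, `score`.
#' @export
patient_pim_score <- function(diagnoses, prescriptions,
                              rules = default_pim_rules()) {
  if (length(diagnoses) == 1 && grepl(";", diagnoses, fixed = TRUE))
    diagnoses <- strsplit(diagnoses, ";", fixed = TRUE)[[1]]
  n <- max(nrow(prescriptions), 1L)
  ds <- claims_dataset(
    patients = data.frame(patient_id = "P1", age = 80L, sex = "F",
                          region = "R1",
                          diagnoses = paste(diagnoses, collapse = ";")),
    practices = data.frame(practice_id = "PR1", specialty = "general_practice",
                           region = "R1"),
    encounters = data.frame(
      encounter_id = unique(c(prescriptions$encounter_id, "E0")),
      patient_id = "P1", practice_id = "PR1", year = 2016L,
      emergency = FALSE),
    prescriptions = if (nrow(prescriptions) > 0) data.frame(
      prescription_id = sprintf("RX%d", seq_len(nrow(prescriptions))),
      patient_id = "P1", practice_id = "PR1",
      encounter_id = prescriptions$encounter_id, year = 2016L,
      drug_class = prescriptions$drug_class) else
        data.frame(prescription_id = character(), patient_id = character(),
                   practice_id = character(), encounter_id = character(),
                   year = integer(), drug_class = character()))
  res <- pim_scores(ds, rules, filter_config(year = 2016))
  list(over = res$over[1], under = res$under[1], score = res$score[1])
}

#' Practice-level summed PIM (FORTA-style) scores
#'
#' Sums the annual PIM score of every senior patient with at least one
#' encounter at the practice during the year. A patient shared by k
#' practices contributes their full annual score to each of the k practices
#' (the score is attributed to all practices responsible for the patient).
#'
#' @param x a [claims_dataset()] (analytic sample).
#' @param scores output of [pim_scores()].
#' @param config a [filter_config()].
#' @return named integer vector of summed scores over all practices in the
#'   dataset (0 for practices without senior patients).
#' @export
practice_summed_pim <- function(x, scores, config = filter_config()) {
  stopifnot(inherits(x, "claims_dataset"))
  pp <- unique(x$encounters[x$encounters$year == config$year,
                            c("patient_id", "practice_id")])
  pp <- merge(pp, scores[c("patient_id", "score")], by = "patient_id")
  out <- setNames(integer(nrow(x$practices)), sort(x$practices$practice_id))
  if (nrow(pp) > 0) {
    sums <- tapply(pp$score, pp$practice_id, sum)
    out[names(sums)] <- as.integer(sums)
  }
  out
}

#' Practice covariates for the regression
#'
#' Builds one analysis row per practice: panel size, number and percentage
#' of seniors, mean Charlson index over the practice's senior patients,
#' primary-care-provider dummy (general/internal medicine or gynecology),
#' region and region dummy (0 for the reference region), and the summed PIM
#' outcome.
#'
#' @param x the analytic [claims_dataset()].
#' @param scores output of [pim_scores()].
#' @param config a [filter_config()].
#' @param weights a [charlson_weights()] object.
#' @param region_levels region labels in reference-first order; defaults to
#'   sorted unique regions.
#' @return data frame (`practice_records`) with one row per practice.
#' @export
practice_records <- function(x, scores, config = filter_config(),
                             weights = charlson_weights(),
                             region_levels = NULL) {
  stopifnot(inherits(x, "claims_dataset"))
  if (is.null(region_levels)) region_levels <- sort(unique(x$practices$region))
  pp <- unique(x$encounters[c("patient_id", "practice_id")])
  sen_ids <- senior_ids(x, config)
  ch <- charlson_scores(x$patients[x$patients$patient_id %in% sen_ids, ,
                                   drop = FALSE], weights)
  summed <- practice_summed_pim(x, scores, config)

  pr <- x$practices[order(x$practices$practice_id), , drop = FALSE]
  n_pat <- table(factor(pp$practice_id, levels = pr$practice_id))
  sen_pp <- pp[pp$patient_id %in% sen_ids, , drop = FALSE]
  n_sen <- table(factor(sen_pp$practice_id, levels = pr$practice_id))
  mean_ch <- tapply(ch[sen_pp$patient_id], sen_pp$practice_id, mean)

  out <- data.frame(
    practice_id = pr$practice_id,
    region = factor(pr$region, levels = region_levels),
    region_dummy = as.integer(pr$region != region_levels[1]),
    specialty = pr$specialty,
    pcp = as.integer(pr$specialty %in% pcp_specialties()),
    n_patients = as.integer(n_pat[pr$practice_id]),
    n_seniors = as.integer(n_sen[pr$practice_id]),
    stringsAsFactors = FALSE)
  out$pct_seniors <- ifelse(out$n_patients > 0,
                            out$n_seniors / out$n_patients, NA_real_)
  out$mean_charlson <- as.numeric(mean_ch[pr$practice_id])
  out$summed_forta <- as.integer(summed[pr$practice_id])
  rownames(out) <- NULL
  out
}

#' Merge centralities into practice records
#'
#' @param records output of [practice_records()].
#' @param centralities a [centrality_table()] (or a row-bound set covering
#'   several regions).
#' @return records with `degree`, `betweenness`, `eigenvector` columns;
#'   practices absent from the centrality table get NA.
#' @export
add_centralities <- function(records, centralities) {
  idx <- match(records$practice_id, centralities$practice_id)
  records$degree <- centralities$degree[idx]
  records$betweenness <- centralities$betweenness[idx]
  records$eigenvector <- centralities$eigenvector[idx]
  records
}
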
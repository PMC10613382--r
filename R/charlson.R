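# Age-adjusted Charlson comorbidity index.

#' Charlson comorbidity weights
#'
#' The original 17-condition weight set (weights 1/2/3/6) with the standard
#' age adjustment of one point per decade from 50--59 up to 80 and above.
#' Hierarchy rules prevent double counting: metastatic solid tumour
#' supersedes any malignancy, moderate/severe liver disease supersedes mild
#' liver disease, and diabetes with end-organ damage supersedes uncomplicated
#' diabetes.
#'
#' @param conditions named integer vector of condition weights.
#' @param age_breaks lower bounds of the age bands earning points.
#' @param age_points points per age band (parallel to `age_breaks`).
#' @param hierarchy list of `c(when = , drop = )` pairs: when condition
#'   `when` is present, condition `drop` does not score.
#' @return a `charlson_weights` object.
#' @export
charlson_weights <- function(
    conditions = c(mi = 1, chf = 1, pvd = 1, cvd = 1, dementia = 1,
                   copd = 1, rheumatic = 1, ulcer = 1, mild_liver = 1,
                   diabetes = 1, diabetes_comp = 2, hemiplegia = 2,
                   renal = 2, malignancy = 2, severe_liver = 3,
                   metastatic = 6, aids = 6),
    age_breaks = c(50, 60, 70, 80),
    age_points = c(1, 2, 3, 4),
    hierarchy = list(c(when = "metastatic", drop = "malignancy"),
                     c(when = "severe_liver", drop = "mild_liver"),
                     c(when = "diabetes_comp", drop = "diabetes"))) {
  stopifnot(all(conditions >= 0), length(age_breaks) == length(age_points))
  structure(list(conditions = conditions, age_breaks = age_breaks,
                 age_points = age_points, hierarchy = hierarchy),
            class = "charlson_weights")
}

#' Age-adjusted Charlson comorbidity index
#'
#' Sums the weights of the qualifying conditions present in `diagnoses`
#' (after applying the hierarchy rules) and adds the age points for the
#' patient's age band. Codes that are not Charlson conditions are ignored.
#'
#' @param diagnoses character vector of diagnosis codes for one patient
#'   (or a single `;`-separated string).
#' @param age age in years (>= 0).
#' @param weights a [charlson_weights()] object.
#' @return non-negative integer score.
#' @export
charlson_index <- function(diagnoses, age, weights = charlson_weights()) {
  stopifnot(age >= 0)
  if (length(diagnoses) == 1 && grepl(";", diagnoses, fixed = TRUE))
    diagnoses <- strsplit(diagnoses, ";", fixed = TRUE)[[1]]
  present <- intersect(unique(diagnoses), names(weights$conditions))
  for (h in weights$hierarchy) {
    if (h[["when"]] %in% present) present <- setdiff(present, h[["drop"]])
  }
  cond_score <- sum(weights$conditions[present])
  age_score <- age_points(age, weights)
  as.integer(cond_score + age_score)
}

age_points <- function(age, weights = charlson_weights()) {
  band <- findInterval(age, weights$age_breaks)
  ifelse(band == 0, 0L, as.integer(weights$age_points[pmax(band, 1)]))
}

# Vectorized Charlson scores over a patients table; returns named vector.
charlson_scores <- function(patients, weights = charlson_weights()) {
  if (nrow(patients) == 0) return(setNames(integer(), character()))
  dl <- dx_long(patients)
  dl <- dl[dl$code %in% names(weights$conditions), , drop = FALSE]
  # apply hierarchy: remove (patient, drop) rows where (patient, when) exists
  for (h in weights$hierarchy) {
    who <- unique(dl$patient_id[dl$code == h[["when"]]])
    dl <- dl[!(dl$code == h[["drop"]] & dl$patient_id %in% who), , drop = FALSE]
  }
  dl <- unique(dl)
  w <- weights$conditions[dl$code]
  cond <- tapply(w, dl$patient_id, sum)
  score <- setNames(age_points(patients$age, weights), patients$patient_id)
  score[names(cond)] <- score[names(cond)] + as.integer(cond)
  setNames(as.integer(score), patients$patient_id)
}
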
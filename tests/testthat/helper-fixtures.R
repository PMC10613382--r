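# Programmatic fixtures: toy claims built from a membership map, random toy
# datasets, and a small simulation configuration shared by several tests.

# members: named list patient_id -> character vector of practice ids; a
# practice repeated k times gives k encounters for that pair.
toy_claims <- function(members, ages = NULL, specialties = NULL,
                       region = "R1", year = 2016, emergency = NULL,
                       years = NULL, diagnoses = NULL, prescriptions = NULL,
                       sex = "F") {
  pids <- names(members)
  practice_ids <- sort(unique(unlist(members)))
  if (is.null(ages)) ages <- setNames(rep(50L, length(pids)), pids)
  if (is.null(specialties)) {
    specialties <- setNames(rep("general_practice", length(practice_ids)),
                            practice_ids)
  }
  if (is.null(diagnoses)) diagnoses <- setNames(rep("", length(pids)), pids)
  enc <- data.frame(
    patient_id = rep(pids, lengths(members)),
    practice_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE)
  enc$encounter_id <- sprintf("E%04d", seq_len(nrow(enc)))
  enc$year <- if (is.null(years)) year else years
  enc$emergency <- if (is.null(emergency)) FALSE else emergency
  rx <- if (is.null(prescriptions)) {
    data.frame(prescription_id = character(), patient_id = character(),
               practice_id = character(), encounter_id = character(),
               year = integer(), drug_class = character(),
               stringsAsFactors = FALSE)
  } else prescriptions
  claims_dataset(
    patients = data.frame(patient_id = pids, age = unname(ages[pids]),
                          sex = rep_len(sex, length(pids)), region = region,
                          diagnoses = unname(diagnoses[pids]),
                          stringsAsFactors = FALSE),
    practices = data.frame(practice_id = practice_ids,
                           specialty = unname(specialties[practice_ids]),
                           region = region, stringsAsFactors = FALSE),
    encounters = enc[c("encounter_id", "patient_id", "practice_id", "year",
                       "emergency")],
    prescriptions = rx)
}

# random toy dataset for projection / attribution property tests
random_toy_claims <- function(seed, max_practices = 10, max_patients = 200) {
  set.seed(seed)
  n_pr <- sample(2:max_practices, 1)
  n_pat <- sample(5:max_patients, 1)
  pr_ids <- sprintf("PR%02d", seq_len(n_pr))
  members <- lapply(seq_len(n_pat), function(i) {
    k <- sample(1:min(4, n_pr), 1)
    sample(pr_ids, k)
  })
  names(members) <- sprintf("P%03d", seq_len(n_pat))
  ages <- setNames(sample(c(40L, 70L, 80L), n_pat, TRUE), names(members))
  toy_claims(members, ages = ages)
}

# small two-region configuration with the planted gradient; fast to generate
mini_cfg <- function(seed, ...) {
  sim_config(n_patients_per_region = c(2500, 2500),
             n_practices_per_region = c(60, 60),
             senior_fraction = 0.2,
             n_communities = c(4, 4),
             panel_size_skew = 0.5,
             planted_quartile_irr = c(1, 0.5, 0.25, 0.1),
             dispersion = 0.5,
             seed = seed, ...)
}

expect_claims_equal <- function(a, b) {
  for (tab in c("patients", "practices", "encounters", "prescriptions")) {
    expect_equal(a[[tab]], b[[tab]], ignore_attr = FALSE)
  }
}
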
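# PIM scoring engine, Charlson index and practice covariates.

demo_rules <- default_pim_rules()

test_that("rule tables reject a class that is both indicated and contraindicated", {
  bad <- data.frame(diagnosis = "d", indicated = "x;y", contraindicated = "y")
  expect_error(pim_rules(bad), "both indicated and contraindicated")
})

test_that("a patient with no rule-matching diagnoses scores zero", {
  res <- patient_pim_score(c("chf", "unrelated_code"),
                           data.frame(encounter_id = "E1",
                                      drug_class = "melatonin"),
                           demo_rules)
  expect_equal(res$score, 0)
})

test_that("repeated contraindicated prescribing accrues per encounter", {
  # insomnia contraindicates benzodiazepine; prescribed at 2 encounters
  res <- patient_pim_score("insomnia",
                           data.frame(encounter_id = c("E1", "E2"),
                                      drug_class = "benzodiazepine"),
                           demo_rules)
  expect_equal(res$over, 2)
  expect_equal(res$under, 1)  # melatonin indicated but never prescribed
  expect_equal(res$score, 3)
})

test_that("an unmet indicated class scores one under-prescribing point", {
  res <- patient_pim_score("depression_old_age",
                           data.frame(encounter_id = character(),
                                      drug_class = character()),
                           demo_rules)
  expect_equal(res$under, 1)
  expect_equal(res$over, 0)
})

test_that("per-year mode never exceeds per-encounter mode", {
  rules_year <- default_pim_rules(scoring_mode = "per_year")
  rx <- data.frame(encounter_id = c("E1", "E2", "E3"),
                   drug_class = c("benzodiazepine", "benzodiazepine", "z_drug"))
  pe <- patient_pim_score("insomnia", rx, demo_rules)
  py <- patient_pim_score("insomnia", rx, rules_year)
  expect_equal(pe$over, 3)
  expect_equal(py$over, 2)  # each contraindicated class once per year
  expect_lte(py$score, pe$score)
})

test_that("unknown prescribed classes are ignored with a warning", {
  ds <- toy_claims(list(S1 = "A"), ages = c(S1 = 70L),
                   diagnoses = c(S1 = "insomnia"))
  ds$prescriptions <- data.frame(
    prescription_id = "RX1", patient_id = "S1", practice_id = "A",
    encounter_id = ds$encounters$encounter_id[1], year = 2016L,
    drug_class = "experimental_compound", stringsAsFactors = FALSE)
  expect_warning(res <- pim_scores(ds, demo_rules, filter_config()),
                 "unknown to the rule table")
  expect_equal(res$score, 1)  # the unmet melatonin indication remains
})

test_that("practice sums attribute a shared patient's full score to each practice", {
  ds <- toy_claims(list(S1 = c("A", "B"), S2 = "A"),
                   ages = c(S1 = 70L, S2 = 80L))
  scores <- data.frame(patient_id = c("S1", "S2"), over = c(4L, 3L),
                       under = c(0L, 0L), score = c(4L, 3L))
  sums <- practice_summed_pim(ds, scores, filter_config())
  expect_equal(unname(sums["A"]), 7L)
  expect_equal(unname(sums["B"]), 4L)
  # total over practices exceeds the unique-patient total because S1 is shared
  expect_equal(sum(sums), 11L)
  expect_gte(sum(sums), sum(scores$score))
})

test_that("two patients with scores 3 and 5 sum to 8", {
  ds <- toy_claims(list(S1 = "A", S2 = "A"), ages = c(S1 = 70L, S2 = 80L))
  scores <- data.frame(patient_id = c("S1", "S2"), over = c(3L, 5L),
                       under = c(0L, 0L), score = c(3L, 5L))
  expect_equal(unname(practice_summed_pim(ds, scores, filter_config())["A"]), 8L)
})

test_that("the multi-attribution accounting identity holds on random toys", {
  fc <- filter_config()
  for (seed in 1:30) {
    set.seed(seed + 500)
    ds <- random_toy_claims(seed + 500, max_practices = 5, max_patients = 30)
    # give some seniors rule diagnoses and prescriptions
    sen <- senior_ids(ds, fc)
    dxs <- sample(demo_rules$rules$diagnosis, length(sen), TRUE)
    ds$patients$diagnoses[match(sen, ds$patients$patient_id)] <- dxs
    scores <- suppressWarnings(pim_scores(ds, demo_rules, fc))
    sums <- practice_summed_pim(ds, scores, fc)
    pp <- unique(ds$encounters[c("patient_id", "practice_id")])
    k <- table(factor(pp$patient_id, levels = scores$patient_id))
    expect_equal(sum(sums), sum(scores$score * as.integer(k[scores$patient_id])))
    expect_gte(sum(sums), sum(scores$score))
    shared_positive <- any(scores$score > 0 &
                             as.integer(k[scores$patient_id]) > 1)
    expect_equal(sum(sums) > sum(scores$score), shared_positive)
  }
})

test_that("Charlson worked examples reproduce from the default weights", {
  expect_equal(charlson_index(character(), 40), 0L)
  expect_equal(charlson_index(c("mi", "diabetes"), 66), 4L)  # 1 + 1 + 2
  # metastatic disease supersedes the co-coded malignancy: 6 + 4 age points
  expect_equal(charlson_index(c("metastatic", "malignancy"), 82), 10L)
  expect_equal(charlson_index(c("severe_liver", "mild_liver"), 45), 3L)
})

test_that("the Charlson index is monotone in diagnoses and age", {
  base <- charlson_index(c("chf"), 60)
  expect_gte(charlson_index(c("chf", "copd"), 60), base)
  expect_gte(charlson_index(c("chf"), 75), base)
  # vectorized scores agree with the scalar version
  pats <- data.frame(patient_id = c("a", "b"), age = c(66L, 82L),
                     sex = "F", region = "R1",
                     diagnoses = c("mi;diabetes", "metastatic;malignancy"))
  expect_equal(unname(charlson_scores(pats)), c(4L, 10L))
})

test_that("practice covariates compute ratios, means and dummies", {
  members <- c(lapply(setNames(nm = sprintf("Y%02d", 1:30)), function(i) "G"),
               list(S1 = "G", S2 = "G", S3 = "G", S4 = "G", S5 = "G",
                    S6 = "G", S7 = "G", S8 = "G", S9 = "G", S10 = "G"))
  ages <- c(setNames(rep(40L, 30), sprintf("Y%02d", 1:30)),
            setNames(rep(70L, 10), paste0("S", 1:10)))
  dx <- setNames(rep("", 40), names(ages))
  dx["S1"] <- "chf"        # charlson 1 + 3 age points = 4
  dx["S2"] <- "renal"      # 2 + 3 = 5
  ds <- toy_claims(members, ages = ages, diagnoses = dx,
                   specialties = c(G = "gynecology"))
  scores <- suppressWarnings(pim_scores(ds, demo_rules, filter_config()))
  rec <- practice_records(ds, scores, filter_config())
  expect_equal(rec$n_patients, 40L)
  expect_equal(rec$n_seniors, 10L)
  expect_equal(rec$pct_seniors, 0.25)
  # senior charlson scores: 4, 5 and eight times 3 (age points only)
  expect_equal(rec$mean_charlson, mean(c(4, 5, rep(3, 8))))
  expect_equal(rec$pcp, 1L)  # gynecology is primary care
  ds2 <- toy_claims(list(S1 = "D"), ages = c(S1 = 70L),
                    specialties = c(D = "dermatology"))
  rec2 <- practice_records(ds2, data.frame(patient_id = "S1", over = 0L,
                                           under = 0L, score = 0L),
                           filter_config())
  expect_equal(rec2$pcp, 0L)
})
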
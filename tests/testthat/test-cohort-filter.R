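# Eligibility filtering and the sample-flow report.

make_panel <- function(practice, n, prefix) {
  members <- replicate(n, practice, simplify = FALSE)
  names(members) <- sprintf("%s%03d", prefix, seq_len(n))
  members
}

test_that("the minimum-panel boundary keeps 30 and drops 29 unique patients", {
  members <- c(make_panel("KEEP", 30, "K"), make_panel("DROP", 29, "D"))
  ds <- toy_claims(members)
  out <- filter_for_network(ds, filter_config())
  expect_setequal(out$practices$practice_id, "KEEP")
  strict <- filter_for_network(ds, filter_config(min_patients_comparison = "gt"))
  expect_equal(nrow(strict$practices), 0)
})

test_that("excluded specialties are removed with their encounters", {
  ds <- toy_claims(list(P1 = c("A", "R"), P2 = c("A", "R")),
                   specialties = c(A = "general_practice", R = "radiology"))
  out <- filter_for_network(ds, filter_config(min_patients = 1))
  expect_setequal(out$practices$practice_id, "A")
  expect_true(all(out$encounters$practice_id == "A"))
})

test_that("a hand-enumerated 6-practice toy leaves 3 survivors", {
  # A, B excluded specialties; C a small panel; D, E, F survive
  members <- c(
    lapply(setNames(nm = sprintf("PA%02d", 1:6)), function(i) "A"),
    lapply(setNames(nm = sprintf("PB%02d", 1:6)), function(i) "B"),
    lapply(setNames(nm = sprintf("PC%02d", 1:4)), function(i) "C"),
    lapply(setNames(nm = sprintf("PD%02d", 1:7)), function(i) c("D", "E")),
    lapply(setNames(nm = sprintf("PF%02d", 1:5)), function(i) "F"))
  ds <- toy_claims(members, specialties = c(
    A = "radiology", B = "nuclear_medicine", C = "dermatology",
    D = "general_practice", E = "cardiology", F = "gynecology"))
  out <- filter_for_network(ds, filter_config(min_patients = 5))
  expect_setequal(out$practices$practice_id, c("D", "E", "F"))
  flow <- sample_flow(out)
  # hand counts: 28 patients / 6 practices / 35 claims initially; dropping
  # A and B removes 12 patients and 12 claims; C (4 patients) fails the
  # 5-patient minimum
  expect_equal(flow$n_practices, c(6, 4, 4, 4, 3))
  expect_equal(flow$n_patients, c(28, 16, 16, 16, 12))
  expect_equal(flow$n_claims, c(35, 23, 23, 23, 19))
})

test_that("emergency and off-year claims are removed in order", {
  members <- list(P1 = c("A", "A", "A"), P2 = "A", P3 = "A")
  ds <- toy_claims(members,
                   years = c(2016L, 2015L, 2016L, 2016L, 2016L),
                   emergency = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filter_for_network(ds, filter_config(min_patients = 1))
  expect_equal(nrow(out$encounters), 3)
  expect_true(all(out$encounters$year == 2016))
  expect_true(all(!out$encounters$emergency))
})

test_that("an absent year yields an empty result with a warning", {
  ds <- toy_claims(list(P1 = "A"), year = 2016)
  expect_warning(out <- filter_for_network(ds, filter_config(year = 1999,
                                                             min_patients = 1)),
                 "1999")
  expect_equal(nrow(out$encounters), 0)
})

test_that("filtering is idempotent and the flow is non-increasing", {
  ds <- generate_claims(mini_cfg(21))
  fc <- filter_config()
  once <- filter_for_network(ds, fc)
  twice <- filter_for_network(once, fc)
  expect_claims_equal(once, twice)
  flow <- sample_flow(once)
  for (col in c("n_practices", "n_patients", "n_claims")) {
    expect_true(all(diff(flow[[col]]) <= 0))
  }
  expect_equal(flow$n_practices[nrow(flow)], nrow(once$practices))
  expect_equal(flow$n_claims[nrow(flow)], nrow(once$encounters))
})

test_that("the analytic sample keeps exactly the practices with seniors", {
  members <- list(Y1 = c("A", "B"), Y2 = c("A", "B"), S1 = "A")
  ds <- toy_claims(members, ages = c(Y1 = 40L, Y2 = 50L, S1 = 70L))
  fc <- filter_config(min_patients = 1)
  an <- analytic_sample(filter_for_network(ds, fc), fc)
  expect_setequal(an$practices$practice_id, "A")
  # a practice with one 70-year-old among many youngsters is retained
  members2 <- c(make_panel("A", 39, "Y"), list(S1 = "A"))
  ds2 <- toy_claims(members2, ages = c(setNames(rep(30L, 39),
                                                sprintf("Y%03d", 1:39)),
                                       S1 = 70L))
  an2 <- analytic_sample(filter_for_network(ds2, fc), fc)
  expect_setequal(an2$practices$practice_id, "A")
})

test_that("an all-senior dataset passes the analytic filter unchanged", {
  ds <- toy_claims(list(S1 = c("A", "B"), S2 = c("A", "B"), S3 = "B"),
                   ages = c(S1 = 70L, S2 = 80L, S3 = 90L))
  fc <- filter_config(min_patients = 1)
  nf <- filter_for_network(ds, fc)
  an <- analytic_sample(nf, fc)
  expect_claims_equal(nf, an)
})

test_that("the network sample contains the analytic sample", {
  ds <- generate_claims(mini_cfg(22))
  fc <- filter_config()
  nf <- filter_for_network(ds, fc)
  an <- analytic_sample(nf, fc)
  expect_true(all(an$practices$practice_id %in% nf$practices$practice_id))
})
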
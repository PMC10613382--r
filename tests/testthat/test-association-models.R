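# Quartile assignment, association screens and the negative binomial model.

test_that("eight distinct values split into the forced equal quarters", {
  qa <- assign_quartiles(setNames(1:8, paste0("p", 1:8)))
  got <- split(qa$practice_id, qa$quartile)
  expect_setequal(got$Q1, c("p7", "p8"))
  expect_setequal(got$Q2, c("p5", "p6"))
  expect_setequal(got$Q3, c("p3", "p4"))
  expect_setequal(got$Q4, c("p1", "p2"))
})

test_that("identical values collapse into one quartile with a warning", {
  expect_warning(qa <- assign_quartiles(setNames(rep(2, 6), paste0("p", 1:6))),
                 "identical")
  expect_true(all(qa$quartile == "Q1"))
})

test_that("quartiles are assigned independently per region", {
  vals <- setNames(c(1:8, 101:108), paste0("p", 1:16))
  region <- rep(c("lo", "hi"), each = 8)
  qa <- assign_quartiles(vals, region)
  q_of <- setNames(as.character(qa$quartile), qa$practice_id)
  # the top of the low region is Q1 there despite being below the high
  # region's Q4 cut
  expect_equal(unname(q_of["p8"]), "Q1")
  expect_equal(unname(q_of["p9"]), "Q4")
  expect_error(assign_quartiles(setNames(1:3, paste0("p", 1:3))), "at least 4")
})

test_that("spearman handles monotone, antitone and tied toy cases", {
  expect_equal(spearman_assoc(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_assoc(1:5, rev(1:5))$rho, -1)
  # rank oracle: d = (-1, 1, -1, 1, 0), sum d^2 = 4, rho = 1 - 24/120
  expect_equal(spearman_assoc(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_warning(out <- spearman_assoc(rep(1, 5), 1:5), "rank variance")
  expect_true(is.na(out$rho))
})

test_that("variance inflation factors match closed forms", {
  X <- data.frame(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1),
                  x3 = c(1, -1, -1, 1))
  expect_equal(unname(vif_table(X)), rep(1, 3))
  set.seed(42)
  x1 <- rnorm(200)
  x2 <- x1 + rnorm(200, sd = 0.1)
  v <- vif_table(data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(v["x2"]), 1 / (1 - cor(x1, x2)^2), tolerance = 1e-10)
  vdup <- suppressWarnings(vif_table(data.frame(a = x1, b = x1)))
  expect_true(all(is.infinite(vdup)))
})

test_that("an intercept-only fit on constant counts recovers log(c)", {
  rec <- data.frame(summed_forta = rep(7L, 50))
  fit <- suppressWarnings(fit_pim_model(rec, formula = summed_forta ~ 1))
  expect_equal(unname(fit$coefficients), log(7), tolerance = 1e-6)
  # at the Poisson boundary the dispersion collapses towards zero
  expect_lt(fit$dispersion, 1e-3)
})

test_that("simulated NB coefficients are recovered within 0.1", {
  set.seed(2024)
  n <- 5000
  x <- rnorm(n)
  y <- rnbinom(n, mu = exp(0.5 + 1.2 * x), size = 2)  # dispersion 0.5
  fit <- fit_pim_model(data.frame(summed_forta = y, x = x),
                       formula = summed_forta ~ x)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.5), 0.1)
  expect_lt(abs(fit$coefficients[["x"]] - 1.2), 0.1)
  expect_lt(abs(fit$dispersion - 0.5), 0.1)
})

test_that("pinning the dispersion near zero reproduces the Poisson fit", {
  set.seed(11)
  x <- rnorm(800)
  y <- rpois(800, exp(1 + 0.5 * x))
  d <- data.frame(summed_forta = y, x = x)
  nb <- fit_pim_model(d, formula = summed_forta ~ x, theta = 1e8)
  pois <- glm(summed_forta ~ x, data = d, family = poisson())
  expect_equal(unname(nb$coefficients), unname(coef(pois)), tolerance = 1e-4)
})

test_that("robust and model-based SEs agree on correctly specified data", {
  set.seed(12)
  n <- 5000
  x <- rnorm(n)
  y <- rnbinom(n, mu = exp(0.8 + 0.6 * x), size = 2)
  fit <- fit_pim_model(data.frame(summed_forta = y, x = x),
                       formula = summed_forta ~ x)
  expect_lt(max(abs(fit$se / fit$model_se - 1)), 0.1)
})

test_that("the model rejects invalid outcomes", {
  expect_error(fit_pim_model(data.frame(summed_forta = c(1.5, 2)),
                             formula = summed_forta ~ 1),
               "non-negative integer")
  expect_error(fit_pim_model(data.frame(summed_forta = c(-1L, 2L)),
                             formula = summed_forta ~ 1),
               "non-negative integer")
})

test_that("IRR tables exponentiate with bracketing Wald intervals", {
  fake <- structure(list(coefficients = c(a = 0, b = -3.22),
                         se = c(a = 0.1, b = 0.064)), class = "pim_fit")
  tab <- irr_table(fake)
  expect_equal(tab$irr[1], 1)
  expect_equal(tab$irr[2], exp(-3.22))
  expect_equal(tab$lo[2], exp(-3.22 - 1.96 * 0.064), tolerance = 1e-4)
  expect_equal(tab$hi[2], exp(-3.22 + 1.96 * 0.064), tolerance = 1e-4)
  expect_true(all(tab$lo <= tab$irr & tab$irr <= tab$hi))
})

test_that("the three model variants fit on generated records", {
  cfg <- mini_cfg(77)
  ds <- generate_claims(cfg)
  fc <- filter_config()
  nf <- filter_for_network(ds, fc)
  an <- analytic_sample(nf, fc)
  cents <- do.call(rbind, lapply(regions(nf), function(r)
    suppressMessages(centrality_table(build_practice_network(nf, r)))))
  scores <- pim_scores(an, cfg$rule_table, fc)
  rec <- add_centralities(practice_records(an, scores, fc, region_levels = cfg$regions), cents)
  rec <- add_quartiles(rec, "degree")
  fits <- lapply(c("centrality", "controls", "full"), function(m)
    fit_pim_model(rec, m))
  expect_true(all(vapply(fits, function(f) is.finite(f$aic), logical(1))))
  expect_true(all(vapply(fits, function(f) f$dispersion > 0, logical(1))))
})

test_that("robust SEs exceed model-based SEs under heteroskedastic dispersion", {
  set.seed(33)
  n <- 4000
  x <- rnorm(n)
  # strong overdispersion only where x > 0: the constant-variance-function
  # model understates the slope SE, the sandwich estimate does not
  u <- ifelse(x > 0, rgamma(n, shape = 0.3, rate = 0.3), 1)
  y <- rpois(n, exp(1 + 0.5 * x) * u)
  fit <- fit_pim_model(data.frame(summed_forta = y, x = x),
                       formula = summed_forta ~ x, theta = 1e8)
  expect_gt(fit$se[["x"]], 1.2 * fit$model_se[["x"]])
})
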
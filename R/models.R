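# Within-region centrality quartiles, correlation/collinearity screens, and
# the pooled negative binomial regression reported as incidence rate ratios.

#' Assign within-region centrality quartiles
#'
#' Cut points are the empirical 25/50/75 percentiles of the measure within
#' each region. Q1 is the most well-connected quartile (highest centrality)
#' and serves as the reference in the models; values tied with a cut point
#' are assigned to the better-connected side, deterministically.
#'
#' @param values numeric vector of centrality values, named by practice id.
#' @param region factor/character of the same length giving each practice's
#'   region (a single region may be passed as NULL).
#' @param measure label stored in the output (e.g. `"degree"`).
#' @return data frame with `practice_id`, `measure`, `quartile` (factor
#'   Q1..Q4, Q1 = reference).
#' @export
assign_quartiles <- function(values, region = NULL, measure = "degree") {
  if (is.null(region)) region <- rep("all", length(values))
  stopifnot(length(region) == length(values))
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  out <- lapply(split(seq_along(values), region), function(idx) {
    x <- values[idx]
    if (length(x) < 4)
      stop("need at least 4 practices per region to form quartiles")
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    q <- ifelse(x >= qs[3], 1L, ifelse(x >= qs[2], 2L, ifelse(x >= qs[1], 3L, 4L)))
    if (length(unique(x)) == 1)
      warning("all centrality values identical within a region: single quartile")
    data.frame(practice_id = names(x), quartile = q, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  data.frame(practice_id = out$practice_id,
             measure = measure,
             quartile = factor(paste0("Q", out$quartile),
                               levels = paste0("Q", 1:4)),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties and a two-sided p-value
#' (asymptotic; the outcome counts are heavily tied).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`; both NA (with a warning) when either
#'   variable has zero rank variance.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of predictor j on the remaining predictors (with intercept).
#' Exact collinearity is reported as `Inf`.
#'
#' @param X numeric matrix or data frame of predictors (no intercept
#'   column).
#' @return named numeric vector of VIFs.
#' @export
vif_table <- function(X) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  v <- vapply(seq_along(X), function(j) {
    if (stats::sd(X[[j]]) == 0) {
      warning(sprintf("predictor '%s' has zero variance: VIF undefined",
                      names(X)[j]))
      return(NA_real_)
    }
    fit <- lm(X[[j]] ~ ., data = X[-j])
    r2 <- summary(fit)$r.squared
    if (is.na(r2)) NA_real_ else if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE)
  setNames(v, names(X))
}

#' Fit the negative binomial PIM model
#'
#' NB2 log-link regression of the practice-level summed PIM score. Three
#' model variants mirror the analysis design: `"centrality"` (quartiles
#' only), `"controls"` (covariates only) and `"full"` (both). The dispersion
#' parameter is estimated by maximum likelihood (via [MASS::glm.nb()]),
#' unless `theta` pins it; standard errors are heteroskedasticity-robust
#' sandwich estimates (HC0 by default). Complete-case rows are used and the
#' number used is reported.
#'
#' @param records a [practice_records()] frame carrying a `quartile` column
#'   (see [assign_quartiles()] / [add_centralities()]).
#' @param model `"full"` (default), `"centrality"` or `"controls"`.
#' @param theta optional fixed NB size parameter (dispersion = 1/theta); by
#'   default estimated by ML.
#' @param robust sandwich flavour, `"HC0"` (default) or `"HC1"`;
#'   `"model"` uses the model-based covariance instead.
#' @param formula optional formula overriding the model variant entirely.
#' @return a `pim_fit` object: coefficients, robust SEs, dispersion, AIC,
#'   n used, and the underlying glm fit.
#' @export
fit_pim_model <- function(records, model = c("full", "centrality", "controls"),
                          theta = NULL, robust = c("HC0", "HC1", "model"),
                          formula = NULL) {
  model <- match.arg(model)
  robust <- match.arg(robust)
  if (is.null(formula)) {
    rhs <- switch(model,
      centrality = "quartile",
      controls = "pct_seniors + mean_charlson + pcp + region",
      full = "quartile + pct_seniors + mean_charlson + pcp + region")
    # a single-region dataset carries no region contrast
    if (length(unique(records$region)) < 2)
      rhs <- sub(" \\+ region$", "", rhs)
    formula <- as.formula(paste("summed_forta ~", rhs))
  }
  vars <- all.vars(formula)
  yname <- vars[1]
  y <- records[[yname]]
  if (any(y < 0, na.rm = TRUE) || any(y != round(y), na.rm = TRUE))
    stop("outcome must be a non-negative integer count")
  keep <- complete.cases(records[intersect(vars, names(records))])
  dat <- droplevels(records[keep, , drop = FALSE])
  boundary <- FALSE
  fit <- if (is.null(theta)) {
    # ML dispersion can sit at the Poisson boundary (no overdispersion);
    # theta.ml then diverges, and the fit falls back to a pinned large theta
    f <- tryCatch(MASS::glm.nb(formula, data = dat), error = function(e) NULL)
    if (is.null(f)) {
      boundary <- TRUE
      glm(formula, data = dat, family = MASS::negative.binomial(theta = 1e8))
    } else f
  } else {
    glm(formula, data = dat, family = MASS::negative.binomial(theta = theta))
  }
  if (is.null(theta) && !boundary && !fit$converged)
    stop("negative binomial fit did not converge after ",
         fit$iter %||% NA, " iterations")
  th <- theta %||% (if (boundary) 1e8 else fit$theta)
  vc <- switch(robust,
               model = vcov(fit),
               sandwich::vcovHC(fit, type = robust))
  structure(list(
    coefficients = coef(fit),
    se = sqrt(diag(vc)),
    model_se = sqrt(diag(vcov(fit))),
    vcov = vc,
    theta = th,
    dispersion = 1 / th,
    aic = AIC(fit),
    n = nobs(fit),
    model = model,
    robust = robust,
    formula = formula,
    fit = fit), class = "pim_fit")
}

#' @export
print.pim_fit <- function(x, ...) {
  cat(sprintf("<pim_fit> %s model, n = %d, dispersion = %.4g, AIC = %.1f (%s SEs)\n",
              x$model, x$n, x$dispersion, x$aic, x$robust))
  print(irr_table(x), digits = 3)
  invisible(x)
}

#' Incidence rate ratios with Wald confidence intervals
#'
#' Exponentiated coefficients of a fitted PIM model with 95% Wald intervals
#' built from the robust standard errors.
#'
#' @param fit a `pim_fit`.
#' @param level confidence level (default 0.95).
#' @return data frame with `term`, `irr`, `lo`, `hi`, `se`, `p`.
#' @export
irr_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pim_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- fit$se
  data.frame(term = names(b),
             irr = exp(b),
             lo = exp(b - z * se),
             hi = exp(b + z * se),
             se = se,
             p = 2 * pnorm(-abs(b / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attach a measure's quartiles to practice records
#'
#' @param records a [practice_records()] frame with centrality columns.
#' @param measure `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @return records with a `quartile` factor column (NA rows dropped from the
#'   quartile computation but retained with NA quartile).
#' @export
add_quartiles <- function(records, measure = c("degree", "betweenness",
                                               "eigenvector")) {
  measure <- match.arg(measure)
  vals <- records[[measure]]
  ok <- !is.na(vals)
  qa <- assign_quartiles(setNames(vals[ok], records$practice_id[ok]),
                         region = as.character(records$region)[ok],
                         measure = measure)
  records$quartile <- qa$quartile[match(records$practice_id, qa$practice_id)]
  records
}
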
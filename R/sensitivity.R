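# Robustness checks: (i) remap the network using only patients under 65 and
# re-derive centralities for the unchanged analytic sample; (ii) remap with
# the tie threshold raised (default 25) and refit.

#' Remap the network using only under-65 patients
#'
#' Rebuilds the per-region patient-sharing networks from the encounters of
#' patients younger than the senior cutoff, at the same tie threshold as the
#' main analysis. The node set is the full practice set of the input
#' dataset: practices with no under-65 encounters at all are absent from the
#' remapped claim set and get `NA` centralities (they are dropped from model
#' fits downstream, with a message); practices that merely lose all their
#' ties stay in with centrality 0.
#'
#' @param x the network-filtered [claims_dataset()] of the main analysis.
#' @param config a [filter_config()].
#' @param threshold tie threshold (default 8, as in the main analysis).
#' @return list with `networks` (per region) and `centralities` (row-bound
#'   [centrality_table()] with NA rows for absent practices).
#' @export
remap_under65 <- function(x, config = filter_config(), threshold = 8) {
  stopifnot(inherits(x, "claims_dataset"))
  young <- x$patients$patient_id[!is_senior(x$patients$age,
                                            config$senior_age_cutoff,
                                            config$senior_comparison)]
  y <- x
  y$encounters <- y$encounters[y$encounters$patient_id %in% young, , drop = FALSE]
  if (nrow(y$encounters) == 0)
    stop("no encounters by under-65 patients: cannot remap the network")
  y$prescriptions <- y$prescriptions[
    y$prescriptions$encounter_id %in% y$encounters$encounter_id, , drop = FALSE]
  # keep the full practice node set; mark practices absent from the young
  # claim set
  present <- unique(y$encounters$practice_id)
  absent <- setdiff(x$practices$practice_id, present)
  if (length(absent) > 0) {
    message(sprintf(
      "%d practice(s) absent from the under-65 claim set: centralities set to NA",
      length(absent)))
  }
  nets <- list(); cents <- list()
  for (r in regions(x)) {
    net <- build_practice_network(y, region = r, threshold = threshold)
    ct <- suppressMessages(centrality_table(net))
    nets[[r]] <- net
    cents[[r]] <- ct
  }
  cent <- do.call(rbind, cents)
  rownames(cent) <- NULL
  cent[cent$practice_id %in% absent, c("degree", "betweenness", "eigenvector")] <- NA
  list(networks = nets, centralities = cent)
}

#' Remap the network at a higher tie threshold
#'
#' Rebuilds the per-region networks with the raised shared-patient threshold
#' (default 25). With `drop_isolates = TRUE` (default), practices left
#' without any retained tie get `NA` centralities so that model fits exclude
#' them; with `FALSE` they keep centrality 0 and fall into the
#' least-connected quartile.
#'
#' @param x the network-filtered [claims_dataset()].
#' @param threshold raised tie threshold (default 25).
#' @param drop_isolates drop tie-less practices from model fits (default
#'   TRUE).
#' @return list with `networks` and `centralities` as in [remap_under65()].
#' @export
remap_threshold <- function(x, threshold = 25, drop_isolates = TRUE) {
  stopifnot(inherits(x, "claims_dataset"))
  nets <- list(); cents <- list()
  for (r in regions(x)) {
    net <- build_practice_network(x, region = r, threshold = threshold)
    ct <- suppressMessages(centrality_table(net))
    nets[[r]] <- net
    cents[[r]] <- ct
  }
  cent <- do.call(rbind, cents)
  rownames(cent) <- NULL
  if (drop_isolates) {
    iso <- cent$degree == 0
    if (any(iso)) {
      message(sprintf(
        "%d practice(s) without ties at threshold %d dropped from model fits",
        sum(iso), threshold))
      cent[iso, c("degree", "betweenness", "eigenvector")] <- NA
    }
  }
  list(networks = nets, centralities = cent)
}

#' Run a sensitivity scenario end to end
#'
#' Replaces the centrality columns of the main-analysis practice records
#' with the remapped ones (outcome and covariates untouched), re-derives
#' within-region quartiles, and refits the full negative binomial model per
#' measure.
#'
#' @param x the network-filtered [claims_dataset()].
#' @param records the main-analysis [practice_records()] (with or without
#'   centrality columns; they are replaced).
#' @param scenario `"under65"` or `"threshold25"`.
#' @param config a [filter_config()].
#' @param threshold tie threshold of the remap (defaults: 8 for under65, 25
#'   for threshold25).
#' @param measures centrality measures to refit.
#' @param ... passed to [fit_pim_model()].
#' @return a `sensitivity_result`: scenario label, remapped networks,
#'   updated records, per-measure fits and IRR tables, and n used.
#' @export
run_sensitivity <- function(x, records, scenario = c("under65", "threshold25"),
                            config = filter_config(), threshold = NULL,
                            measures = c("degree", "betweenness", "eigenvector"),
                            ...) {
  scenario <- match.arg(scenario)
  remap <- if (scenario == "under65") {
    remap_under65(x, config, threshold = threshold %||% 8)
  } else {
    remap_threshold(x, threshold = threshold %||% 25)
  }
  rec2 <- add_centralities(records, remap$centralities)
  fits <- list(); irrs <- list()
  for (m in measures) {
    fit <- tryCatch({
      rm_ <- suppressWarnings(add_quartiles(rec2, m))
      fit_pim_model(rm_, model = "full", ...)
    }, error = function(e) {
      message(sprintf(
        "scenario %s, measure %s: model not estimable (%s); reported as a gap",
        scenario, m, conditionMessage(e)))
      NULL
    })
    fits[m] <- list(fit)
    irrs[m] <- list(if (is.null(fit)) NULL else irr_table(fit))
  }
  structure(list(scenario = scenario,
                 networks = remap$networks,
                 records = rec2,
                 fits = fits,
                 irr = irrs,
                 n = vapply(fits, function(f) if (is.null(f)) NA_real_
                            else as.numeric(f$n), numeric(1))),
            class = "sensitivity_result")
}

#' Compare main and sensitivity IRR estimates
#'
#' Side-by-side incidence rate ratios (Q2--Q4 versus Q1) per centrality
#' measure and scenario, with flags marking scenarios whose IRR direction
#' (above/below 1) or significance (95% CI excluding 1) differs from the
#' main analysis. A missing scenario is emitted with NA values as an
#' explicit gap.
#'
#' @param main named list of main-analysis IRR tables (one per measure, as
#'   from [irr_table()]).
#' @param sensitivity named list of `sensitivity_result`s (or of per-measure
#'   IRR-table lists); NULL elements mark missing scenarios.
#' @return long data frame: measure, term, scenario, irr, lo, hi,
#'   `direction_change`, `significance_change`.
#' @export
compare_scenarios <- function(main, sensitivity) {
  qterms <- function(tab) tab[grepl("^quartileQ", tab$term), , drop = FALSE]
  out <- list()
  for (m in names(main)) {
    base <- qterms(main[[m]])
    base$scenario <- "main"
    base$direction_change <- FALSE
    base$significance_change <- FALSE
    out[[length(out) + 1L]] <- cbind(measure = m, base)
    for (s in names(sensitivity)) {
      res <- sensitivity[[s]]
      tab <- if (is.null(res)) NULL
             else if (inherits(res, "sensitivity_result")) res$irr[[m]]
             else res[[m]]
      if (is.null(tab)) {
        gap <- base
        gap[c("irr", "lo", "hi", "se", "p")] <- NA_real_
        gap$scenario <- s
        gap$direction_change <- NA
        gap$significance_change <- NA
        out[[length(out) + 1L]] <- cbind(measure = m, gap)
        next
      }
      tab <- qterms(tab)
      tab <- tab[match(base$term, tab$term), , drop = FALSE]
      tab$scenario <- s
      tab$direction_change <- sign(tab$irr - 1) != sign(base$irr - 1)
      tab$significance_change <- ((tab$lo > 1 | tab$hi < 1) !=
                                    (base$lo > 1 | base$hi < 1))
      out[[length(out) + 1L]] <- cbind(measure = m, tab)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
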
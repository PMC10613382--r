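# End-to-end orchestration: claims -> samples -> networks -> metrics ->
# scores -> models -> sensitivity -> reports, with CSV/JSON artifacts.

#' Descriptive report of patients, practices and networks
#'
#' Publication-style per-region tables: senior patient characteristics
#' (count, % female, median/IQR age, median/IQR Charlson), practice
#' characteristics (count, median/IQR panel size, % primary care), node
#' centrality medians/IQRs, and the network-level summary including the
#' random-graph baseline. IQRs are reported as the single number Q3 - Q1.
#'
#' @param x the analytic [claims_dataset()].
#' @param records a [practice_records()] frame with centrality columns.
#' @param summaries optional row-bound [network_summary()] frames.
#' @param config a [filter_config()].
#' @return list of data frames: `patients`, `practices`, `centrality`,
#'   `network`.
#' @export
descriptive_report <- function(x, records, summaries = NULL,
                               config = filter_config()) {
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(median(v), unname(diff(quantile(v, c(0.25, 0.75)))))
  }
  pat_rows <- list(); pr_rows <- list(); cen_rows <- list()
  for (r in regions(x)) {
    pats <- x$patients[x$patients$region == r, , drop = FALSE]
    sen <- pats[is_senior(pats$age, config$senior_age_cutoff,
                          config$senior_comparison), , drop = FALSE]
    ch <- if (nrow(sen) > 0) charlson_scores(sen) else integer()
    a <- med_iqr(sen$age); cc <- med_iqr(ch)
    pat_rows[[r]] <- data.frame(
      region = r, n_patients = nrow(sen),
      pct_female = if (nrow(sen) > 0) 100 * mean(sen$sex == "F") else NA_real_,
      age_median = a[1], age_iqr = a[2],
      charlson_median = cc[1], charlson_iqr = cc[2],
      stringsAsFactors = FALSE)
    rec <- records[records$region == r, , drop = FALSE]
    p <- med_iqr(rec$n_patients)
    pr_rows[[r]] <- data.frame(
      region = r, n_practices = nrow(rec),
      panel_median = p[1], panel_iqr = p[2],
      pct_pcp = if (nrow(rec) > 0) 100 * mean(rec$pcp) else NA_real_,
      stringsAsFactors = FALSE)
    for (m in c("degree", "betweenness", "eigenvector")) {
      v <- med_iqr(rec[[m]])
      cen_rows[[paste(r, m)]] <- data.frame(
        region = r, measure = m, median = v[1], iqr = v[2],
        stringsAsFactors = FALSE)
    }
  }
  list(patients = do.call(rbind, c(pat_rows, list(make.row.names = FALSE))),
       practices = do.call(rbind, c(pr_rows, list(make.row.names = FALSE))),
       centrality = do.call(rbind, c(cen_rows, list(make.row.names = FALSE))),
       network = summaries)
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on one configuration: generate (or take) the
#' claims, apply the eligibility filters, map the per-region patient-sharing
#' networks, compute node- and network-level measures, score PIMs and build
#' practice records, derive within-region quartiles, fit the three
#' negative binomial model variants per centrality measure, run both
#' sensitivity scenarios, and emit descriptive reports. When `out_dir` is
#' given, all artifacts are written as CSV/JSON plus a plain-text run log;
#' outputs are deterministic for a fixed config (no timestamps), so two runs
#' with the same config and seed produce identical files.
#'
#' @param config a [sim_config()]; ignored if `dataset` is supplied.
#' @param dataset an existing [claims_dataset()] (optional).
#' @param out_dir artifact directory (optional).
#' @param filter a [filter_config()]; defaults to the config's year and
#'   senior cutoff.
#' @param threshold tie threshold of the main analysis (default 8).
#' @param measures centrality measures to model.
#' @param baseline_reps random graphs for the mean-distance baseline.
#' @param baseline_seed seed of the baseline draws (defaults to the config
#'   seed).
#' @param sensitivity run the two sensitivity scenarios (default TRUE).
#' @param rules a [pim_rules()] table; defaults to the config's rule table.
#' @return (invisibly) a list with the dataset, samples, networks,
#'   summaries, records, fits, IRR tables, spearman screen, VIFs,
#'   sensitivity results and the descriptive report.
#' @export
run_pipeline <- function(config = NULL, dataset = NULL, out_dir = NULL,
                         filter = NULL, threshold = 8,
                         measures = c("degree", "betweenness", "eigenvector"),
                         baseline_reps = 1000, baseline_seed = NULL,
                         sensitivity = TRUE, rules = NULL) {
  if (is.null(dataset)) {
    stopifnot(inherits(config, "sim_config"))
    dataset <- generate_claims(config)
  }
  if (is.null(filter)) {
    filter <- if (!is.null(config)) {
      filter_config(year = config$year,
                    senior_age_cutoff = config$senior_age_cutoff)
    } else filter_config()
  }
  rules <- rules %||% (if (!is.null(config)) config$rule_table
                       else default_pim_rules())
  baseline_seed <- baseline_seed %||% (if (!is.null(config)) config$seed else 1L)
  region_levels <- if (!is.null(config)) config$regions else NULL

  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }

  nf <- filter_for_network(dataset, filter)
  an <- analytic_sample(nf, filter)
  flow <- sample_flow(an)
  for (i in seq_len(nrow(flow))) {
    say("sample flow | %s: %d practices, %d patients, %d claims",
        flow$step[i], flow$n_practices[i], flow$n_patients[i], flow$n_claims[i])
  }

  networks <- list(); summaries <- list(); cents <- list()
  for (i in seq_along(regions(nf))) {
    r <- regions(nf)[i]
    net <- build_practice_network(nf, region = r, threshold = threshold)
    networks[[r]] <- net
    summaries[[r]] <- network_summary(net, baseline_reps = baseline_reps,
                                      seed = baseline_seed + i)
    cents[[r]] <- suppressMessages(centrality_table(net))
    say("network %s: %d nodes, %d ties, density %.4f", r,
        summaries[[r]]$n_nodes, summaries[[r]]$n_edges, summaries[[r]]$density)
  }
  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  centralities <- do.call(rbind, c(cents, list(make.row.names = FALSE)))

  scores <- pim_scores(an, rules, filter)
  records <- practice_records(an, scores, filter,
                              region_levels = region_levels)
  records <- add_centralities(records, centralities)
  say("analytic sample: %d practices, %d scored seniors, total summed score %d",
      nrow(records), nrow(scores), sum(records$summed_forta))

  fits <- list(); irrs <- list(); spear <- list()
  for (m in measures) {
    rm_ <- add_quartiles(records, m)
    fits[[m]] <- list(
      centrality = fit_pim_model(rm_, model = "centrality"),
      controls = fit_pim_model(rm_, model = "controls"),
      full = fit_pim_model(rm_, model = "full"))
    irrs[[m]] <- irr_table(fits[[m]]$full)
    sp <- spearman_assoc(records[[m]], records$summed_forta)
    spear[[m]] <- data.frame(measure = m, rho = sp$rho, p = sp$p,
                             stringsAsFactors = FALSE)
    q4 <- irrs[[m]]$irr[irrs[[m]]$term == "quartileQ4"]
    say("model %s: full AIC %.1f (n=%d), controls AIC %.1f, Q4 IRR %.4f",
        m, fits[[m]]$full$aic, fits[[m]]$full$n, fits[[m]]$controls$aic,
        if (length(q4) == 1) q4 else NA_real_)
  }
  spear <- do.call(rbind, c(spear, list(make.row.names = FALSE)))

  X <- records[c("pct_seniors", "mean_charlson", "pcp", "region_dummy")]
  X$degree <- records$degree
  X <- X[complete.cases(X), ]
  X <- X[vapply(X, function(col) stats::sd(col) > 0, logical(1))]
  vifs <- vif_table(X)

  sens <- NULL; comparison <- NULL
  if (sensitivity) {
    sens <- list(
      under65 = suppressMessages(
        run_sensitivity(nf, records, "under65", filter, measures = measures)),
      threshold25 = suppressMessages(
        run_sensitivity(nf, records, "threshold25", filter,
                        measures = measures)))
    comparison <- compare_scenarios(irrs, sens)
    for (s in names(sens)) {
      say("sensitivity %s: n used %s", s,
          paste(sprintf("%s=%s", names(sens[[s]]$n), sens[[s]]$n),
                collapse = ", "))
    }
  }

  report <- descriptive_report(an, records, summaries, filter)

  result <- list(dataset = dataset, network_sample = nf, analytic = an,
                 flow = flow, networks = networks, summaries = summaries,
                 centralities = centralities, scores = scores,
                 records = records, fits = fits, irr = irrs,
                 spearman = spear, vif = vifs, sensitivity = sens,
                 comparison = comparison, report = report,
                 log = log_lines)
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  invisible(result)
}

coef_frame <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = unname(fit$se),
             model_se = unname(fit$model_se),
             stringsAsFactors = FALSE)
}

write_artifacts <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) write.csv(df, file.path(out_dir, name),
                                       row.names = FALSE)
  write_claims(result$analytic, file.path(out_dir, "analytic_sample"))
  wcsv(result$flow, "sample_flow.csv")
  wcsv(result$summaries, "network_summary.csv")
  wcsv(result$centralities, "centralities.csv")
  wcsv(result$scores, "patient_scores.csv")
  wcsv(result$records, "practice_records.csv")
  wcsv(result$spearman, "spearman.csv")
  wcsv(data.frame(predictor = names(result$vif), vif = unname(result$vif)),
       "vif.csv")
  for (r in names(result$networks)) {
    write_edge_list(result$networks[[r]],
                    file.path(out_dir, sprintf("network_%s_edges.csv", r)))
    write_network_graphml(result$networks[[r]],
                          file.path(out_dir, sprintf("network_%s.graphml", r)))
  }
  stats <- list()
  for (m in names(result$fits)) {
    wcsv(irr_table(result$fits[[m]]$full), sprintf("irr_%s.csv", m))
    for (v in names(result$fits[[m]])) {
      wcsv(coef_frame(result$fits[[m]][[v]]),
           sprintf("coef_%s_%s.csv", m, v))
      f <- result$fits[[m]][[v]]
      stats[[m]][[v]] <- list(aic = f$aic, n = f$n, dispersion = f$dispersion)
    }
  }
  jsonlite::write_json(stats, file.path(out_dir, "model_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$comparison)) wcsv(result$comparison,
                                        "sensitivity_comparison.csv")
  wcsv(result$report$patients, "report_patients.csv")
  wcsv(result$report$practices, "report_practices.csv")
  wcsv(result$report$centrality, "report_centrality.csv")
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
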
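# Synthetic claims generator with a planted centrality-to-PIM association.
#
# The generator works in three passes:
#   1. structure: practices (specialty, community, two independent
#      attractiveness weights) and patients (age, sex, Charlson conditions),
#      then the patient-practice affiliation graph -- younger patients visit
#      several practices (preferential attachment within communities),
#      seniors attend a single primary practice -- and baseline encounters
#      with year and emergency flags;
#   2. planting: the package's own default filter -> network -> degree ->
#      within-region quartile chain is run on the baseline claims, each
#      analytic practice gets the planted rate-ratio multiplier of its
#      realized degree quartile together with a Gamma latent quality, and
#      every eligible senior draws an annual PIM event count from
#      Poisson(base rate x quartile multiplier x practice quality x region
#      ratio) -- marginally negative binomial at the practice level with the
#      configured dispersion;
#   3. emission: each planted event is materialized as a diagnosis /
#      prescription combination that the scoring engine counts back exactly
#      (over events: a contraindicated class at a dedicated encounter;
#      under events: an indicated class left unprescribed, with the rule's
#      remaining indicated classes covered by maintenance prescriptions).

.specialist_pool <- c("cardiology", "dermatology", "orthopedics", "neurology",
                      "ophthalmology", "ent", "urology", "psychiatry",
                      "pulmonology", "gastroenterology")

#' Generate a synthetic claims dataset
#'
#' @param config a [sim_config()].
#' @return a [claims_dataset()]; identical config and seed give
#'   byte-identical tables.
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, generate_claims_impl(config))
}

generate_claims_impl <- function(config) {
  K <- length(config$regions)
  practices <- list(); patients <- list(); pairs <- list()
  w_senior_all <- numeric(); primary_all <- character()
  pr_offset <- 0L; pat_offset <- 0L

  for (k in seq_len(K)) {
    n_pr <- config$n_practices_per_region[k]
    n_pat <- config$n_patients_per_region[k]
    pr_ids <- sprintf("PR%04d", pr_offset + seq_len(n_pr))
    pat_ids <- sprintf("P%06d", pat_offset + seq_len(n_pat))
    pr_offset <- pr_offset + n_pr; pat_offset <- pat_offset + n_pat

    # practices ---------------------------------------------------------
    specialty <- character(n_pr)
    if (n_pr > 0) {
      excl <- runif(n_pr) < config$excluded_specialty_fraction
      specialty[excl] <- sample(default_excluded_specialties(), sum(excl), TRUE)
      pcp <- !excl & runif(n_pr) < config$pcp_fraction[k]
      specialty[pcp] <- sample(pcp_specialties(), sum(pcp), TRUE,
                               prob = c(0.55, 0.25, 0.20))
      rest <- !excl & !pcp
      specialty[rest] <- sample(.specialist_pool, sum(rest), TRUE)
    }
    community <- if (n_pr > 0) sample.int(config$n_communities[k], n_pr, TRUE)
                 else integer()
    w_young <- rlnorm(n_pr, 0, config$panel_size_skew)
    w_senior <- rlnorm(n_pr, 0, config$panel_size_skew)
    practices[[k]] <- data.frame(practice_id = pr_ids, specialty = specialty,
                                 region = rep(config$regions[k], n_pr),
                                 stringsAsFactors = FALSE)
    w_senior_all <- c(w_senior_all, w_senior)

    # patients ----------------------------------------------------------
    senior <- runif(n_pat) < config$senior_fraction[k]
    age <- integer(n_pat)
    n_sen <- sum(senior)
    age[senior] <- pmin(
      config$senior_age_cutoff +
        floor(rgamma(n_sen, shape = config$senior_age_shape[k],
                     scale = config$senior_age_scale[k])), 104)
    age[!senior] <- floor(runif(n_pat - n_sen, config$adult_age_range[1],
                                config$senior_age_cutoff))
    sex <- ifelse(runif(n_pat) < config$female_fraction, "F", "M")

    prev <- config$charlson_prevalence
    dx <- rep("", n_pat)
    if (n_pat > 0 && length(prev) > 0) {
      long_pat <- integer(); long_code <- character()
      for (cond in names(prev)) {
        p <- ifelse(senior, prev[[cond]], prev[[cond]] * config$nonsenior_dx_scale)
        hit <- which(runif(n_pat) < p)
        long_pat <- c(long_pat, hit)
        long_code <- c(long_code, rep(cond, length(hit)))
      }
      if (length(long_pat) > 0) {
        by_pat <- split(long_code, long_pat)
        dx[as.integer(names(by_pat))] <-
          vapply(by_pat, function(v) paste(sort(v), collapse = ";"), character(1))
      }
    }
    patients[[k]] <- data.frame(patient_id = pat_ids, age = age,
                                sex = as.character(sex),
                                region = rep(config$regions[k], n_pat),
                                diagnoses = dx, stringsAsFactors = FALSE)

    # affiliation -------------------------------------------------------
    if (n_pat > 0 && n_pr > 0) {
      ns <- which(!senior)
      extras <- rpois(length(ns), config$mean_visits_per_patient - 1)
      first <- sample.int(n_pr, length(ns), TRUE, prob = w_young)
      home <- community[first]
      e_pat <- rep(ns, extras)
      e_home <- rep(home, extras)
      # target community of each extra visit: home with the configured
      # odds; otherwise mostly a ring-adjacent community (communities are
      # laid out like contiguous localities), occasionally any other
      nc <- config$n_communities[k]
      p_within <- config$within_community_odds / (config$within_community_odds + 1)
      u <- runif(length(e_pat))
      target <- e_home
      if (nc > 1) {
        adj <- u >= p_within & u < p_within + (1 - p_within) * 0.7
        step_dir <- sample(c(-1L, 1L), length(e_pat), TRUE)
        target[adj] <- 1L + (e_home[adj] - 1L + step_dir[adj]) %% nc
        far <- u >= p_within + (1 - p_within) * 0.7
        if (any(far)) {
          shift <- 1L + floor(runif(sum(far)) * (nc - 1))
          target[far] <- 1L + (e_home[far] - 1L + shift) %% nc
        }
      }
      chosen <- integer(length(e_pat))
      for (cm in seq_len(nc)) {
        in_c <- which(community == cm)
        rows <- which(target == cm)
        if (length(rows) == 0) next
        pool <- if (length(in_c) > 0) in_c else seq_len(n_pr)
        chosen[rows] <- pool[sample.int(length(pool), length(rows), TRUE,
                                        prob = w_young[pool])]
      }
      prim_sen <- sample.int(n_pr, n_sen, TRUE, prob = w_senior)
      pk <- data.frame(
        patient_id = c(pat_ids[ns], pat_ids[e_pat], pat_ids[senior]),
        practice_id = pr_ids[c(first, chosen, prim_sen)],
        stringsAsFactors = FALSE)
      pk <- unique(pk)
      pk <- pk[order(pk$patient_id, pk$practice_id), , drop = FALSE]
      pairs[[k]] <- pk
      primary_all <- c(primary_all, setNames(pr_ids[prim_sen], pat_ids[senior]))
    } else {
      pairs[[k]] <- data.frame(patient_id = character(),
                               practice_id = character(),
                               stringsAsFactors = FALSE)
    }
  }

  practices <- do.call(rbind, practices)
  patients <- do.call(rbind, patients)
  pairs <- do.call(rbind, pairs)
  rownames(practices) <- rownames(patients) <- rownames(pairs) <- NULL

  # baseline encounters ------------------------------------------------
  n_enc_pair <- if (nrow(pairs) > 0)
    1L + rpois(nrow(pairs), config$encounter_rate - 1) else integer()
  enc <- data.frame(
    patient_id = rep(pairs$patient_id, n_enc_pair),
    practice_id = rep(pairs$practice_id, n_enc_pair),
    stringsAsFactors = FALSE)
  n_enc <- nrow(enc)
  enc$year <- ifelse(runif(n_enc) < config$off_year_fraction,
                     config$year - 1L, config$year)
  enc$emergency <- runif(n_enc) < config$emergency_fraction
  enc$encounter_id <- sprintf("E%07d", seq_len(n_enc))
  enc <- enc[c("encounter_id", "patient_id", "practice_id", "year", "emergency")]

  empty_rx <- data.frame(prescription_id = character(),
                         patient_id = character(), practice_id = character(),
                         encounter_id = character(), year = integer(),
                         drug_class = character(), stringsAsFactors = FALSE)
  ds0 <- claims_dataset(patients, practices, enc, empty_rx, validate = FALSE)

  # planting ------------------------------------------------------------
  planted <- plant_pim_events(ds0, primary_all, config)

  patients$diagnoses <- merge_dx(patients, planted$added_dx)
  enc_all <- rbind(enc, planted$event_encounters)
  enc_all <- enc_all[order(enc_all$encounter_id), , drop = FALSE]
  claims_dataset(patients, practices, enc_all, planted$prescriptions)
}

merge_dx <- function(patients, added) {
  if (length(added) == 0) return(patients$diagnoses)
  idx <- match(names(added), patients$patient_id)
  base <- patients$diagnoses[idx]
  patients$diagnoses[idx] <- vapply(seq_along(added), function(i) {
    old <- if (nzchar(base[i])) strsplit(base[i], ";", fixed = TRUE)[[1]]
           else character()
    paste(sort(unique(c(old, added[[i]]))), collapse = ";")
  }, character(1))
  patients$diagnoses
}

# Draw planted PIM event counts and materialize them as diagnosis /
# prescription combinations. Returns added diagnoses (named list by
# patient), extra event encounters and the prescriptions table.
plant_pim_events <- function(ds0, primary, config) {
  empty <- list(added_dx = list(),
                event_encounters = ds0$encounters[0, , drop = FALSE],
                prescriptions = data.frame(
                  prescription_id = character(), patient_id = character(),
                  practice_id = character(), encounter_id = character(),
                  year = integer(), drug_class = character(),
                  stringsAsFactors = FALSE))
  if (nrow(ds0$patients) == 0 || length(primary) == 0) return(empty)

  fc <- filter_config(year = config$year,
                      senior_age_cutoff = config$senior_age_cutoff)
  nf <- suppressWarnings(filter_for_network(ds0, fc))
  an <- analytic_sample(nf, fc)
  if (nrow(an$practices) == 0) return(empty)

  # quartile multiplier per analytic practice, from realized degree
  mult <- setNames(rep(NA_real_, nrow(ds0$practices)),
                   ds0$practices$practice_id)
  for (r in regions(an)) {
    pr_r <- an$practices$practice_id[an$practices$region == r]
    if (length(pr_r) < 4) {
      warning(sprintf(
        "region %s has fewer than 4 analytic practices: no planted effect there", r))
      next
    }
    net <- build_practice_network(nf, region = r,
                                  threshold = config$tie_threshold)
    deg <- degree_centrality(net)
    deg_r <- deg[pr_r]
    deg_r[is.na(deg_r)] <- 0L
    qa <- suppressWarnings(assign_quartiles(deg_r, measure = "degree"))
    qnum <- as.integer(sub("Q", "", as.character(qa$quartile)))
    mult[qa$practice_id] <- config$planted_quartile_irr[qnum]
  }

  # practice latent quality (Gamma, mean 1, variance = dispersion)
  u <- setNames(rgamma(nrow(ds0$practices), shape = 1 / config$dispersion,
                       rate = 1 / config$dispersion),
                ds0$practices$practice_id)
  region_of <- setNames(ds0$practices$region, ds0$practices$practice_id)
  rrr <- setNames(config$region_rate_ratio, config$regions)

  # eligible seniors: present in the analytic sample with their (single)
  # primary practice carrying a planted multiplier
  elig <- intersect(names(primary), an$patients$patient_id)
  elig <- elig[!is.na(mult[primary[elig]])]
  if (length(elig) == 0) return(empty)
  prim <- primary[elig]
  # The planted gradient is defined on the practice-level outcome scale:
  # per-senior rates are scaled by the practice's senior panel so that the
  # expected practice total is base_rate x mean panel x quality x quartile
  # ratio x region ratio, with no separate panel-size channel (the analysis
  # model carries no size offset).
  n_sen_pr <- table(prim)
  mean_panel <- tapply(as.integer(n_sen_pr), region_of[names(n_sen_pr)], mean)
  lambda <- config$base_pim_rate * mult[prim] * u[prim] *
    rrr[region_of[prim]] *
    mean_panel[region_of[prim]] / as.integer(n_sen_pr[prim])
  n_events <- rpois(length(elig), lambda)

  active <- which(n_events > 0)
  if (length(active) == 0) return(empty)
  n_over <- rbinom(length(active), n_events[active],
                   config$over_event_fraction)
  n_under <- n_events[active] - n_over

  rules <- config$rule_table
  ind_rules <- which(lengths(rules$indicated) > 0)
  con_rules <- which(lengths(rules$contraindicated) > 0)
  if (length(con_rules) == 0)
    stop("rule table has no contraindicated classes: cannot emit over events")

  # first in-year non-emergency encounter at the primary practice, for
  # attaching maintenance prescriptions (guaranteed to exist for eligible
  # seniors)
  enc_ok <- nf$encounters[nf$encounters$patient_id %in% elig, , drop = FALSE]
  enc_ok <- enc_ok[order(enc_ok$encounter_id), , drop = FALSE]
  first_enc <- enc_ok[!duplicated(enc_ok$patient_id), , drop = FALSE]
  first_enc_id <- setNames(first_enc$encounter_id, first_enc$patient_id)

  added_dx <- vector("list", length(active))
  names(added_dx) <- elig[active]
  maint_pat <- character(); maint_class <- character()
  ev_pat <- character(); ev_class <- character(); ev_n <- integer()

  for (i in seq_along(active)) {
    pid <- elig[active[i]]
    no <- n_over[i]; nu <- n_under[i]
    sel_under <- integer(); used <- character()
    if (nu > 0) {
      for (r in sample(ind_rules)) {
        if (length(sel_under) == nu) break
        if (!any(rules$indicated[[r]] %in% used)) {
          sel_under <- c(sel_under, r)
          used <- c(used, rules$indicated[[r]])
        }
      }
      no <- no + (nu - length(sel_under))  # overflow becomes over events
    }
    over_rule <- NA_integer_
    if (no > 0) {
      unmet <- vapply(sel_under, function(r) rules$indicated[[r]][1],
                      character(1))
      cand <- setdiff(con_rules, sel_under)
      ok <- vapply(cand, function(r) !any(rules$indicated[[r]] %in% unmet),
                   logical(1))
      cand <- cand[ok]
      if (length(cand) == 0) cand <- setdiff(con_rules, sel_under)
      if (length(cand) == 0) cand <- con_rules
      over_rule <- cand[sample.int(length(cand), 1)]
    }
    dx_i <- rules$rules$diagnosis[c(sel_under, over_rule)]
    added_dx[[i]] <- dx_i[!is.na(dx_i)]
    mnt <- character()
    for (r in sel_under) mnt <- c(mnt, rules$indicated[[r]][-1])
    if (!is.na(over_rule)) mnt <- c(mnt, rules$indicated[[over_rule]])
    mnt <- unique(mnt)
    if (length(mnt) > 0) {
      maint_pat <- c(maint_pat, rep(pid, length(mnt)))
      maint_class <- c(maint_class, mnt)
    }
    if (no > 0) {
      ev_pat <- c(ev_pat, pid)
      ev_class <- c(ev_class, rules$contraindicated[[over_rule]][1])
      ev_n <- c(ev_n, no)
    }
  }

  # event encounters: one per over event, at the primary practice
  ev_pat_rep <- rep(ev_pat, ev_n)
  ev_class_rep <- rep(ev_class, ev_n)
  n_base <- nrow(ds0$encounters)
  event_enc <- data.frame(
    encounter_id = sprintf("E%07d", n_base + seq_along(ev_pat_rep)),
    patient_id = ev_pat_rep,
    practice_id = unname(primary[ev_pat_rep]),
    year = config$year,
    emergency = FALSE,
    stringsAsFactors = FALSE)

  rx <- data.frame(
    patient_id = c(maint_pat, ev_pat_rep),
    practice_id = unname(primary[c(maint_pat, ev_pat_rep)]),
    encounter_id = c(unname(first_enc_id[maint_pat]), event_enc$encounter_id),
    year = config$year,
    drug_class = c(maint_class, ev_class_rep),
    stringsAsFactors = FALSE)
  rx <- rx[order(rx$patient_id, rx$encounter_id, rx$drug_class), , drop = FALSE]
  rx <- cbind(prescription_id = sprintf("RX%07d", seq_len(nrow(rx))), rx,
              stringsAsFactors = FALSE)

  list(added_dx = added_dx, event_encounters = event_enc, prescriptions = rx)
}
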
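# pimnet

Patient-sharing practice networks and prescribing appropriateness.

## The problem

Seniors (65+) accumulate prescriptions from several practices, and a
substantial share of those prescriptions are potentially inappropriate
medications (PIMs) — contraindicated drugs given, or indicated drugs
withheld. One line of health-services research asks whether a practice's
*position in its professional network* is associated with its prescribing
quality: practices that share many patients exchange information (referrals,
reports, informal advice), and that information environment may help — or,
through insulation and local norms, hurt — adherence to prescribing
guidance.

`pimnet` implements this analysis end to end for anyone working with
ambulatory claims data (epidemiologists, health-services researchers,
regional care managers):

1. **Cohorts** — eligibility filtering of raw claims (non-coordinating
   specialties out, emergency claims out, one calendar year, a minimum
   practice panel of 30 unique patients), then the analytic sample of
   practices caring for at least one senior, with an auditable sample-flow
   report.
2. **Networks** — per region, the bipartite patient × practice graph is
   projected to an undirected practice graph; practices are tied when they
   share at least *t* patients (*t* = 8 by default, 25 in a sensitivity
   analysis). Edge weight w(i,j) = |patients seen by both i and j|.
3. **Measures** — per practice: degree, unnormalized Brandes betweenness,
   and eigenvector centrality (max-normalized, largest component); per
   network: density 2m/(n(n−1)), mean shortest-path length over connected
   pairs, and a G(n,m) random-graph baseline (1000 replicates) for the mean
   distance.
4. **Outcome** — a rule-table-driven PIM engine scores each senior's year:
   +1 per encounter at which a contraindicated class (given the patient's
   diagnoses) is prescribed, +1 per (diagnosis, indicated class) pair never
   filled that year. Practice outcome y = Σ patient scores over the
   practice's senior panel (a shared patient counts fully at every
   practice). Covariates: age-adjusted Charlson index (original weights
   1/2/3/6 + 1 point per decade from 50), % seniors, primary-care dummy,
   region dummy.
5. **Model** — within-region quartiles of each centrality measure (Q1 = most
   connected, reference) enter a pooled NB2 negative binomial regression

   log E[y] = α + β₁·quartile + β₂·%seniors + β₃·meanCharlson + β₄·PCP + β₅·region

   with ML dispersion and heteroskedasticity-robust (HC0) standard errors,
   reported as incidence rate ratios exp(β) with 95% Wald intervals; plus
   Spearman screens, VIF diagnostics, and two sensitivity analyses
   (network remapped from under-65 patients only; tie threshold raised
   to 25).
6. **Synthetic claims** — real claims of this kind are proprietary, so
   `generate_claims()` produces datasets with the structure the analysis
   assumes — two regions, skewed panels, community-structured sharing,
   overdispersed counts — and a *planted*, configurable quartile rate-ratio
   gradient, so the whole pipeline is testable and the regression can be
   validated by parameter recovery.

## Worked example

```r
library(pimnet)
cfg <- sim_config(n_patients_per_region = c(6000, 5000),
                  n_practices_per_region = c(150, 100),
                  n_communities = c(8, 5), seed = 42)
res <- run_pipeline(cfg, baseline_reps = 200)

sample_flow(res$analytic)
#>                                          step n_practices n_patients n_claims
#> 1                          full claims record         250      11000    68595
#> 2        exclude non-coordinating specialties         233      10849    64530
#> 3                    exclude emergency claims         233      10795    61395
#> 4              restrict to calendar year 2016         233      10753    59055
#> 5 exclude practices with < 30 unique patients         233      10753    59055
#> 6   exclude practices without senior patients         232      10750    58756

res$summaries[, c("region", "n_nodes", "n_edges", "density",
                  "mean_distance", "random_baseline_mean_distance")]
#>   region n_nodes n_edges density mean_distance random_baseline_mean_distance
#> 1  urban     140    1037   0.107          3.07                          2.08
#> 2  rural      93     902   0.211          2.12                          1.80

subset(res$irr$degree, grepl("quartile", term))[, c("term", "irr", "lo", "hi")]
#>        term   irr    lo    hi
#>  quartileQ2 0.246 0.173 0.349
#>  quartileQ3 0.064 0.044 0.093
#>  quartileQ4 0.038 0.025 0.057
```

Reading the output: both regions' networks are *less* integrated than random
graphs of the same size (mean distance 3.07 and 2.12 versus baselines 2.08
and 1.80). The adjusted incidence rate ratios say that practices in the
least-connected degree quartile (Q4) accumulate only ~0.04 times the summed
PIM score of the most-connected quartile (Q1) — here recovering the
generator's planted gradient (1, 0.21, 0.073, 0.040), i.e. well-connected
practices are associated with *worse* prescribing. The positive Spearman
correlation between degree and the summed score (ρ = 0.74) tells the same
story marginally.

A thin CLI mirrors the pipeline stages (`simulate`, `filter`, `network`,
`metrics`, `score`, `fit`, `sensitivity`, `report`, `run-all`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pimnet.R", package = "pimnet"))')" \
  run-all --config config.yaml --out artifacts/
```

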
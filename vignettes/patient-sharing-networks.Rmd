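---
title: "Patient-sharing networks and prescribing appropriateness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-sharing networks and prescribing appropriateness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

`pimnet` studies the association between a physician practice's structural
position in a regional patient-sharing network and the appropriateness of
its prescribing for senior (65+) patients. Two practices are taken to have
an information-sharing relationship when they treat a threshold number of
common patients within a calendar year; the shared patient is the conduit
along which clinical habits, referrals and advice travel. The outcome is a
practice-level count of potentially inappropriate medication (PIM) events
accumulated by the practice's senior panel over the year; the exposure is
the practice's within-region centrality quartile.

The estimating model is a pooled NB2 negative binomial regression with log
link,

$$\log E[y] = \alpha + \beta_1\,\text{centrality quartile}
  + \beta_2\,\text{pct seniors} + \beta_3\,\text{mean Charlson}
  + \beta_4\,\text{PCP} + \beta_5\,\text{region},$$

fitted separately for degree, betweenness and eigenvector centrality, each
as a categorical quartile contrast with Q1 (the most connected quarter) as
reference. Coefficients are reported as incidence rate ratios
$\mathrm{IRR}=e^{\beta}$ with 95% Wald intervals from
heteroskedasticity-robust standard errors. Overdispersion is the reason for
the NB2 choice: practice totals are sums over panels that share latent
practice-level prescribing habits, so their variance grows quadratically
with the mean.

### Assumptions worth stating

* Shared patients proxy communication; the tie threshold trades sensitivity
  (low thresholds admit coincidental sharing) against specificity.
* The cross-sectional design identifies association, not direction: highly
  connected practices could attract complex patients rather than be
  influenced by peers. The under-65 remap (below) probes exactly this
  concern on the network side.
* Attribution is deliberately generous: a senior shared by $k$ practices
  contributes their full annual score to each of the $k$ practices, because
  every treating practice is considered responsible for the medication
  profile.

## Pipeline conventions

**Cohort filters** run sequentially — excluded specialties (anesthesiology,
radiology, pathology, radiotherapy, nuclear medicine), emergency claims,
calendar year, then the minimum panel of 30 unique patients — with each
step logged in a sample-flow report. The panel minimum is evaluated after
the preceding exclusions; both the order and the comparison
(`>= 30` by default) are configurable because printed descriptions of such
rules are often ambiguous between "more than 30" and "at least 30".
A *senior* means age ≥ 65 by default (strict `>` available).

**Tie threshold** is inclusive: an edge requires `shared >= 8`
(`>= 25` in the sensitivity remap). The comparison operator is exposed for
users whose protocols read "more than".

**Centralities** are computed on the binary projection — each tied practice
weighted equally — because degree is defined as a count of connected
practices, and the quartile contrasts should not mix tie existence with tie
volume:

* degree: number of distinct neighbours;
* betweenness: standard unnormalized pair-fraction (Brandes) betweenness
  over unweighted shortest paths; pairs without a connecting path
  contribute nothing;
* eigenvector: leading eigenvector of the adjacency matrix, computed by
  power iteration on $A + I$ (the shift prevents oscillation on bipartite
  components) from a deterministic uniform start, converged to
  $10^{-10}$ in the max norm (error, with the iteration count, otherwise),
  rescaled to unit maximum. Eigenvector centrality is ill-defined on a
  disconnected graph, so it is computed on the largest connected component
  (ties broken towards the component containing the first practice id) and
  set to 0 elsewhere, with component sizes reported.

**Network summaries**: density $2m/(n(n-1))$; mean distance averages
shortest-path lengths over *connected* pairs (the common convention;
a largest-component variant is available). The random baseline fixes both
node and edge counts — uniform G(n, m), 1000 replicates by default — so the
comparison isolates wiring from size; a G(n, p) variant is exposed.

**Quartiles** are cut at the empirical 25/50/75 percentiles within each
region; values tied with a cut point go to the better-connected side,
deterministically. With heavy ties (many zeros) quartiles can collapse;
the model then uses the levels that exist, and a scenario whose quartiles
degenerate to a single level is reported as an explicit gap rather than
fitted.

**The PIM engine** is rule-table-driven: each rule links a diagnosis code
to indicated and contraindicated drug classes. Over-prescribing counts one
point per distinct (encounter, contraindicated class) pair — repeat
prescribing across encounters keeps accruing, reflecting unresolved
inappropriate therapy; a per-year mode counts each class once.
Under-prescribing counts one point per (diagnosis, indicated class) pair
with no prescription of that class anywhere in the year. Codes unknown to
the table are ignored (with a warning), so partial rule sets degrade
gracefully. The shipped 15-rule table demonstrates the schema; the licensed
consensus drug classification it stands in for is not redistributable, so
the engine's semantics — not the rule content — are the tested artifact.

**Charlson index**: original 17-condition weights (1/2/3/6) with
hierarchies (metastatic disease supersedes malignancy, moderate/severe
liver disease supersedes mild, complicated diabetes supersedes
uncomplicated) plus one age point per decade from 50–59 to ≥ 80. The
practice covariate averages the index over the practice's *senior*
patients, matching the population whose outcome is scored. Reported
medians in comparable studies (e.g. 4.25) cannot disambiguate every
variant of the index; the weight set is therefore a configurable fixture.

**Model fitting** uses maximum likelihood for the dispersion
(`MASS::glm.nb`); when the data carry no overdispersion the ML estimate
diverges to the Poisson boundary, which is caught and refitted with a
pinned very large size parameter (dispersion ≈ 0). Robust covariance is
HC0 by default (HC1 optional); model-based covariance is also retained so
the two can be compared. Rows with missing model variables are dropped
per model and the n used is reported. Total panel size is not a control —
it is nearly collinear with the percentage of seniors — but can be added
via a custom formula.

**Sensitivity analyses**: (i) the network is remapped from encounters of
under-65 patients only, at the main threshold, and the *original* analytic
records keep their outcome and covariates while the centrality columns and
quartiles are re-derived (practices absent from the under-65 claim set get
missing centralities and drop from the fits; isolated-but-present practices
keep centrality 0); (ii) the projection threshold is raised to 25, and
practices left without any tie are dropped from the fits by default
(configurable), since a tie-less practice carries no positional information
at that specificity. Quartiles are re-derived on the remapped centralities
in both scenarios.

## The synthetic claims generator

Claims data of this kind are proprietary, so the package ships a generator
whose output has the statistical structure the analysis assumes, plus a
*planted*, sign-configurable centrality-to-PIM gradient that downstream
stages must recover.

### What it emulates

* Two regions with configurable practice and patient counts (defaults:
  560/350 practices, 28,500/21,000 patients, senior shares 19%/14%).
* Skewed practice panels via log-normal attractiveness weights
  (`panel_size_skew` is the log-sd).
* Community-structured sharing: practices belong to communities arranged on
  a ring (contiguous localities); a younger patient's additional visits stay
  in the home community with probability `odds/(odds+1)` (default 0.8),
  otherwise mostly spill into a ring-adjacent community and occasionally
  anywhere. Typical shared-patient counts between same-community practices
  scale as (younger patients per practice) × (within-community visits)² /
  (practices per community); the default community sizes keep that quantity
  near the tie threshold, which yields a giant component with a broad
  degree/betweenness/eigenvector spread rather than isolated cliques.
* Ages: seniors are cutoff + Gamma years (region-specific shape/scale
  targeting medians in the low/mid 70s with IQRs near 11–12); younger
  patients uniform over 18–64.
* Comorbidity: independent Bernoulli draws per Charlson condition, with
  senior prevalences chosen so a typical senior's age-adjusted index is
  about 4; younger patients use a scaled-down prevalence.
* Overdispersed outcomes: each practice draws a Gamma latent quality with
  mean 1 and variance `dispersion`, shared by its senior panel, making
  practice totals marginally NB2 with the configured dispersion.

### The planting mechanism

After baseline encounters are generated, the generator runs the package's
own default filter → network → degree → within-region quartile chain on
them, so the planted quartiles and the quartiles the analysis later
estimates coincide by construction. Each analytic practice receives the
rate-ratio multiplier of its realized degree quartile
(`planted_quartile_irr`, default (1, 0.21, 0.073, 0.040) — a steep negative
gradient of the magnitude reported in regional claims analyses of this
design; tests use (1, 0.5, 0.25, 0.1)). A senior's annual PIM event count
is Poisson with mean

$$\lambda_i = \text{base rate} \times \text{quartile multiplier}
  \times \text{practice quality} \times \text{region ratio}
  \times \bar n_{\text{sen}} / n_{\text{sen}}(A),$$

where the last factor scales by the practice's senior panel so that the
*practice-level expectation* — the scale the regression models, which
contains no size offset — depends only on quartile, latent quality and
region. Planted events are then materialized as real claims rows: an over
event adds a dedicated encounter carrying a contraindicated class for one
of the patient's rule diagnoses; an under event adds a rule diagnosis whose
first indicated class is never filled, with the rule's remaining indicated
classes covered by maintenance prescriptions. Because the demonstration
rule table uses diagnosis codes disjoint from the Charlson conditions and
never reuses a drug class as indicated in one rule and contraindicated in
another, the scoring engine recovers each patient's planted count exactly.

### Deliberate departures from real claims

These choices make the planted gradient identifiable; they are also the
boundaries of what passing tests demonstrate.

* **Seniors attend a single primary practice.** The outcome attributes a
  shared senior's full score to every treating practice, so senior sharing
  would blend practice quality across quartiles and the planted IRR would
  no longer be the estimand. Consequently the under-65 network remap
  reproduces the main network exactly on generated data (the invariance
  case); toy fixtures exercise the non-trivial remap path. Real seniors see
  multiple practices, and real under-65 remaps genuinely change the
  network.
* **Senior panel attractiveness is independent of the younger-panel
  attractiveness** that drives connectivity, so degree quartile is not
  mechanically confounded with senior volume. In real claims the two are
  correlated, and part of an observed centrality gradient can be a panel
  size effect — a caveat for interpretation, not a property the generator
  tries to reproduce.
* **Covariates carry no planted effects** (apart from a region rate ratio,
  default 1.25): the Charlson, %-senior and PCP coefficients are null in
  the generator. Recovery tests therefore validate the estimation
  machinery, not any clinical claim about those controls.
* Network-level statistics are structurally similar to, but not calibrated
  against, any particular published network: with the default scale the
  generated densities sit a factor ~2 below, and mean distances above,
  those of the denser empirical networks this design is applied to, and
  eigenvector centrality is only weakly coupled to degree on the ring
  topology. The abstract code systems (condition names, drug classes)
  stand in for ICD-10/ATC; claims carry year granularity only.

## Problem sizes and tolerances

The test suite validates the graph machinery against hand-written
brute-force oracles (BFS distances, full shortest-path enumeration, dense
eigendecomposition) on hundreds of random graphs of up to 7 nodes at
tolerance 1e−8, and the projection against pairwise set intersection on
random toy datasets. Parameter recovery runs 20 replicates of a study with
two regions × 400 practices × 18,000 patients (14% seniors; ~5,000 scored
seniors and ~650–750 analytic practices per replicate), planted quartile
IRRs (1, 0.5, 0.25, 0.1) and dispersion 0.5 — chosen as a mid-sized
realization of the design the defaults emulate — and asks the fitted
Q4-vs-Q1 IRR to fall below 1 in every replicate, its 95% CI to cover the
planted value in at least 18 of 20, the full model's AIC to beat the
controls-only model's, and both sensitivity scenarios to preserve the
direction of the association. `scripts/acceptance.R` reruns the
default-scale study once and writes every headline quantity it computes as
JSON.

## Known limitations

* The degenerate-quartile behaviour under heavy ties (all-identical
  centralities collapse to one quartile with a warning) is a faithful
  consequence of the deterministic tie rule, not a statistical remedy;
  sparse networks may need a lower threshold or a coarser contrast.
* The per-encounter over-prescribing count cannot distinguish "repeated
  because unresolved" from "repeated within a single episode" at year
  granularity; episode-of-care linkage is out of scope.
* The demonstration rule table has no clinical authority.
* `vif_table` reports `Inf` under exact collinearity and `NA` for
  zero-variance predictors rather than failing, leaving the modelling
  decision to the analyst.
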
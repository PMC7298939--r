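---
title: "Patient-sharing networks for severe mental illness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-sharing networks for severe mental illness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carenets` implements a complete claims-to-inference pipeline for studying
how hospitals providing psychiatric care share patients with community-based
providers, and whether the shape of that sharing relates to the quality of
care. This vignette explains the models and the methodological choices; the
README shows a worked run.

## The scientific setting

Adults hospitalized full time for a severe mental health disorder
(schizophrenia-spectrum, bipolar/severe personality, or severe depressive
episodes) depend on follow-up from many actors: the hospital's own
ambulatory teams, community psychiatrists, general practitioners and nurses.
In systems with hospital-centered psychiatric sectorization, the hospital of
the index admission anchors this follow-up. Claims data record every billed
contact, so co-occurrence of patients across providers — *patient sharing* —
can proxy working relationships where no survey data exist.

The pipeline has five analysis stages, each a module with a stable surface:

1. **Cohort** (`build_cohort`): select index hospitalizations and derive
   patient covariates.
2. **Networks** (`build_networks`): one weighted patient-sharing network per
   index hospital.
3. **Profiles** (`network_profiles`): structural, compositional and
   contextual characteristics per network.
4. **Typology** (`prune_correlated`, `run_pca`, `cluster_networks`,
   `characterize_clusters`): a data-driven classification of the networks.
5. **Quality and models** (`quality_table`, `fit_quality_models`): four
   utilization-based indicators on the schizophrenia-spectrum subcohort and
   cluster-correlated log-binomial models relating them to network
   characteristics.

A sixth, first-class module — the synthetic claims generator
(`generate_bundle`) — exists because the claims data this design targets are
access-restricted. Every stage is validated against data with planted,
recoverable structure.

## Cohort definition

An index stay is the *earliest* full-time psychiatric inpatient stay in the
two index years (default 2012–2013), at a sectorized non-military hospital,
with a qualifying ICD-10 main diagnosis, for a patient aged 18–65 at
admission. Codes are compared uppercased with dots stripped; F2x is matched
by prefix (psychotic group), F30x/F31x by prefix plus F603 exactly
(bipolar/personality group), and F322/F323/F332/F333 exactly (severe
depressive group). When several stays qualify, the earliest maximizes the
follow-up window; this is a package decision, as is the operationalization
of "adult" as 18+ and of "over 65 excluded" as retaining age 65.

The *precedence* covariate is true when any hospital psychiatric contact
(full- or part-time) occurs in the 730 days before the index admission. All
windows are day-exact; no calendar-month arithmetic is used anywhere, which
keeps every boundary decidable and testable.

## Network construction

Within each patient's personal window — day 1 to day 365 after index
discharge — eligible events are visits to in-region community
psychiatrists, GPs and nurses, and admissions to other hospitals for
psychiatric care, suicide attempts or emergencies. Contacts with the index
hospital itself create no links (a hospital cannot share a patient with
itself); they instead feed the in-hospital ambulatory share described
below.

Link weights count *distinct shared patients*, never visits. The retention
rule keeps a provider in a network when its count of patients shared with
the index hospital is **strictly greater than the third quartile** of such
counts, computed per provider type and pooled across all index hospitals
(one region-wide threshold per type; identical thresholds across networks
are what a pooled computation produces, and a per-network variant is
exposed). The quartile uses linear interpolation between order statistics
(the `type = 7` convention) — on the worked set {1,2,2,3,4,6,8,20} this
gives 6.5 and retains {8, 20}. The convention is configurable because
integer thresholds are consistent with several quantile definitions.

Two deliberate asymmetries: provider-to-provider ("secondary") links are
*not* thresholded — retention is a property of the index-hospital link only,
and a secondary link survives exactly when both endpoints are retained; and
a sensitivity mode rebuilds everything with all thresholds at zero
(`zero_thresholds`), so the thresholded network is always a subgraph of the
full ≥1-shared-patient graph.

## Network characterization

* **Density**: percent of possible undirected links present, on the
  unweighted skeleton.
* **Transitivity**: percent of connected triples closed into triangles
  (global clustering coefficient), unweighted.
* **Median weighted degree**: the median over all nodes (index hospital
  included, configurable) of the sum of incident link weights.
* **Composition**: counts and percentages per provider type (among non-index
  providers), community professionals per 100,000 adult catchment
  inhabitants, specialist and physician shares among community
  professionals, and the private share among hospital providers (index
  hospital in the denominator).
* **Loyalty index**: share of the hospital's index patients living in its
  catchment area, banded `>80%`, `[60–80%]` (closed at both ends, so 60 and
  80 fall in the middle band), `<60%`.
* **In-hospital ambulatory share**: index-hospital ambulatory psychiatric
  contacts as a percentage of all specialized ambulatory contacts. Only the
  numerator is unambiguous in the field's usage; the denominator here is
  declared as index-hospital ambulatory plus community-psychiatrist visits,
  and is configurable.
* **Average contacts per patient**: all in-window contacts including those
  within the index hospital and follow-up admissions, averaged over every
  cohort patient of the network — patients with zero contacts stay in the
  denominator. Each claim line counts; same-day repeat contacts are separate
  events.

Density and transitivity are deliberately computed on the unweighted
skeleton (both are combinatorial definitions); weights enter only through
degree.

## Typology

The typology chain is: prune highly correlated quantitative variables, run
a standardized PCA with qualitative variables projected as illustrative
(never influencing the axes), cluster on retained components, verify
robustness across methods, and characterize the clusters.

**Candidates and pruning.** Nine quantitative variables are candidates for
the active set: density, median weighted degree, psychiatrists and GPs per
100,000, the hospital share, the physician share among community
professionals, the private-hospital share, the in-hospital ambulatory
share, and average contacts per patient. Size and cohesion measures that
duplicate this information (transitivity, provider and link counts, beds)
and the redundant type shares enter the cluster *description* instead.
Pruning is greedy at |r| > 0.7: variables are scanned in a priority order
that puts the most reliably measured quantities first (the contact-pattern
shares, then density as the representative of the size/cohesion group), and
a candidate is dropped when it exceeds the threshold against an
already-kept variable. Constant columns are dropped with a warning.

**Components.** Clustering uses all components with eigenvalue at least 1
(Kaiser rule) by default; `n_components` overrides it. With nine or fewer
standardized variables this typically retains two to four components.

**Cluster count and robustness.** Ward's method (on Euclidean distances
over the retained components) provides candidate partitions; average-link
and k-means (fixed, logged seed; 25 starts) are computed at each `k`. Method
agreement is summarized by the mean pairwise adjusted Rand index. Agreement
alone, however, cannot select `k`: on cleanly nested data all three methods
also agree perfectly at every coarser cut, so an agreement-maximizing
criterion collapses to the smallest `k`, and on noisy data it gravitates to
outlier-isolating large `k`. Selection is therefore two-stage: a partition
is *admissible* when it is method-robust (mean pairwise ARI at least 0.8,
`ari_floor`) and every cluster has at least 3 members (`min_cluster_size`;
a one- or two-network "type" cannot be characterized — its within-type
spread and v-statistics are meaningless); among admissible `k` the best
mean silhouette width of the Ward partition wins, with ties toward the
smallest `k`. If no partition clears the robustness floor, the combined
agreement-plus-silhouette score ranks candidates instead. This mirrors the
common practice of pairing a stability check with a cluster-quality index
battery.

**Characterization.** For each quantitative variable and cluster the
v-statistic compares the cluster mean to the overall mean with a
finite-population correction,
`v = (mean_k − mean) / sqrt((s² / n_k) · (N − n_k) / (N − 1))`,
where `s²` is the population variance (denominator `N`) — the convention of
PCA-based cluster description. Cells are flagged at the two-sided 5% normal
threshold. Each cluster's *parangon* is the member network closest to the
cluster centroid in component space; it is exported for visual inspection
(layout is left to external tools — the package writes GraphML and weighted
edge lists, plus a Newick-style dendrogram).

## Quality indicators

All four indicators are computed on patients whose index diagnosis group is
schizophrenia-spectrum (`psychotic`), and all windows anchor at the index
discharge (the wording "within … of the index hospitalization" is anchored
at discharge for comparability across indicators):

1. **15-day readmission**: any full-time psychiatric admission, any
   hospital (the index hospital counts), days 1–15 inclusive.
2. **Referring-physician contact**: a contact with the patient's designated
   referring physician within 60 days. Patients with no designation score
   `FALSE` — the indicator measures the realized hospital-to-community
   transition, not its possibility.
3. **Somatic prevention**: all three configured prevention-procedure tags
   within 730 days; the tags are configuration-defined
   (defaults `P1`,`P2`,`P3`) because their exact clinical identity is
   site-specific.
4. **Antipsychotic continuity**: at least nine antipsychotic deliveries
   within 365 days; same-day deliveries count separately by default.

Indicators are pure functions of events inside their windows: shifting all
dates by a common offset cannot change them, which the suite checks as a
property.

## Relative-rate models

Each indicator is modelled at the patient level with a log-link binomial
marginal model, so coefficients exponentiate to relative rates rather than
odds ratios. Because patients treated within the same group of networks
share unmeasured context, generalized estimating equations with an
exchangeable working correlation and robust (sandwich) standard errors are
used; the clustering unit is the typology cluster by default (`cluster_on =
"network"` switches to the 19 networks — the coarser unit is the default
because that is where shared context operates). Multi-level random-effect
models are deliberately not provided: with a handful of clusters their
variance components are unreliable and frequently collapse to zero.

The GEE is fitted by Fisher scoring with the exchangeable inverse applied
blockwise in closed form; the working correlation is re-estimated from
standardized residuals at each iteration (moment estimator). Log-binomial
models can fail when fitted probabilities approach 1; the fitter
step-halves against boundary overshoot and, if the binomial-variance fit
still fails or pins at the boundary, falls back to the Poisson variance
function with the same log link — the standard robust-Poisson estimator of
relative rates — and flags `convergence_status = "poisson-fallback"`.
A `small_sample` option inflates the sandwich by `K/(K−1)·(N−1)/(N−p)`
since plain sandwich variances are anti-conservative with few clusters;
simulation tests in the suite use 20+ clusters where the plain estimator is
adequate.

Before fitting, network-level covariates pass the same |r| > 0.7
collinearity screen as the typology (patient adjustors — age, sex,
low-income coverage, precedence, somatic comorbidity — are never dropped),
and an aliasing guard removes network covariates beyond the rank that
`n_networks` distinct values can support.

The no-threshold sensitivity analysis rebuilds the networks with all
retention thresholds at zero, recomputes profiles and indicators, refits
the four models on the same typology clusters, and reports paired relative
rates with the maximum absolute difference per covariate. Run when
thresholds are already zero it reproduces the main fit exactly.

## The synthetic claims generator

`generate_bundle()` emulates a two-index-year national claims extract with
one follow-up year: provider, patient, stay, contact, delivery and
procedure tables with referential integrity, ISO dates and realistic
marginals (age 41.7 ± 12.2 truncated to 18–65, 57% male, 66/22/11%
diagnostic mix, 56% precedence, 21% low-income coverage, 15% somatic
comorbidity).

Three planted archetypes drive the network structure, patterned on the
three types that hospital-centered mental-health systems exhibit:

* **A1 — hospital-centric**: high in-hospital ambulatory share (40%), high
  loyalty (0.92), concentrated referral pathways (high density and
  transitivity), few private hospitals, rural/limited-resource areas.
* **A2 — scattered urban**: the most patients and providers, highest
  contact intensity (~82 contacts/patient), low in-hospital share (15%),
  strong private supply, urban typologies.
* **A3 — medically oriented**: sharing directed at physicians (~84% of
  community professionals), few nurses, fewest distinct providers but loyal
  repeat visits, lowest contact volume (~48).

Mechanically, each hospital has local provider pools per type; each patient
contacts a Poisson number of distinct providers per type and revisits them.
Two mechanisms shape the one-mode projection independently of contact
volume: **per-provider concentration** (expected shared patients per pooled
provider, ≈10–12 by type and archetype), which against the pooled
third-quartile rule determines how much of each pool is retained, and
**referral-pathway sharing** (a patient follows an earlier patient's
provider set with archetype-specific probability), which concentrates
co-occurrence and drives density and transitivity. Per-hospital lognormal
jitters on patient volume, pool scale, visit intensity, the ambulatory
share and the pathway share create within-archetype heterogeneity; their
scales are kept moderate so that the planted taxonomy remains identifiable
from 19 networks — real claims data show wider within-type spread, so
passing recovery tests here demonstrates correctness of the machinery, not
that any real system must cluster this cleanly. Compositional shares (more
psychiatrist and hospital involvement than the sparsest real networks) are
likewise chosen to keep count-based percentages stable at the default
scale of 200 baseline patients per hospital (the full regional cohort would
be ~2.5× larger; structure, not scale, is what the tests exercise).

Outcomes are generated by *exact realization*: each patient's four
indicator outcomes are drawn from a log-linear model — baseline rates
(0.30/0.33/0.50/0.54), optional planted covariate effects, and a shared
archetype-level latent intercept on the log scale whose variance
`log(1 + ρ(1−p)/p)` induces approximately the configured exchangeable
correlation ρ — and the events the indicators read are then constructed
consistently with the drawn outcome (an early readmission only when the
readmission outcome is true; referring-physician contacts placed inside or
displaced outside the 60-day window; ≤2 procedure tags for negatives;
delivery counts ≥9 or ≤8). This preserves planted probabilities exactly,
which parameter-recovery tests require; the cost is that, for example,
early readmissions carry no information beyond the outcome model, which is
acceptable for a validation generator. Every patient receives a referring
physician by default for the same reason (an undesignated patient scores
`FALSE` deterministically, which would dilute a planted rate);
`referring_designation_rate` lowers the coverage when realism matters more
than exactness. `simulate_outcome_data()` exposes the outcome model alone
for large relative-rate recovery and coverage experiments.

What the generator does **not** emulate: French billing nomenclature,
seasonal/touristic utilization, military-hospital exclusions beyond a flag,
inter-regional patient flows, provider turnover, and correlation between
patient covariates and network membership. Passing tests on this generator
therefore validates the pipeline's algebra and inference machinery — not
any claim about real claims data.

## Numerical choices and degenerate inputs

* Quartiles: `stats::quantile` type 7; configurable at the call site.
* Quality and window boundaries: day 15/60/365/730 inclusive; day-exact.
* Networks with a single node report density and transitivity as missing;
  undefined shares (no community professional, no specialized ambulatory
  contact) are missing, not zero, and PCA mean-imputes rare missing cells
  rather than dropping a network.
* GEE: convergence tolerance 1e-8 on coefficients, 100 iterations,
  correlation estimate clipped to [0, 0.95]; rank-deficient designs are
  refused rather than silently reduced (the aliasing guard acts earlier, at
  covariate selection, and reports what it removed).
* k-means uses its own fixed seed and restores the caller's RNG state, so
  end-to-end runs are bit-reproducible for a given scenario seed.
* Bit-reproducibility: `generate_bundle` touches the RNG only through the
  scenario seed; rerunning a pipeline with the same configuration yields
  byte-identical output files (checksummed in the run manifest).

## Known limitations

* The typology machinery is tuned for a small number of units (tens of
  networks); silhouette-based selection is not meaningful for hundreds.
* The sandwich variance is anti-conservative below ~20 clusters even with
  the small-sample inflation; with the 3 clusters a real typology may
  yield, confidence intervals should be read qualitatively.
* The in-hospital ambulatory share depends on a declared denominator;
  alternative conventions change its level (not its ordering) across
  networks.
* Secondary (provider-provider) links are never thresholded; if the
  field's practice diverges here, `build_network` is the single place to
  change it.
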
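---
title: "Methods: disproportionality signals and symptom networks for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and symptom networks for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrnet)
```

## The problem

Spontaneous pharmacovigilance databases collect individual case safety
reports (ICSRs): each report lists one or more drugs (with a role:
suspect, interacting or concomitant), one or more adverse events coded as
MedDRA-style preferred terms (PTs), and patient-level covariates (age,
sex, reporter type, country, dates). Signal detection asks which
drug-event pairs are reported *disproportionately* often relative to the
rest of the database. `sdrnet` implements this workflow for an index
condition defined by a PT set — the worked configuration throughout the
package is drug-induced Raynaud's phenomenon (RP), an episodic digital
vasospasm — together with the machinery needed to probe how robust each
signal is and what co-reported symptom structure surrounds it.

Real pharmacovigilance databases are access-restricted, so the package
ships a synthetic ICSR generator whose databases have *known* ground
truth. Every statistical claim the package makes about itself is backed
by a recovery, calibration or construction argument on generated data.

## Case selection and exclusion

Cases are reports carrying at least one event in the case-definition PT
set (`select_cases()`). Two definitions are supported: narrow (the single
index PT) and broad (index PT plus "Peripheral ischaemia" and
"Chilblains", absorbing coding variability). Reports carrying any drug
flagged as a treatment for the condition are excluded
(`apply_exclusion()`) — such reports likely reflect pre-existing disease
rather than drug-induced onset. Two choices here were genuinely open:

* **Exclusion matches any drug role.** A treatment drug listed as
  concomitant still indicates treated disease, so the filter does not
  restrict to suspect entries. This is configurable via
  `exclusion_drugs`.
* **Excluded cases leave the analysis universe entirely** (they are
  neither cases nor comparators), mirroring the usual flow-chart reading
  of "excluded from the analysis".

The treatment-drug list is configuration, not code: a default set of ATC
prefixes covering calcium channel blockers (C08), PDE5 inhibitors
(G04BE), endothelin receptor antagonists (C02KX), angiotensin receptor
blockers and ACE inhibitors (C09A-D), alpha blockers (C02CA) and
intravenous prostanoids (B01AC09/11/21) is provided by
`default_exclusion_atc()` and applied with `flag_rp_treatment()`.

## Dates and time to onset

Partial dates are completed deterministically (`impute_date()`): a
missing day becomes the 15th; a date known only to the year becomes July
2 (mid-year). Time to onset (`compute_tto()`) is onset minus drug start
in calendar days — month arithmetic is never approximated by 30-day
months. When either date is missing the interval is treated as missing;
when completion produces a *negative* interval it is also set missing,
because a negative value after imputation is an artefact of completion,
not evidence about ordering. A same-day start and onset is kept as 0
days. Drug start dates use the same completion rule as event onset dates.

## The information component

For a drug-event pair let `O` be the number of reports carrying both,
`n_drug` and `n_event` the margins, `N` the universe size, and
`E = n_drug * n_event / N` the count expected under independence. The
information component is

    IC = log2( (O + 0.5) / (E + 0.5) )

The +0.5 offsets implement the shrinkage of the Bayesian
confidence-propagation framework: rare combinations are pulled towards
IC = 0 and the statistic is defined at `O = 0`. The observed-to-expected
ratio has a Gamma(O + 0.5, E + 0.5) posterior, and the signal criterion
is the 2.5th posterior percentile on the log2 scale:

    IC_025 = log2( qgamma(0.025, shape = O + 0.5, rate = E + 0.5) )

A pair is a signal of disproportionate reporting (SDR) when `IC_025 > 0`.
The closed-form approximation `IC - 3.3 (O+0.5)^(-1/2) - 2 (O+0.5)^(-3/2)`
is also implemented (`method = "approximate"`); it is kept as an
independent cross-check, and the two agree within 0.1 bits whenever
`O >= 10`. The exact gamma form is the default because it is valid at any
count and any credibility level. No minimum-case threshold is imposed at
computation time; reporting layers may filter (e.g. `O >= 3`).

## Sensitivity analyses

`run_analysis()` implements the primary analysis and four sensitivity
variants, all sharing the counting machinery:

1. **`hcp_only`** — cases *and* comparators restricted to reports from
   health care professionals (the conservative subset reading: a
   restriction of the universe, not only of the cases).
2. **`atc3_background`** — for each drug, the comparator universe is
   restricted to reports carrying at least one drug sharing an ATC
   level-3 prefix (first four characters) with it, countering indication
   bias. For multi-class drugs the background is the union over their
   classes, and the index drug's own reports remain in it. Drugs without
   ATC codes are flagged `evaluable = FALSE` rather than dropped.
3. **`mh_stratified`** — Mantel-Haenszel pooling of expected counts over
   sex x age-band strata: `E_MH = sum_s n_drug[s] n_event[s] / N[s]`,
   with `O` summed over strata. Age bands are `<18`, `18-44`, `45-64`,
   `65-74`, `>=75`, with unknown age and unknown sex kept as their own
   strata (dropping them would silently change the universe). With a
   single stratum this reduces bit-for-bit to the crude analysis. Pooled
   expected counts (not averaged stratum-wise ICs) are used, consistent
   with the Mantel-Haenszel tradition.
4. **`broad_definition`** — the broad PT set replaces the narrow one.

Drug margins count suspect and interacting entries only; concomitant
entries are retained for case summaries. Drugs are analysed at the
substance level; fixed-dose combinations (dictionary tag `combination`)
are dropped at the ranking stage, not at computation.

`run_all()` joins the five analyses per drug and derives
`consistent_all`: significant in the primary analysis and in every
sensitivity analysis where the drug is *evaluable*. Non-evaluable
analyses (e.g. zero reports in the HCP universe) do not count against a
drug but are surfaced in `n_not_evaluable`. This makes consistency
monotone: removing an analysis from the configuration can never turn a
consistent drug inconsistent. `rank_signals()` orders by consistency then
primary `IC_025` and can annotate prior awareness from a user lookup; it
deliberately assigns no probable/possible/unlikely category — that
judgment is expert work, out of scope.

## Event-event networks per drug class

Within the reports carrying a drug of a pharmacological class,
`select_terms()` screens every other PT for disproportionate co-reporting
with the index condition (a 2x2 of term presence x case status over the
class reports, same IC machinery, `IC_025 > 0`). The comparator here is
the class's non-case reports — the 2x2 construction the package adopts
and documents, since several readings are possible. Selected terms form
the columns of a binary case-by-term matrix (`build_case_term_matrix()`),
from which two networks are estimated:

* **Ising** (`fit_ising()`): node-wise L1-penalised logistic regressions,
  penalty chosen per node by the extended BIC
  (`-2 loglik + df log n + 2 gamma df log(p-1)`, `gamma = 0.25` by
  default; `gamma = 0` is plain BIC and denser graphs), symmetrised by
  the AND rule (edge kept only when selected in both directions, weight =
  mean of the two coefficients). The OR rule is available and always
  yields a supergraph. Fits are refused below 20 rows or 3 columns —
  small class case series give unstable clusters, and the refusal is
  explicit rather than silent. Perfectly collinear columns are dropped
  (the later one) with a warning.
* **PPMI** (`compute_ppmi()`): `max(0, log2(p(a,b) / (p(a) p(b))))` with
  row-frequency probabilities and +0.5 smoothing on joint counts so that
  never-co-occurring pairs stay finite (they clip to 0 regardless); the
  matrix is symmetric and non-negative by construction and both
  properties are asserted on every call.

Communities are found by walktrap on the positive-weight subgraph
(`detect_communities()`; louvain-style alternatives can be swapped in by
the caller since the partition is just a named vector). Partitions from
the two methods are compared by the adjusted Rand index plus the Jaccard
overlap of the edge sets (`compare_partitions()`). No consensus partition
is constructed: reporting *agreement* is honest about the fact that the
two estimators can and do disagree, which is itself a finding.

## The synthetic generator

`generate_database()` emulates the structure of a WHO-style
pharmacovigilance extract. Per report: a stratum (sex, age band),
reporter type, country, year and seriousness; 1-5 drugs drawn by weighted
sampling without replacement from a power-law dictionary (the first drawn
drug is always a suspect); events drawn as independent per-term Bernoulli
indicators whose probabilities multiply three effects on a baseline
power-law marginal:

* a planted `rate_ratio` when the report carries the paired drug —
  per-term Bernoulli sampling makes these ratios exact in expectation;
* stratum multipliers for declared confounders (drug weight and event
  probability both scaled within a stratum, independence *within* every
  stratum preserved by construction);
* a cluster boost when a latent per-report indicator (on with probability
  `p_on` in reports carrying a class drug) is active — a shared latent
  Bernoulli induces positive pairwise association among the cluster's
  terms without specifying a full joint table.

Any multiplied probability above 1 aborts generation naming the term.
Reports that draw zero events receive one fallback event from the
baseline marginal, independent of their drugs, so the independence null
stays clean. Partial-date missingness is applied to start and onset
dates at configurable rates. All draws descend from a single seed;
regeneration is byte-identical, and the generator restores the caller's
RNG state. The ground-truth ledger records the planted structure and the
exact stratum/reporter counts drawn.

The three case-definition terms are pinned to mid ranks of the event
power law (ranks 10, 15, 18): an index condition like RP is a
mid-frequency event, and this also leaves headroom for planted rate
ratios up to ~20 on the index term. Treatment-flagged drugs likewise sit
at mid drug ranks, so the exclusion step removes a realistic ~8% of the
case series rather than half of it.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: duplicate reports, reporting-lag (Weber)
dynamics, country-specific reporting cultures, masking by blockbuster
drugs, terminology migration over MedDRA versions, and narrative-level
misclassification. Recovery of planted structure shows the estimators are
correct, not that real signals are causal.

## Validation scenarios and study sizes

Three canonical configurations (20,000 reports each — large enough for
stable calibration, small enough that a 20-seed study runs in minutes on
one CPU) are exported:

* `null_config()` — nothing planted. Across 20 seeds, the fraction of
  drug-event pairs with `O >= 3` flagged at `IC_025 > 0` estimates the
  interval's one-sided miscoverage (nominal 2.5%; the package's
  validation band is 1-5%).
* `planted_config()` — one pair at rate ratio 4, dimensioned so the
  expected suspect/interacting co-report count is about 25 (drug D035 x
  term PT0048 under the default marginals; the dimensioning was checked
  empirically across seeds before being frozen), plus rate-ratio-1
  control pairs that must flag only at the miscoverage rate.
* `confounded_config()` — three-fold enrichment of a drug and the index
  term in one stratum with within-stratum independence. Scenario
  geometry: the enriched drug is the most-reported one and the enriched
  stratum has 30% prevalence, because the crude observed-to-expected
  mixture ratio `(1 + w(r_d r_e - 1)) / ((1 + w(r_d - 1))(1 + w(r_e - 1)))`
  peaks near `w = 0.3` when drug enrichment saturates below its nominal
  three-fold value (weighted sampling without replacement cannot triple
  an already-common drug). No treatment-flagged drugs are present in this
  scenario: the exclusion step would otherwise couple case status to
  drug co-occurrence through competition for the 1-5 drug slots per
  report and tilt the within-stratum null — an instructive artefact, but
  not the construction this scenario exists to demonstrate.

Ising recovery uses exact sampling (`sample_ising()` enumerates all 2^p
states; p <= 20) from a planted two-cluster model (8 nodes, within-cluster
coupling 1.0, thresholds -1) at 1,000 rows across 10 seeds, scoring edge
sensitivity, false-edge rate, community ARI against planted labels, and
sign agreement of recovered couplings.

## Numerical and degenerate-input choices

* `ic_point(0, 0) = 0` exactly; `IC_025` at `O = 0` is strongly negative,
  so zero-count pairs can never signal.
* The exact bound works at any `level` in (0,1); the closed-form
  approximation is specific to 95% and errors otherwise.
* Empty strata are dropped from Mantel-Haenszel pooling with a warning;
  an empty background is fatal.
* Unknown PT codes in a case definition are fatal (a typo must not
  produce a silent empty case series); unknown keys in data rows are
  skipped with counted warnings on load.
* Target aggregation double-counts a drug's cases across its targets by
  design; the schema makes the multiplicity visible rather than choosing
  an arbitrary de-duplication.
* TSV round-trips treat the empty string as missing; empty and missing
  are equivalent for list-valued dictionary fields.

## Reproducibility

`run_pipeline()` drives simulate → signals → consistency → networks →
targets from one YAML-able configuration with a single top-level seed;
stages derive fixed sub-seeds, outputs carry no timestamps, and a
manifest with md5 hashes of inputs and outputs is written alongside the
data. Reruns under the same configuration are byte-identical — this is
asserted in the test suite and recomputed by `scripts/acceptance.R`.
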
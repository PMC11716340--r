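---
title: "Prioritizing RNAi target genes from lethality screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing RNAi target genes from lethality screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaitier)
```

## The problem

Genome-wide RNAi screens for insect pest control inject double-stranded RNA
against one gene per cohort of ten larvae and score how many die. The output
is a cascade of ever-smaller gene sets: all screened genes, the *targets*
that kill at high dose, the *most effective* targets that still kill at low
dose, and the *superior* targets whose orthologs also kill a second pest
species when the dsRNA is delivered orally. `rnaitier` implements that
cascade — scoring, selection, dose–response validation, efficacy tiering,
annotation-term enrichment, and transfer evaluation — together with a
synthetic screen generator so every stage can be tested against planted
ground truth.

## Lethality scoring

An experiment is a cohort of `n_injected` animals (ten by default) scored
for cumulative deaths on one or more days post-injection. Deaths on days 1–2
are attributed to the injection itself ("technical lethality") and excluded
from **both** numerator and denominator — those animals are treated as never
enrolled, because an animal killed by the needle carries no information
about the gene:

```{r}
series <- data.frame(gene_id = "G1", phase = "II", dose_ng_ul = 1000,
                     day = c(2, 7), n_injected = 10, n_dead = c(2, 6),
                     batch = "B001", species = "T_castaneum")
compute_lethality(series, day = 7, technical_death_day = 2)
```

Four of the eight informative animals died: 50%, not the 60% a naive
count would give. Setting `technical_death_day = 0` disables the exclusion.
Percentages are rounded half-up to one decimal for reports; raw counts are
carried alongside.

## Primary selection

A gene is a **target** when its lethality at the phase's scoring day (day 11
for the older phase-I screen, day 7 for phase II) reaches
`primary_threshold_pct` (90%). Long screens suffer episodes of elevated
background mortality in whole injection batches; genes scored in a flagged
batch are held to `contamination_cutoff_pct` (100%), since in a batch where
controls die too, nine deaths out of ten no longer separate gene effect from
husbandry. Genes at or below `background_max_lethality_pct` (50%) form the
low-mortality background; the remainder are intermediate. The partition is
exhaustive and disjoint, and raising the threshold can only shrink the
target set.

## Dose–response validation and imputation

Validation re-tests targets at 3, 30 and 300 ng/µL, scoring days 7 and 8.
The universal dose — injected for every validated gene — is 30 ng/µL. Two
resolutions are deliberate design choices:

* **Scoring day.** When a gene was scored on both day 7 and day 8 the later
  day is used (`day_rule = "latest"`); lethality is cumulative, so the later
  observation is the more complete one. `"earliest"` or a fixed day are
  available.
* **Imputation direction.** Genes never tested at 300 ng/µL get that value
  copied from the 30 ng/µL observation, flagged as imputed. The copy is a
  conservative lower bound: response at a tenfold higher dose can only be
  equal or higher under a monotone dose–response. Imputation never runs
  downward to 3 ng/µL, never overwrites an observation, and is idempotent.

Two selections follow: the *flat* list (observed 30 ng/µL lethality exactly
100%) and the *clustering subset* — genes tested at 3 ng/µL with
(post-imputation) lethality ≥ `clustering_min_lethality_pct` (75%) at
30 ng/µL. The ≥75% gate is evaluated on the universal dose, which is always
observed by screen design.

## Efficacy tiers

The subset's three lethality percentages form the feature vector. Features
are left unstandardized — all three share the 0–100 scale, and standardizing
would inflate whichever dose happens to vary least
(`standardize_features` switches this). k-means (Euclidean, 25 seeded
restarts per k; a single random start is fragile and breaks the determinism
contract) is run either at a fixed `k_fixed = 5` or at the k chosen by the
elbow method, implemented as the maximizer of the discrete second difference
$W(k-1) - 2W(k) + W(k+1)$ of the within-cluster sum of squares — the
sharpest bend of the curve. Raw cluster labels are arbitrary, so clusters
are relabeled into **tiers** ordered by descending mean lethality over all
doses (ties: mean at the lowest dose, then smallest raw label). Tier 1 kills
at every dose; the union of tiers in `most_effective_tiers` (1–3) is the
most-effective set.

## Enrichment

Over-representation of annotation terms (GO or KEGG style) in the target set
uses the upper-tail hypergeometric probability, accumulated in log space
(`lchoose` + log-sum-exp) so terms twenty orders of magnitude into the tail
do not underflow. The universe is targets plus the low-mortality background;
intermediate genes are excluded because the comparison of interest is
"lethal versus clearly non-lethal" (`enrichment_universe = "full"` restores
the whole screen). Reported terms need at least `enrichment_min_genes` (5)
study genes and raw p ≤ `enrichment_alpha` (0.01). The minimum-gene filter
applies to study-set genes in the term rather than term size
(`min_genes_on` switches this). Benjamini–Hochberg adjusted p-values are
computed over all tested terms before filtering and reported alongside;
filtering stays on raw p for fidelity to the screen's reporting convention.
Annotation tables are consumed as-is: whether GO terms were propagated up
the ontology graph is the annotation provider's decision, not this
package's.

## Cross-species transfer

A transfer assay feeds the ortholog's dsRNA to a second species and records
treated and control lethality within ten days. The success criterion
"increased lethality by more than 50% compared to controls" is ambiguous
between an absolute and a relative reading; with near-zero control mortality
the relative reading is nearly vacuous (1% vs 0.5% would pass), so the
default is the absolute one — treated minus control strictly greater than
`transfer_delta_pct` points — with `transfer_mode = "relative"` available
and the mode recorded in the output. Per-tier rates report tested counts,
successes and integer-rounded percentages; a tier never tested is absent
from the table, not 0%. Successful tier-1 transfers form the superior set,
and a confirmation round in a third species is the same operation over a
second table — no new rule.

## The synthetic screen

The generator exists to make every stage testable with known truth; real
screen tables plug in through the same TSV dialect.

Each gene carries a potency profile: a log-logistic (Hill) dose–response
with a hard onset day,

$$L(d, t) = \begin{cases}
  L_{\max}\, \dfrac{d^{h}}{d^{h} + \mathrm{LC}_{50}^{h}} & t \ge t_{0}\\
  0 & t < t_{0},
\end{cases}$$

the simplest form with the dose- and time-dependence lethality screens
show. Background mortality $b$ combines with treatment as independent
hazards, $1 - (1-b)(1-L)$, which keeps probabilities in $[b, 1]$ and makes
expected lethality monotone in dose and day. Cohort deaths are binomial:
each animal draws one uniform per (gene, dose) from a stream keyed by
(seed, gene, dose) and is dead by day $t$ iff its uniform falls below the
expected lethality at $t$. Each record is therefore marginally
Binomial(10, p) while cumulative deaths never decrease over days, and
subsetting genes never reshuffles another gene's draws.

Potency tiers 0–5 are planted by largest-remainder apportionment of the
configured proportions. The presets place tier centroids along the
admissible monotone dose–response range, approximately
(95, 100, 100), (30, 95, 100), (2, 45, 97), (0, 8, 60) and (0, 1, 10)
percent lethality at 3/30/300 ng/µL, with a small per-gene lognormal jitter
on the LC50. Adjacent centroids sit 50–65 points apart in feature space —
comfortably above the ~16-point standard deviation binomial noise reaches
at cohort size ten, so that the tiers are recoverable in principle and a
failure to recover them indicts the clustering machinery, not the
generator. Episodes of elevated background mortality can be planted on
whole batches (by default roughly every tenth batch gains 30 points of
background mortality), emulating the husbandry problems long screens
encounter; buffer-control records per batch make the episodes detectable
downstream.

What the generator does **not** emulate: within-cohort correlation, sex or
larval-stage effects, dsRNA off-target activity, morphological phenotypes,
and day-to-day scoring noise beyond the binomial. Tests passing on this
generator show the pipeline's rules and statistics are implemented
correctly under the stated noise model — not that the biology of any real
screen satisfies that model.

## The recovery experiment

The strongest test simulates 200 genes spread evenly over the five lethal
tiers (cohorts of ten, doses 3/30/300 ng/µL, scored day 7, no background
episodes — binomial noise is the only noise source), builds and imputes
profiles, clusters all of them at k = 5, and compares recovered tiers to
planted ones. The ≥75% eligibility gate is deliberately not applied here:
it is a study-specific selection rule that would discard the planted
low-potency tiers and leave five-tier agreement undefined; the experiment
tests the tiering machinery across the full potency range. The test suite
requires adjusted Rand index ≥ 0.8 against the planted tiers and ≥ 90% of
planted tier-1 genes inside the recovered most-effective set; the
acceptance script recomputes both.

## Numerical choices and degenerate inputs

* Report rounding is half-up (`round_half_up`), not banker's rounding.
* A cohort entirely lost to technical deaths raises a `degenerate_cohort`
  condition and is flagged, never scored as 0/0.
* `choose_k_elbow` returns 1 for identical rows and shrinks the scanned
  range when it exceeds the number of distinct rows; `tier_profiles`
  likewise shrinks an infeasible fixed k with a warning.
* Readers reject out-of-range values with a row locator instead of
  coercing; duplicate experiment keys and conflicting ortholog rows are
  errors.
* The run report is timestamp-free, so identical seeds and inputs produce
  byte-identical JSON.

## Problem sizes

The shipped analyses and tests run at deliberately small scale: 80–400
simulated genes, 1 000 cohorts for binomial moment checks, universes up to
12 genes for exhaustive hypergeometric enumeration, and 200 genes for the
recovery experiment — sizes at which every oracle can be computed exactly
or by brute force while exercising the same code paths a full screen would.

## Limitations

Lethality is scored at a point in time; no survival-curve or time-to-death
model is fitted, and no LC50 curve is fitted to the three-dose validation
series — the tiering operates on the raw percentages. Enrichment ignores
gene length and the GO graph. Field-rate doses in transfer tables are
metadata only; no conversion to dietary concentration is attempted.
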
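---
title: "Ontology-based phenotype clustering and survival analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based phenotype clustering and survival analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclust)
```

This vignette documents the statistical model behind `phenoclust`, the
assumptions and tunable parameters of each stage, what the synthetic-cohort
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The model

### Information content from cohort frequency

A patient is a set of ontology terms (plus covariates and a censored
survival outcome). For each term `t`, the cohort annotation frequency
`p_t` is the fraction of patients carrying `t`, and its information content
is `IC(t) = -log p_t`.

Two frequency conventions are exposed through `term_frequencies()`:

* **propagated** (default for IC and similarity): each patient's term set
  is first closed under ontology ancestors (the "true-path" rule). This
  guarantees `IC` is non-decreasing from root to leaf, which in turn gives
  the Resnik similarity its textbook bound
  `sim(s, t) <= min(IC(s), IC(t))` and makes a patient's self-similarity
  equal the mean IC of their terms.
* **explicit**: verbatim annotations, matching how descriptive prevalence
  tables are reported clinically. Whether the original analyses used
  explicit or propagated frequencies is not decidable from published
  summaries; both are provided and neither is claimed to reproduce any
  specific published heatmap.

The log base defaults to the natural log (the convention of the ontology
similarity software lineage this follows); bases 2 and 10 are options with
no effect on any downstream ranking, only on the IC scale.

Terms never observed in a cohort have no IC and cannot act as informative
common ancestors. A frequency of exactly 1 yields `IC = 0`: a universal
term contributes nothing to similarity, which is the desired behaviour.

### Term and patient similarity

Term similarity is Resnik's most-informative-common-ancestor form over the
reflexive is-a closure:

$$\mathrm{sim}(s,t) = \max_{v \in \mathrm{anc}(s)\cap \mathrm{anc}(t)} IC(v).$$

Reflexivity makes `sim(s, s) = IC(s)`. Only `is_a` edges define the DAG;
other OBO relation types are ignored. On multi-rooted toy ontologies the
ancestor intersection may be empty, in which case the similarity is defined
as 0 (no virtual super-root is inserted).

Patient similarity is the symmetric best-match average over the two term
sets:

$$\mathrm{sim}(D_a, D_b) = \frac{1}{2|D_a|}\sum_{s\in D_a}\max_{t\in D_b}\mathrm{sim}(s,t)
 + \frac{1}{2|D_b|}\sum_{t\in D_b}\max_{s\in D_a}\mathrm{sim}(s,t).$$

One property worth stating because it is easy to get wrong: each
*directional* best-match mean is monotone when the opposite set grows, but
the full BMA is **not** — adding a term to `D_b` also enlarges the
denominator of `D_b`'s own directional average, so the total can decrease
when the added term's IC is below that side's mean. The property tests
assert the true (directional) monotonicity.

`similarity_matrix()` computes all pairs by tabulating, once, the best
match of every vocabulary term against every patient, which collapses the
double sum into a matrix product. The result is identical (to strict
floating tolerance, verified cellwise against a literal-formula oracle) to
evaluating the equation pair by pair, and scales to cohorts of several
hundred patients in well under a second. Term columns are processed in
sorted term-id order so matrices are bit-reproducible across runs.

### Distance and complete-linkage clustering

The dissimilarity is `max(sim_mat) - sim_mat`, the maximum taken over the
full matrix **including** the diagonal. Self-similarity varies by patient
(it is their mean IC), so the raw transform has a positive diagonal; the
diagonal is therefore forced to exactly 0 (a `zero_diagonal = FALSE` escape
hatch records the alternative reading). The distance matrix itself is what
gets clustered — an alternative reading of heatmap-tool pipelines is that
rows of the distance matrix are re-distanced euclideanly before
clustering; this package clusters the distance matrix directly, which is
the literal reading of "clustering according to the distance matrix".

Agglomeration is complete linkage (inter-cluster distance = maximal
pairwise member distance), delegated to `stats::hclust` and verified
against a naive O(n³) re-scanning oracle. Complete linkage is monotone, so
merge heights never decrease. `cut_tree(dend, k)` cuts into exactly `k`
clusters and renumbers labels by descending size, so "cluster 1" is always
the largest — matching the convention of reporting the dominant phenotype
group first and making labels comparable across seeds.

### Cluster characterization

Per term: a 2×k presence/absence-by-cluster table tested with the Pearson
chi-square test, switching to Fisher's exact test when **any observed
cell** is below 10. That is the strictest reading of the conventional
"small group" rule; the threshold is a parameter (`fisher_threshold`).
Per continuous covariate: one-way ANOVA with mean ± SD summaries when every
cluster passes a Shapiro–Wilk normality check at α = 0.05, otherwise a
Kruskal–Wallis rank test with median (IQR) summaries. The normality test
and its α are design choices (the underlying convention names only
"normal vs skew"); both are explicit in the code and the gate is itself
re-verified in the tests by recomputing the per-group Shapiro decisions
independently.

### Survival

Time zero is definitive surgery; patients alive at last contact are
right-censored at the last revisit or follow-up. Kaplan–Meier estimation,
the k-group log-rank test, and Cox proportional-hazards regression are
delegated to the `survival` package and cross-checked in the tests against
literal product-limit, explicit risk-set (O−E, hypergeometric variance) and
grid-search partial-likelihood oracles. Cox ties default to Efron
(`ties = "breslow"` available); confidence intervals are reported as
`exp(coef ± 1.96·SE)` and p-values are two-sided Wald tests with α = 0.05
throughout.

Variable selection follows the two-stage published rule implemented in
`select_variables()`: univariate screening of the cluster (as a single
ordinal score, matching how a univariable "Cluster" row is conventionally
reported), demographics, surgery type, and terms with prevalence > 5%;
the multivariate model pools univariate-significant variables with the
cluster (dummy-coded, smallest cluster as reference), demographics, surgery
type and terms with prevalence > 25%. Surgery type enters as a three-level
factor; an ordinal single-row treatment seen in some published tables is
noted but not replicated.

## The synthetic cohort generator

`simulation_spec()` defaults describe the study conditions the package is
validated under:

| parameter | default | rationale |
|---|---|---|
| cluster sizes | 522 / 94 / 32 | the very unequal three-cluster shape of the emulated cohort (n = 648) |
| terms per patient | median ≈ 6, clamped to 1–12 | reported annotation depth |
| baseline hazard | 0.024 / year (exponential) | ≈ 88.7% five-year survival in the low-risk cluster |
| cluster hazard multipliers | 1 / 2 / 2 | clusters 2–3 carry roughly twice the hazard, the direction of the published KM separation |
| term log-hazard effects | ln 3.7 (abnormal AV connection analog), ln 2.3 (persistent left SVC analog) | the two published multivariate hits, used as planted truths for recovery tests |
| censoring | 51.2% "reached" → U(5, 13) y; 48.8% "lost" → U(0.25, 5) y | emulates a telephone-follow-up design with 48.81% loss, censoring the lost at an earlier last revisit; median follow-up ≈ 5 y |
| ages | lognormal, cluster medians 2 / 0.71 / 5.5 y | published per-cluster age medians |
| sex, BMI, surgery type | per-cluster frequencies | published descriptive table |

All randomness derives from one integer seed through named sub-streams
(terms, covariates, survival, censoring), so adding a stream never
perturbs the others, and a fixed seed gives byte-identical output files.

### Why the archetypes are sharper than real prevalence tables

The per-cluster term-inclusion probabilities (`default_archetypes()`)
follow the qualitative enrichment structure of the emulated cohort — VSD /
Fallot / RVH / collaterals defining the large cluster, hypoplastic right
heart / ASD / tricuspid disease the medium one, single ventricle /
dextrocardia / common atrium the small one — but they are deliberately
*disjoint-leaning* rather than copies of published prevalences, because
the package's validation demands that the planted partition be recoverable
by complete-linkage clustering of the Resnik/BMA distance.

Complete linkage is governed by worst-case pairs, which forces three design
rules, each found by analysis and confirmed by simulation during
development:

1. **Each cluster needs a probability-1 exclusive "defining lesion"
   marker.** A cluster's merge completion height is set by its *least*
   similar internal pair; without a guaranteed shared informative term two
   members can intersect in nothing but universal terms and the cluster's
   diameter reaches the height at which unrelated blocks merge. Note the
   majority cluster is structurally handicapped here: any term carried by
   ~80% of the cohort has IC ≤ 0.22 nats, so its within-cluster similarity
   floor is thin no matter how its signatures are chosen.
2. **Informative terms must not leak across clusters** (cross-cluster
   inclusion probabilities ≤ 0.01, most at 0.002). A single patient
   carrying another cluster's high-IC signature forms a high-similarity
   cross pair; under complete linkage such a "bridge" patient can be
   absorbed early into a foreign subcluster and pin that subcluster away
   from its own block — one bridge can misplace a hundred patients.
   Low-IC majority-cluster terms tolerate leaks freely (they attract
   nothing), which is why the VSD analog may still appear outside its home
   cluster while the tricuspid-disease analogs may not.
3. **Shared terms must be near-universal or cluster-confined.** A term (or
   an ontology ancestor) of mid-range frequency shared by two clusters
   gives *every* pair across them a similarity floor above the majority
   cluster's internal floor and reorders the top of the dendrogram. This
   also constrains the fixture ontology: the ASD/PFO analogs are septal
   children only, because giving them a second parent shared with the
   small cluster's common-atrium analog created precisely such a mid-IC
   bridge ancestor. (Multi-parent diamonds remain elsewhere — the Fallot
   analog under both ventricle and great-vessel branches, the AV-canal
   analog under septum and AV-connection.)

The consequences for interpretation are stated plainly: passing recovery
tests on this generator shows the pipeline correctly recovers *separable*
planted structure at realistic cohort shape, depth and censoring; it does
not show that real hospital cohorts — where informative phenotypes do leak
across clinical subgroups and mid-frequency comorbidities abound — carry
structure this clean. On real data the same pipeline may legitimately
produce clusters that complete linkage cannot protect from bridge
patients; average or Ward linkage (available via the `method` pass-through)
is more robust to exactly this failure mode.

Other things the generator does not emulate: echo/ECG measurement error,
genetic etiology, inter-hospital heterogeneity, informative censoring
(dropout is independent of risk), and competing risks.

## Numerical choices and degenerate inputs

* Floating accumulation order is fixed (sorted term ids; single matrix
  product), so similarity matrices are bit-identical across runs.
* Ties inside the max over common ancestors need no tie-break (only the IC
  value is used). Agglomeration tie-breaks are inherited from
  `stats::hclust`; the validation oracle uses continuous random distances
  where ties have probability zero.
* `cut_tree` size ties keep cut order; `remap_to_supported` breaks
  equal-depth ties lexicographically.
* Degenerate inputs: empty term sets are rejected at load; zero-frequency
  terms are dropped from IC with a warning; constant covariates are
  excluded from Cox models; a log-rank test with zero events errors
  rather than returning 0/0.
* Cox models containing a probability-1 cluster marker alongside cluster
  dummies are near-collinear by construction; `survival::coxph` then
  reports monotone-likelihood estimates (extreme hazard ratios with
  infinite confidence intervals and p ≈ 1) for those columns. This is
  faithful behaviour, visible in the multivariate screen on default
  simulations, and a known cost of rule-based variable selection plus
  mandatory markers.
* Fisher's exact test on 2×k tables uses the exact network algorithm with
  an enlarged workspace, falling back to the hybrid approximation only if
  the exact computation is infeasible.

## Problem sizes used in validation

The shipped test-and-acceptance workloads run at the study's native scale
where that matters (648-patient cohorts for recovery and survival
separation, 50 simulation seeds, 200 Cox replicates at n = 1000) and at
reduced scale for formula-equivalence oracles (random DAGs up to 100
terms, cohorts up to 20 patients, where the literal double-sum oracle is
affordable). These sizes are the package's validation design; the
implementation itself has no special-cased limits.

## Known limitations

* Resnik/BMA similarity with cohort-frequency IC systematically
  under-rewards the majority phenotype: its defining terms are common and
  hence carry little information. Stratification quality for a dominant
  subgroup rests on the *minority* clusters being coherent.
* Complete linkage's sensitivity to single outlier patients is inherited
  by the whole pipeline (see the archetype discussion above).
* `k` is fixed by the user (default 3); no automatic model selection or
  bootstrap stability analysis is provided.
* The OBO parser covers the `[Term]`/`id`/`name`/`is_a`/`alt_id`/
  `is_obsolete` subset of OBO 1.2/1.4 — sufficient for the HPO's is-a
  backbone and the packaged fixtures, not a general OBO toolchain.
* Proportional-hazards diagnostics (Schoenfeld residuals), competing
  risks and time-varying covariates are out of scope.
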
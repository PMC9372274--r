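# phenoclust

Deep phenotyping of congenital heart disease cohorts with the Human
Phenotype Ontology (HPO): ontology-based patient similarity, unsupervised
phenotype clustering, and survival comparison of the resulting clusters.

## The problem

Complex congenital defects such as pulmonary atresia are traditionally
classified by a single lesion (ventricular septal defect present/absent),
which ignores most of the recorded cardiac morphology. When every patient
is annotated with a set of HPO terms, the full phenotype profile can drive
an unsupervised stratification instead, and the resulting phenotype
clusters can be compared on survival after definitive surgery.

`phenoclust` implements that pipeline end to end for cohorts annotated with
ontology terms:

1. **Information content.** For each term `t` with cohort annotation
   frequency `p_t`, `IC(t) = -log p_t` (natural log by default): rare
   phenotypes are informative, universal ones carry nothing.
2. **Resnik term similarity.** `sim(s, t) = max { IC(v) : v ∈ anc(s) ∩
   anc(t) }` — the information content of the most informative common
   ancestor in the ontology DAG (ancestor closure is reflexive).
3. **Best-match-average patient similarity.** For patient term sets
   `D_a`, `D_b`:

   `sim(D_a, D_b) = 1/(2|D_a|) Σ_{s∈D_a} max_{t∈D_b} sim(s,t)
                  + 1/(2|D_b|) Σ_{t∈D_b} max_{s∈D_a} sim(s,t)`

4. **Distance and clustering.** The dissimilarity `max(sim_mat) − sim_mat`
   (diagonal forced to 0) is clustered by complete-linkage agglomeration and
   cut into `k` clusters (k = 3 by default), labels renumbered by
   descending size.
5. **Characterization and survival.** Per-term 2×k tables (Pearson
   chi-square, or Fisher's exact test when any cell is below 10),
   continuous covariates by ANOVA or Kruskal–Wallis behind a Shapiro–Wilk
   gate, Kaplan–Meier curves per cluster, the log-rank test, and a
   two-stage Cox proportional-hazards screen (univariate over clusters,
   demographics, surgery type and terms with prevalence > 5%; multivariate
   over the univariate-significant variables plus clusters, demographics,
   surgery type and terms with prevalence > 25%).

Because the hospital cohorts this methodology targets are not publicly
deposited, the package ships a first-class synthetic-cohort generator
(`simulation_spec()` / `generate_cohort()`) with planted phenotype clusters
of 522/94/32 patients, a toy cardiac ontology, covariates, and
proportional-hazards survival with cluster- and term-level effects — so
every stage is testable and every number below is reproducible offline.

## Worked example

```r
library(phenoclust)

obo <- system.file("extdata", "toy_cardiac.obo", package = "phenoclust")
dag <- parse_obo(obo)
dag
#> ontology_dag: 38 terms, 39 is-a edges, 1 root(s)
#>   obsolete (excluded): 1

sim <- generate_cohort(simulation_spec(seed = 42))
cohort <- sim$cohort
cohort
#> phenotype_cohort: 648 patients, 25 distinct terms
terms_per_patient(cohort)$median
#> [1] 6

ic <- information_content(term_frequencies(cohort, "propagated"))
simmat <- similarity_matrix(cohort, ic, dag)
simmat
#> patient_similarity: 648 patients, max 3.475

assignment <- cut_tree(complete_linkage(to_distance(simmat)), k = 3)
assignment
#> cluster_assignment: k = 3 sizes: 522/94/32
evaluate_recovery(assignment, sim$truth)$ari
#> [1] 1

records <- cohort$patients[, c("time", "event")]
logrank_test(records, assignment$labels[cohort$patients$patient_id])[c("chisq", "df", "p")]
#> $chisq 52.19   $df 2   $p 4.6e-12
km_readout(km_estimate(records), at = 5)$surv_at
#> [1] 0.8394515
```

Read: at this seed the three planted phenotype clusters are recovered
exactly (sizes 522/94/32, adjusted Rand index 1), their survival differs
strongly (log-rank p ≈ 5e-12 — the small clusters carry twice the baseline
hazard), and overall five-year survival is ≈ 84%. `cluster_term_table()`,
`cluster_covariate_table()` and `cox_screen()` then produce the
characterization and risk-factor tables, and `run_pipeline(run_config(...))`
writes every stage artifact (IC table, similarity/distance matrices,
dendrogram, assignment, summary tables, KM/log-rank/Cox outputs, manifest)
into an output directory. A thin command-line front end lives at
`inst/cli/phenoclust.R`.

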
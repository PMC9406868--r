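# m6aScore

Consensus subtyping and PCA-based scoring of N6-methyladenosine (m6A)
regulators in prostate-cancer expression cohorts.

## The problem

Most prostate cancers are indolent at diagnosis, but metastatic progression
drives nearly all disease-specific mortality, and there is no reliable
molecular marker for metastatic risk.  m6A is the most common reversible
mRNA modification; it is deposited, removed and recognized by a panel of 21
regulator genes ("writers" such as METTL3 and WTAP, "erasers" ALKBH5 and
FTO, and "readers" such as YTHDF1-3 and HNRNPA2B1), and its dysregulation
tracks progression in several cancers.  This package implements, as a
tested and reusable pipeline, an m6A-regulator analysis of bulk
expression cohorts aimed at exactly that question: do m6A regulator
expression patterns define tumor subtypes, and can a compact per-sample
score built from them predict metastasis?

It is written for computational biologists who want to run, audit or
stress-test this class of analysis.  Because the original cohorts are
external data, the package ships a seeded synthetic-cohort generator with
the same statistical structure (latent subtypes, metastasis labels driven
by a regulator subset, subtype-correlated grades, censored survival), so
every stage is verifiable end to end on data with known truth.

## The method

Given a log2 gene-by-sample matrix and clinical annotations:

1. **Regulator screen** — Mann-Whitney U per regulator, tumor vs normal;
   selection at raw p < 0.05.
2. **Consensus clustering** of tumors on the selected regulators:
   average-linkage hierarchical clustering on the Pearson correlation
   distance d(i,j) = 1 − r(i,j), resampled (80% of samples, 1000
   iterations); the consensus matrix C holds co-clustering frequencies.
   The cluster number k maximizes k ≥ 3 subject to the relative delta-area
   rule Δ(k) = (A(k) − A(k−1))/A(k−1) ≥ 0.2, where A(k) is the area under
   the CDF of the entries of C; otherwise k = 2.  Clusters are validated by
   silhouette widths and pairwise SigClust Monte-Carlo tests.
3. **Signature** — pairwise per-gene t tests between subtypes with
   Benjamini–Hochberg control; significant at |log2FC| > 2, FDR < 0.05;
   de-duplicated union across comparisons.
4. **m6A score** — Student's t screen of the regulators between metastatic
   and non-metastatic tumors; PCA on the z-scored metastasis-associated
   regulators; per sample,

   `m6A score = PC1 + PC2`

   (the sum of the sample's coordinates on the first two oriented
   components).  Signs are fixed so the score anti-correlates with mean
   regulator expression: m6A-hyperactive, metastasis-prone samples score
   low.
5. **Evaluation** — ROC/AUC for metastasis (low score = positive), one-way
   ANOVA across subtypes and Gleason grades, Kaplan–Meier curves with
   log-rank tests for overall and recurrence-free survival, Spearman
   correlations with each regulator and with a rank-based stemness index
   scaled to [0, 1].

See `vignettes/m6a-regulator-analysis.Rmd` for the full methodological
account, including the generator's design and every numerical convention.

## Worked example

```r
library(m6aScore)

cohort <- simulate_cohort(sim_config(seed = 11))   # 150 tumors, 30 normals
res <- run_m6a_pipeline(cohort$expression, cohort$clinical,
                        n_iter = 250, k_max = 6, sigclust_n_sim = 200,
                        seed = 42)
print(res)
#> m6A regulator analysis pipeline
#>   tumor-vs-normal screen: 21/21 regulators selected
#>   consensus clustering: chosen k = 3; mean silhouette 0.520
#>   DEG signature: 16 genes
#>   metastasis screen: 7 regulators
#>   metastasis AUC (low score = metastatic): 0.987
#>   RFS log-rank p = 0.00628; OS log-rank p = 0.297

print(res$k_selection)
#> Consensus-CDF k selection
#>  k   area  delta
#>  2 0.4522 0.4522
#>  3 0.6710 0.4838
#>  4 0.6772 0.0092
#>  5 0.6859 0.0129
#>  6 0.6955 0.0140
#> chosen k = 3 (relative delta threshold 0.20)

adjusted_rand_index(res$subtypes, cohort$truth$subtype)
#> [1] 0.9799376
```

Reading the output: the delta-area rule stops at k = 3 (the gain from 3 to
4 clusters is under 1%), and the recovered subtypes agree with the
generator's latent subtypes at ARI 0.98.  The metastasis screen recovers
exactly the 7 regulators that drive the simulated metastasis labels, and
the score built on them separates metastatic from non-metastatic tumors
with AUC 0.987 in the expected direction (metastatic tumors score lower).
Recurrence-free survival differs across subtypes (the generator gives the
hyperactive subtype a 2.5-fold recurrence hazard) while overall survival,
which carries no subtype effect, does not.

Per-sample scores are plain data frames:

```r
head(compute_scores(res$score_model, cohort$expression[, names(res$subtypes)]))
#>   sample_id       pc1        pc2  m6a_score
#> 1     T0001  1.817349 -0.6189338  1.1984148
#> 2     T0002  1.118426 -0.2526186  0.8658073
#> 3     T0003 -3.096661 -0.4952585 -3.5919192
#> ...
```

A thin command-line wrapper with `simulate`, `screen`, `cluster`,
`signature`, `score` and `evaluate` subcommands is installed at
`inst/scripts/m6a-pipeline.R`.

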
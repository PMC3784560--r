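# cnvprior

Phenotype-specific prioritization of genes affected by copy number
variants (CNVs), for geneticists and method developers interpreting
array-CGH-style deletion/duplication calls against a disease of
interest.

Most CNVs found by genome-wide testing are rare or private, so raw
case/control frequency cannot tell pathogenic from benign. `cnvprior`
fuses two complementary evidence streams for a fixed phenotype defined
by a curated set of *training genes*:

**Stage 1 — composite pathogenicity score.** Every gene is matched to
the training set across six knowledge sources: four category-based
annotation systems (GO-like, mouse-phenotype, pathway and miRNA-target
gene sets; hypergeometric enrichment selects training-enriched
categories, and a gene scores the sum of `-log p` weights of the
enriched categories containing it), a tissue-expression contrast
(Welch-type statistic between tissues where training genes are most vs
least expressed), and truncated network communicability
(`G = Σ_{k=1..6} A^k / k!`) to the training proteins. Each raw feature
becomes a standardized tail log-ratio metric

&nbsp;&nbsp;&nbsp;&nbsp;`z( ln[ P(training ≥ s) / P(background ≥ s) ] )`

and the composite score is the mean of the available features (missing
stays missing; all-missing genes score 0).

**Stage 2 — Bayes factor.** Per-gene deletion frequencies in a case and
a background cohort are modelled as gamma–Poisson counts. A background
gamma prior is centred on the background rate (zero-count genes get a
pseudo-rate of ¼ the lowest observed rate); an informed prior scales
that mean by `1 + κ·s·r*/(r* + r)` for positive scores `s` (κ
calibrated so a unit score at a frequency of 1/2,940 gives a 4.5-fold
increase). The Bayes factor is the ratio of the marginal probabilities
of the observed case count under the two priors, floored at 1, with
conjugate posterior rate distributions. Per-subject gene loads (top-3
Bayes factors with leave-one-subject-out correction), rank-sum cohort
comparisons, leave-one-out cross-validation, ROC/AUC and a
sensitivity/specificity decision-rule sweep complete the pipeline.

A synthetic-data module generates every input — annotation GMTs,
expression matrix, interaction edge list, gene models, cohort CNV
tables — with the statistical structure the method assumes, so the full
pipeline runs and is tested without any external database.

## Worked example

```r
library(cnvprior)

cfg    <- simulation_config(seed = 42)
study  <- simulate_study(cfg)          # knowledge + gene models + CNV calls
scores <- pathogenicity_scores(study$knowledge, study$training)

calls <- filter_calls(study$calls)     # 15 Mb / 4 probes / log2 filters
rec   <- gene_frequency_records(calls, study$gene_models, 2000, 2000)
bayes <- bayes_factor_table(rec, scores)
head(bayes[order(-bayes$bayes_factor), ], 5)
```

```
   gene score k_case k_bg case_per_1000 bg_per_1000 scaling_factor bayes_factor
 G00135  2.59     20    0          10.0         0.0           17.8      7720.83
 G00452  2.34     21    0          10.5         0.0           16.2      5797.07
 G00186  1.80     22    3          11.0         1.5            2.8       229.42
 G00355  1.75      4    0           2.0         0.0           12.4        23.99
 G00293  0.83      2    0           1.0         0.0            6.4         5.22
```

The three planted risk genes of this simulation (`G00135`, `G00186`,
`G00452`) occupy the top three Bayes factors: they combine high
pathogenicity scores (training-like annotation, expression and network
profiles) with case-specific deletion enrichment (`k_case` vs `k_bg`
out of 2,000 subjects each; `*_per_1000` are the same counts per 1,000
subjects). `G00355` shows how a rarely deleted gene with a high score
is boosted (scaling factor 12.4) while the commonly deleted `G00186`
has its knowledge influence attenuated (2.8) — frequency already speaks
for itself there. Leave-one-out cross-validation of the composite score
on this synthetic study gives AUC 1.0 (`loo_crossval()` +
`roc_points()`); on real, noisier knowledge sources this class of score
typically reaches the mid-0.8s.

A thin command-line wrapper covers the same stages
(`inst/scripts/cnvprior.R` with subcommands `simulate`, `score`,
`bayes`, `cohort`, `evaluate`, `all`).

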
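Package: cnvprior
Title: Phenotype-Specific Gene Prioritization for Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage prioritization of genes affected by copy number
    variants for a fixed phenotype. Stage one builds a composite
    pathogenicity score for every gene by matching it against a training
    gene set across several knowledge sources: category-based annotation
    systems (GO-like, mouse-phenotype-like, pathway and miRNA-target gene
    sets) scored through hypergeometric enrichment, a tissue-contrast
    expression statistic, and truncated network communicability on a
    protein-interaction graph; per-source scores are converted to
    standardized tail log-ratio metrics and averaged. Stage two fuses the
    composite score with per-gene deletion frequencies from case and
    background cohorts through a gamma-Poisson model, yielding per-gene
    Bayes factors, posterior rate distributions, per-subject gene-load
    statistics with leave-one-subject-out correction, and a
    sensitivity/specificity decision-rule sweep. A synthetic-data module
    generates all inputs with the statistical structure the method
    assumes, so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
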
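toy_calls <- function() {
  data.frame(
    subject = c("s1", "s1", "s2", "s3", "s4", "s5"),
    cohort = c("case", "case", "case", "background", "case", "case"),
    chrom = "chr1",
    start = c(100, 150, 100, 100, 1e6, 100),
    end = c(200, 260, 200, 200, 17e6, 200),
    type = c("deletion", "deletion", "deletion", "deletion",
             "deletion", "duplication"),
    n_probes = c(10L, 8L, 12L, 9L, 50L, 3L),
    mean_log2 = c(-0.8, -0.7, -0.9, -0.85, -0.8, 0.6),
    stringsAsFactors = FALSE)
}

toy_genes <- function() {
  data.frame(gene = c("gA", "gB", "gC", "gD"),
             chrom = c("chr1", "chr1", "chr1", "chr2"),
             start = c(50, 150, 200, 150),
             end = c(99, 160, 300, 160),
             stringsAsFactors = FALSE)
}

test_that("call filtering applies the span, probe and log2 rules, idempotently", {
  calls <- data.frame(
    subject = "s", cohort = "case", chrom = "chr1",
    start = c(1, 1, 1, 1, 1),
    end = c(16e6, 1e6, 1e6, 1e6, 1e6),
    type = c("deletion", "deletion", "deletion", "duplication",
             "duplication"),
    n_probes = c(20L, 3L, 20L, 5L, 5L),
    mean_log2 = c(-0.8, -0.5, -0.25, 0.25, 0.15),
    stringsAsFactors = FALSE)
  kept <- filter_calls(calls)
  # 16 Mb removed; 3 probes removed; shallow deletion (-0.25) removed;
  # duplication at 0.25 kept; duplication at 0.15 removed
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$type, "duplication")
  expect_equal(kept$mean_log2, 0.25)
  expect_identical(filter_calls(kept), kept)

  # type-consistency: a "deletion" with duplication-like log2 is rejected
  bad <- calls[1, ]
  bad$mean_log2 <- 0.5
  expect_equal(nrow(filter_calls(bad)), 0L)
})

test_that("interval-gene overlap follows closed 1-base-minimum semantics", {
  genes <- toy_genes()
  call <- list(chrom = "chr1", start = 100, end = 200)
  hit <- genes_in_interval(call, genes)
  # [50,99] misses by one base; [150,160] inside; [200,300] touches at 200;
  # chr2 gene with overlapping coordinates excluded
  expect_setequal(hit, c("gB", "gC"))
  # a gene overlapping by exactly one base is included
  g1 <- data.frame(gene = "edge", chrom = "chr1", start = 1, end = 100)
  expect_equal(genes_in_interval(call, g1), "edge")
})

test_that("deletion counts are distinct-subject, per cohort, and additive over cohorts", {
  calls <- toy_calls()
  genes <- toy_genes()
  counts <- gene_deletion_counts(calls, genes, "case")
  # s1 has two overlapping deletions over gB: counts once
  expect_equal(unname(counts["gB"]), 2L)   # s1, s2
  expect_equal(unname(counts["gC"]), 2L)   # s1 (via 150-260), s2 (touch 200)
  expect_equal(unname(counts["gA"]), 0L)
  expect_equal(unname(counts["gD"]), 0L)   # chr2 never touched
  # duplications (s5) never contribute
  bgc <- gene_deletion_counts(calls, genes, "background")
  pooled <- gene_deletion_counts(calls, genes, NULL)
  expect_equal(pooled, counts + bgc)
})

test_that("per-subject maximum pathogenicity respects type and exclusions", {
  calls <- toy_calls()
  genes <- toy_genes()
  scores <- c(gA = 0.2, gB = 1.7, gC = -0.4, gD = 3)
  mx <- subject_max_pathogenicity(calls, genes, scores, "deletion")
  expect_equal(mx[["s1"]], 1.7)
  # the duplication-only subject is absent from the deletion analysis
  expect_false("s5" %in% names(mx))
  # excluding the top gene exposes the runner-up
  mx2 <- subject_max_pathogenicity(calls, genes, scores, "deletion",
                                   exclude_genes = "gB")
  expect_equal(mx2[["s1"]], -0.4)
  # duplications scored separately
  mx3 <- subject_max_pathogenicity(calls, genes, scores, "duplication")
  expect_equal(names(mx3), "s5")
})

test_that("leave-one-subject-out corrects counts and round-trips exactly", {
  rec <- data.frame(gene = c("gA", "gB", "gC"),
                    k_case = c(5L, 1L, 3L), n_case = 1000L,
                    k_bg = c(2L, 0L, 1L), n_bg = 1200L,
                    stringsAsFactors = FALSE)
  sc <- c(gA = 1.2, gB = 2.0, gC = 0.8)
  global <- bayes_factor_table(rec, sc)

  # subject outside the frequency cohort: identical to the global table
  l0 <- loo_subject_bayes_factors(c("gA", "gB"), rec, sc)
  expect_equal(l0$top_genes$bayes_factor,
               sort(global$bayes_factor[global$gene %in% c("gA", "gB")],
                    decreasing = TRUE))

  # sole contributor: gB recomputed at k_case = 0, floored at 1, so it
  # drops out of the >1 list
  l1 <- loo_subject_bayes_factors("gB", rec, sc, contributes = "gB")
  expect_equal(nrow(l1$top_genes), 0L)
  expect_equal(l1$max_bf, 1)

  # removing and re-adding a subject's contribution restores the table
  rec2 <- rec
  rec2$k_case[rec2$gene == "gA"] <- rec2$k_case[rec2$gene == "gA"] - 1L
  rec3 <- rec2
  rec3$k_case[rec3$gene == "gA"] <- rec3$k_case[rec3$gene == "gA"] + 1L
  expect_identical(bayes_factor_table(rec3, sc), global)

  # bookkeeping violation surfaces as an error
  rec0 <- rec
  rec0$k_case[2] <- 0L
  expect_error(loo_subject_bayes_factors("gB", rec0, sc,
                                         contributes = "gB"),
               "bookkeeping")
})

test_that("subject loads rank the top three corrected Bayes factors", {
  cfg <- simulation_config(seed = 21, n_genes = 150L, n_training = 10L,
                           cohorts = list(n_case = 400L, n_bg = 400L,
                                          base_rate = 2e-3))
  st <- simulate_study(cfg)
  sc <- pathogenicity_scores(st$knowledge, st$training)
  fc <- filter_calls(st$calls)
  rec <- gene_frequency_records(fc, st$gene_models, 400L, 400L)
  case_subjects <- unique(fc$subject[fc$cohort == "case"])
  loads <- subject_bayes_loads(fc, st$gene_models, rec, sc,
                               frequency_subjects = case_subjects)
  expect_true(all(loads$max_bf >= loads$bf2 & loads$bf2 >= loads$bf3))
  expect_true(all(loads$max_bf >= 1))
  expect_true(all(is.na(loads$gene1) | loads$max_bf > 1))
  expect_setequal(unique(loads$cohort), c("case", "background"))
})

test_that("cohort comparison is an exact rank-sum agreeing with enumeration", {
  a <- c(10, 11, 12)
  b <- c(1, 2, 3)
  res <- compare_cohorts(a, b, alternative = "greater")
  expect_equal(res$p_value, 1 / choose(6, 3), tolerance = 1e-12)
  expect_equal(res$p_value, ranksum_perm_oracle(a, b), tolerance = 1e-12)

  set.seed(2)
  x <- rnorm(8); y <- rnorm(9)
  r1 <- compare_cohorts(x, y)
  r2 <- compare_cohorts(exp(x), exp(y))   # common monotone transform
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  expect_equal(compare_cohorts(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_warning(res0 <- compare_cohorts(c(2, 2), c(2, 2)), "tied")
  expect_equal(res0$p_value, 1)
})
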
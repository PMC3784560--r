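test_that("enrichment p-values agree with the direct-summation oracle on small universes", {
  set.seed(41)
  for (rep in 1:40) {
    N <- sample(8:30, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:(N - 2), 1)
    training <- sample(universe, K)
    cats <- lapply(1:5, function(i) sample(universe, sample(2:(N - 1), 1)))
    names(cats) <- paste0("c", 1:5)
    sys <- annotation_system("toy", cats, universe)
    # permissive thresholds so every category is reported
    enr <- select_enriched_categories(sys, training,
                                      enrichment_thresholds(max_p = 1,
                                                            min_odds_ratio = 0,
                                                            min_training = 0))
    for (i in seq_len(nrow(enr))) {
      n <- length(cats[[enr$category[i]]])
      k <- length(intersect(cats[[enr$category[i]]], training))
      expect_equal(enr$p_value[i], hyper_tail_oracle(N, K, n, k),
                   tolerance = 1e-12)
      expect_equal(enr$weight[i], -log(enr$p_value[i]))
    }
  }
})

test_that("selection matches the stated examples and boundary cases", {
  # a category holding all 5 training genes in a 20-gene universe:
  # p is the single hypergeometric term 1/choose(20, 5)
  universe <- paste0("g", 1:20)
  training <- universe[1:5]
  sys <- annotation_system("toy", list(hit = training,
                                       none = universe[6:15]), universe)
  enr <- select_enriched_categories(sys, training)
  expect_equal(enr$category, "hit")
  expect_equal(enr$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(enr$n_training, 5L)

  # categories with zero training overlap have p = 1 and are never selected
  enr_all <- select_enriched_categories(
    sys, training, enrichment_thresholds(max_p = 1, min_odds_ratio = 0,
                                         min_training = 0))
  expect_equal(enr_all$p_value[enr_all$category == "none"], 1)
  expect_false("none" %in% enr$category)

  # genome-scale example: 5 of 83 training genes in a 10-gene category
  big_universe <- paste0("g", 1:20000)
  big_training <- big_universe[1:83]
  cat10 <- c(big_training[1:5], big_universe[100:104])
  sys_big <- annotation_system("big", list(hot = cat10), big_universe)
  enr_big <- select_enriched_categories(sys_big, big_training)
  expect_equal(enr_big$category, "hot")
  expect_equal(enr_big$p_value, hyper_tail_oracle(20000, 83, 10, 5),
               tolerance = 1e-10)
})

test_that("degenerate and unusable systems are handled", {
  universe <- paste0("g", 1:10)
  sys <- annotation_system("toy", list(all = universe,
                                       half = universe[1:5]), universe)
  expect_warning(
    enr <- select_enriched_categories(sys, universe[1:4],
                                      enrichment_thresholds(max_p = 1,
                                                            min_odds_ratio = 0,
                                                            min_training = 0)),
    "whole")
  expect_false("all" %in% enr$category)
  expect_error(select_enriched_categories(sys, c("zz1", "zz2")),
               "no training gene")
  expect_error(annotation_system("bad", list(a = character())))
  expect_error(annotation_system("bad", list(a = "outside"), universe))
})

test_that("match scores are additive -log(p) sums, missing off-universe, monotone", {
  universe <- paste0("g", 1:50)
  training <- universe[1:6]
  cats <- list(c1 = c(training[1:4], "g10"),
               c2 = c(training[2:5], "g10", "g11"),
               c3 = universe[20:30])
  sys <- annotation_system("toy", cats, universe)
  enr <- select_enriched_categories(sys, training,
                                    enrichment_thresholds(max_p = 1,
                                                          min_odds_ratio = 0,
                                                          min_training = 1))
  enr_sel <- enr[enr$category %in% c("c1", "c2"), ]
  sc <- annotation_match_scores(c("g10", "g11", "g40", "zz"), sys, enr_sel)
  w <- setNames(enr_sel$weight, enr_sel$category)
  expect_equal(sc[["g10"]], sum(w))              # in both categories
  expect_equal(sc[["g11"]], w[["c2"]])           # in one
  expect_identical(sc[["g40"]], 0)               # covered, in none
  expect_true(is.na(sc[["zz"]]))                 # off-universe: missing

  # one enriched category at p = 0.01 yields exactly -log(0.01)
  fake <- data.frame(category = "c1", p_value = 0.01, odds_ratio = 5,
                     n_training = 4, weight = -log(0.01))
  sc2 <- annotation_match_scores("g10", sys, fake)
  expect_equal(sc2[["g10"]], 4.60517, tolerance = 1e-5)

  # membership in one more enriched category never decreases the score
  expect_gte(sc[["g10"]], sc[["g11"]])
})

test_that("removing training genes from categories collapses enrichment", {
  universe <- paste0("g", 1:100)
  training <- universe[1:8]
  cats <- list(sig = c(training[1:5], "g50"),
               bulk = universe[40:80])
  sys <- annotation_system("toy", cats, universe)
  expect_true("sig" %in%
                select_enriched_categories(sys, training)$category)
  stripped <- lapply(cats, setdiff, training)
  sys2 <- annotation_system("toy", stripped, universe)
  expect_equal(nrow(select_enriched_categories(sys2, training)), 0L)
})
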
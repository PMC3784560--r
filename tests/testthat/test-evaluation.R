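test_that("ROC and AUC follow pair-counting and invariance rules", {
  sc <- c(a = 4, b = 3, c = 2, d = 1)
  r <- roc_points(sc, positives = c("a", "c"))
  expect_equal(r$auc, 0.75)    # 3 of 4 positive-negative pairs won

  perfect <- roc_points(c(p1 = 9, p2 = 8, n1 = 2, n2 = 1), c("p1", "p2"))
  expect_equal(perfect$auc, 1)
  expect_true(all(r$points$sensitivity >= 0 & r$points$sensitivity <= 1))
  expect_true(all(diff(r$points$sensitivity) >= 0))  # thresholds descend

  # invariant under strictly monotone transforms
  r2 <- roc_points(exp(sc), positives = c("a", "c"))
  expect_equal(r2$auc, r$auc)

  # label-independent scores give chance-level AUC at large n
  set.seed(8)
  big <- setNames(rnorm(4000), paste0("g", 1:4000))
  r3 <- roc_points(big, positives = paste0("g", sample(4000, 800)))
  expect_equal(r3$auc, 0.5, tolerance = 0.03)

  expect_error(roc_points(sc, positives = names(sc)), "strict subset")
  expect_error(roc_points(sc, positives = character()), "strict subset")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- setNames(rnorm(300), paste0("g", 1:300))
  pos <- paste0("g", sample(300, 60))
  ours <- roc_points(sc, pos)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = names(sc) %in% pos, predictor = unname(sc),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("the decision-rule sweep counts strictly-greater positives", {
  loads <- data.frame(
    cohort = c("case", "case", "background", "background"),
    max_bf = c(5, 1, 2, 1))
  sw <- decision_rule_sweep(loads, cutoffs = c(0.5, 2, 10))
  expect_equal(sw$sensitivity, c(1, 0.5, 0))
  expect_equal(sw$specificity, c(0, 1, 1))

  # monotone: sensitivity nonincreasing, specificity nondecreasing
  set.seed(4)
  loads2 <- data.frame(cohort = sample(c("case", "background"), 100,
                                       replace = TRUE),
                       max_bf = pmax(1, rexp(100, 0.3)))
  sw2 <- decision_rule_sweep(loads2, cutoffs = seq(0.5, 12, by = 0.25))
  expect_true(all(diff(sw2$sensitivity) <= 0))
  expect_true(all(diff(sw2$specificity) >= 0))
})

test_that("cross-validation holds each training gene out of every pipeline stage", {
  cfg <- simulation_config(seed = 77, n_genes = 150L, n_training = 10L)
  kn <- simulate_knowledge(cfg)
  cv <- loo_crossval(kn, kn$training)
  expect_length(cv$scores, length(kn$genes))
  expect_length(cv$failed, 0L)
  # held-out scores differ from full-pipeline scores for training genes
  full <- setNames(cv$full$composite, cv$full$gene)
  expect_false(any(cv$scores[kn$training] == full[kn$training]))
  # background genes keep their full-pipeline scores
  bg <- setdiff(kn$genes, kn$training)
  expect_equal(cv$scores[bg], full[bg])
})

test_that("a training gene absent from every source cross-validates to zero", {
  universe <- paste0("g", 1:40)
  training <- c(universe[1:4], "orphan")
  cats <- list(c1 = universe[1:6], c2 = universe[c(1:4, 10:12)],
               c3 = universe[20:30])
  sys <- annotation_system("go", cats, universe)
  expr <- matrix(rnorm(40 * 8, 5), 40, 8,
                 dimnames = list(universe, paste0("T", 1:8)))
  expr[universe[1:4], 1:2] <- expr[universe[1:4], 1:2] + 3
  net <- ppi_network(cbind(universe[1:5], universe[2:6]), nodes = universe)
  kn <- list(genes = c(universe, "orphan"), systems = list(go = sys),
             expression = expr, network = net)
  th <- score_config(thresholds = enrichment_thresholds(max_p = 0.05,
                                                        min_training = 2),
                     min_tissues = 2L)
  cv <- suppressWarnings(loo_crossval(kn, training, th))
  expect_identical(unname(cv$scores["orphan"]), 0)
})

test_that("an exclusive category stays enriched when one member is held out", {
  universe <- paste0("g", 1:200)
  training <- universe[1:3]
  cats <- list(excl = training,
               other = universe[50:90])
  sys <- annotation_system("go", cats, universe)
  enr_full <- select_enriched_categories(sys, training)
  expect_true("excl" %in% enr_full$category)
  enr_loo <- select_enriched_categories(sys, training[-1])
  expect_true("excl" %in% enr_loo$category)
  # so the held-out member still collects that category's weight
  sc <- annotation_match_scores(training[1], sys, enr_loo)
  expect_gt(sc[[1]], 0)
})

test_that("percentile gain reports detection efficiency over background cutoffs", {
  set.seed(6)
  sc <- setNames(c(rnorm(50, 2), rnorm(450)), paste0("g", 1:500))
  pg <- percentile_gain(sc, paste0("g", 1:50))
  expect_true(all(diff(pg$fraction_detected) <= 0))
  expect_equal(pg$fraction_detected[1], 1)   # everyone clears the minimum
  expect_gt(pg$fraction_detected[which.min(abs(pg$percentile - 0.95))],
            0.5)
})
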
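#' Leave-one-out cross-validation of the composite score
#'
#' For each training gene, the entire stage-one pipeline — enriched-category
#' selection, contrast-tissue choice, communicability target set, tail
#' fractions and standardization — is re-run with that gene removed from the
#' training set, and the held-out gene's composite score is recorded.
#' Background genes are scored once with the full training set. The
#' communicability matrix does not depend on the training set (the held-out
#' gene stays in the network) and is computed once.
#'
#' @param knowledge Knowledge bundle as for [pathogenicity_scores()].
#' @param training Character vector of training genes (>= 3).
#' @param config A [score_config()].
#' @return List with `scores` (named vector: cross-validated composites for
#'   training genes, full-pipeline composites for all others), `full` (the
#'   full-training score table) and `failed` (training genes whose fold
#'   errored; their score is `NA`).
#' @export
loo_crossval <- function(knowledge, training, config = score_config()) {
  training <- unique(as.character(training))
  if (length(training) < 3L) stop("need at least 3 training genes")
  G <- if (!is.null(knowledge$network))
    truncated_communicability(knowledge$network, config$max_len) else NULL
  full <- pathogenicity_scores(knowledge, training, config, G = G)
  scores <- stats::setNames(full$composite, full$gene)
  failed <- character()
  for (g in training) {
    fold <- tryCatch(
      pathogenicity_scores(knowledge, setdiff(training, g), config, G = G),
      error = function(e) e)
    if (inherits(fold, "error")) {
      failed <- c(failed, g)
      scores[g] <- NA_real_
    } else {
      scores[g] <- fold$composite[match(g, fold$gene)]
    }
  }
  if (length(failed))
    warning("cross-validation folds failed for: ",
            paste(failed, collapse = ", "))
  list(scores = scores, full = full, failed = failed)
}

#' ROC curve and area under the curve
#'
#' Standard ROC over score thresholds (predict positive when
#' `score >= threshold`), with tied scores grouped into a single threshold.
#' The AUC is computed by the trapezoid rule over (1 - specificity,
#' sensitivity), equivalently the probability that a random positive
#' outscores a random negative with ties counted half.
#'
#' @param scores Named numeric vector of scores over all genes.
#' @param positives Character vector naming the positive genes; must be a
#'   non-empty strict subset of the scored genes.
#' @return List with `points` (data.frame `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_points <- function(scores, positives) {
  stopifnot(!is.null(names(scores)))
  scores <- scores[!is.na(scores)]
  lab <- names(scores) %in% positives
  if (!any(lab) || all(lab))
    stop("positives must be a non-empty strict subset of scored genes")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  sens <- vapply(thr, function(t) sum(lab & scores >= t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(!lab & scores < t) / n_neg, numeric(1))
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Percentile gain curve of the cross-validated scores
#'
#' For each percentile cutoff of the background score distribution, the
#' fraction of positive genes meeting or exceeding that cutoff — a
#' detection-efficiency view of the same ranking the ROC summarizes.
#'
#' @param scores Named numeric vector of scores.
#' @param positives Character vector of positive genes.
#' @param percentiles Percentile grid in `[0, 1]`.
#' @return Data.frame with `percentile`, `cutoff`, `fraction_detected`.
#' @export
percentile_gain <- function(scores, positives,
                            percentiles = seq(0, 1, by = 0.01)) {
  scores <- scores[!is.na(scores)]
  lab <- names(scores) %in% positives
  bg <- scores[!lab]
  cutoff <- stats::quantile(bg, percentiles, names = FALSE, type = 7)
  frac <- vapply(cutoff, function(cz) mean(scores[lab] >= cz), numeric(1))
  data.frame(percentile = percentiles, cutoff = cutoff,
             fraction_detected = frac)
}

#' Sensitivity/specificity sweep of the max-Bayes-factor decision rule
#'
#' Treats each subject's maximum Bayes factor among deleted genes as a
#' binary classifier of case status across a grid of cutoffs: a subject is
#' called positive when their maximum Bayes factor strictly exceeds the
#' cutoff. Subjects with no gene above 1 carry a maximum of 1 by
#' definition.
#'
#' @param loads Data.frame with columns `cohort` and `max_bf` (see
#'   [subject_bayes_loads()]).
#' @param cutoffs Numeric vector of Bayes-factor cutoffs; defaults to the
#'   observed values.
#' @param case_label,bg_label Cohort labels.
#' @return Data.frame with `threshold`, `sensitivity`, `specificity`.
#' @export
decision_rule_sweep <- function(loads, cutoffs = NULL,
                                case_label = "case",
                                bg_label = "background") {
  stopifnot(all(c("cohort", "max_bf") %in% names(loads)))
  case_bf <- loads$max_bf[loads$cohort == case_label]
  bg_bf <- loads$max_bf[loads$cohort == bg_label]
  if (length(case_bf) == 0L || length(bg_bf) == 0L)
    stop("both cohort labels must be present")
  if (is.null(cutoffs)) cutoffs <- sort(unique(c(1, loads$max_bf)))
  data.frame(
    threshold = cutoffs,
    sensitivity = vapply(cutoffs, function(t) mean(case_bf > t), numeric(1)),
    specificity = vapply(cutoffs, function(t) mean(bg_bf <= t), numeric(1))
  )
}
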
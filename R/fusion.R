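#' Tail log-ratio metric
#'
#' Converts a raw feature score into the probability-ratio metric: the log
#' of the fraction of training genes with a score at least as high as the
#' index gene's, over the same fraction among background genes (all scored
#' genes). Comparisons are inclusive (`>=`). A zero tail fraction is floored
#' at `1/(2n)` for the respective set so the log stays finite.
#'
#' @param score Numeric vector of raw scores to convert (`NA` propagates).
#' @param training_scores Non-empty numeric vector of raw training-gene
#'   scores.
#' @param background_scores Non-empty numeric vector of raw background-gene
#'   scores (conventionally all genes, training included).
#' @return Numeric vector of natural-log ratios, same length as `score`.
#' @export
tail_logratio <- function(score, training_scores, background_scores) {
  training_scores <- training_scores[!is.na(training_scores)]
  background_scores <- background_scores[!is.na(background_scores)]
  if (length(training_scores) == 0L)
    stop("training_scores must be non-empty")
  if (length(background_scores) == 0L)
    stop("background_scores must be non-empty")
  n_tr <- length(training_scores)
  n_bg <- length(background_scores)
  sort_tr <- sort(training_scores)
  sort_bg <- sort(background_scores)
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  # count(v >= s) = n - count(v < s)
  ge_tr <- n_tr - findInterval(score[ok], sort_tr, left.open = TRUE)
  ge_bg <- n_bg - findInterval(score[ok], sort_bg, left.open = TRUE)
  frac_tr <- pmax(ge_tr / n_tr, 1 / (2 * n_tr))
  frac_bg <- pmax(ge_bg / n_bg, 1 / (2 * n_bg))
  out[ok] <- log(frac_tr / frac_bg)
  out
}

#' Standardize a metric to zero mean and unit standard deviation
#'
#' Subtracts the mean and divides by the sample (n-1) standard deviation of
#' the defined values; `NA` propagates. A feature with fewer than two
#' defined values or zero spread is degenerate and raises an error.
#'
#' @param x Numeric vector (may contain `NA`).
#' @return Numeric vector of the same length and names.
#' @export
standardize_metric <- function(x) {
  defined <- x[!is.na(x)]
  if (length(defined) < 2L)
    stop("degenerate feature: fewer than 2 defined values")
  s <- stats::sd(defined)
  if (!is.finite(s) || s == 0)
    stop("degenerate feature: zero spread")
  (x - mean(defined)) / s
}

#' Raw feature scores to standardized metric
#'
#' Convenience wrapper chaining [tail_logratio()] (training fractions from
#' the training genes' own raw scores, background fractions from all scored
#' genes) and [standardize_metric()].
#'
#' @param raw Named numeric vector of raw scores over all genes (`NA` marks
#'   genes missing from the knowledge source).
#' @param training Character vector of training gene symbols.
#' @return Named numeric vector of standardized scores; `NA` propagates.
#' @export
feature_standard_score <- function(raw, training) {
  stopifnot(!is.null(names(raw)))
  tr <- raw[names(raw) %in% training]
  standardize_metric(tail_logratio(raw, tr, raw))
}

#' Compose feature scores into the composite pathogenicity score
#'
#' The composite is the mean of the available (non-missing) standardized
#' feature scores of each gene; genes with no feature defined in any source
#' receive a composite of exactly 0.
#'
#' @param features Data.frame with a `gene` column and one numeric column
#'   per feature (`NA` marks missing).
#' @return The input with a `composite` column appended.
#' @export
compose_scores <- function(features) {
  stopifnot(is.data.frame(features), "gene" %in% names(features))
  cols <- setdiff(names(features), "gene")
  if (length(cols) == 0L) stop("no feature columns")
  m <- as.matrix(features[cols])
  n_avail <- rowSums(!is.na(m))
  composite <- ifelse(n_avail == 0L, 0, rowMeans(m, na.rm = TRUE))
  features$composite <- as.numeric(composite)
  features
}

#' Configuration of the scoring pipeline
#'
#' @param thresholds Either a single [enrichment_thresholds()] applied to
#'   every annotation system or a named list keyed by system name.
#' @param q Fraction of tissues per side of the expression contrast.
#' @param min_tissues Floor on tissues per contrast side.
#' @param max_len Maximum walk length for network communicability.
#' @return List of class `score_config`.
#' @export
score_config <- function(thresholds = enrichment_thresholds(), q = 0.1,
                         min_tissues = 3L, max_len = 6L) {
  structure(list(thresholds = thresholds, q = q,
                 min_tissues = min_tissues, max_len = max_len),
            class = "score_config")
}

# A feature whose metric has no spread (e.g. no category passed the
# enrichment thresholds, so every gene scores alike) carries no information;
# the pipeline marks it missing for every gene rather than aborting.
feature_or_missing <- function(raw, training, feature, genes) {
  tryCatch(feature_standard_score(raw, training),
           error = function(e) {
             warning("feature '", feature, "' is degenerate (",
                     conditionMessage(e), "); treated as missing",
                     call. = FALSE)
             stats::setNames(rep(NA_real_, length(genes)), genes)
           })
}

system_thresholds <- function(config, name) {
  th <- config$thresholds
  if (inherits(th, "enrichment_thresholds")) return(th)
  if (!is.null(th[[name]])) return(th[[name]])
  enrichment_thresholds()
}

#' Genome-wide composite pathogenicity scores
#'
#' Runs the full stage-one pipeline: for every annotation system, enriched
#' categories are selected against the training set and genes receive
#' additive match scores; the expression feature contrasts
#' training-selected high vs low tissues; the interaction feature sums
#' truncated communicability to the training genes. Every raw feature is
#' turned into the standardized tail log-ratio metric, and the composite is
#' the mean of the available features.
#'
#' @param knowledge List with elements `systems` (named list of
#'   [annotation_system()]), `expression` (gene x tissue matrix),
#'   `network` ([ppi_network()]) and optionally `genes`, the master gene
#'   list (defaults to the union of all sources).
#' @param training Character vector of training gene symbols.
#' @param config A [score_config()].
#' @param G Optional precomputed communicability matrix for
#'   `knowledge$network` (it does not depend on the training set, so
#'   cross-validation reuses it).
#' @return Data.frame with columns `gene`, one standardized score per
#'   feature (`NA` = missing) and `composite`.
#' @export
pathogenicity_scores <- function(knowledge, training,
                                 config = score_config(), G = NULL) {
  genes <- knowledge$genes
  if (is.null(genes)) {
    genes <- unique(c(
      unlist(lapply(knowledge$systems, `[[`, "universe"), use.names = FALSE),
      rownames(knowledge$expression),
      knowledge$network$nodes))
  }
  training <- unique(as.character(training))
  features <- data.frame(gene = genes, stringsAsFactors = FALSE)

  for (nm in names(knowledge$systems)) {
    sys <- knowledge$systems[[nm]]
    enr <- select_enriched_categories(sys, training,
                                      system_thresholds(config, nm))
    raw <- annotation_match_scores(genes, sys, enr)
    features[[nm]] <- feature_or_missing(raw, training, nm, genes)
  }

  if (!is.null(knowledge$expression)) {
    contrast <- select_contrast_tissues(knowledge$expression, training,
                                        q = config$q,
                                        min_tissues = config$min_tissues)
    raw <- expression_tstats(genes, knowledge$expression, contrast)
    features$expression <- feature_or_missing(raw, training, "expression",
                                              genes)
  }

  if (!is.null(knowledge$network)) {
    if (is.null(G))
      G <- truncated_communicability(knowledge$network, config$max_len)
    raw <- communicability_scores(genes, G, training)
    features$ppi <- feature_or_missing(raw, training, "ppi", genes)
  }

  compose_scores(features)
}

#' Write a score table as TSV
#'
#' Missing feature entries are rendered as `"-"`, mirroring the dash
#' convention of published score tables.
#'
#' @param scores Data.frame from [pathogenicity_scores()].
#' @param path Output file path.
#' @export
write_score_table <- function(scores, path) {
  out <- scores
  for (nm in setdiff(names(out), "gene"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "-",
                        formatC(out[[nm]], digits = 6, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path TSV path.
#' @return Data.frame with `NA` restored for `"-"` entries.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "-", check.names = FALSE)
  for (nm in setdiff(names(df), "gene")) df[[nm]] <- as.numeric(df[[nm]])
  df
}
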
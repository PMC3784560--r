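#' Construct an annotation system
#'
#' An annotation system is a named collection of categories (gene sets) over a
#' declared gene universe, e.g. a GO-like ontology, a mouse-phenotype mapping,
#' a pathway database or a miRNA-target table treated as flat sets.
#'
#' @param name Text label for the system (e.g. `"go"`, `"mgi"`).
#' @param categories Named list; each element a character vector of gene
#'   symbols. Duplicates within a category are removed.
#' @param universe Character vector of gene symbols the system covers. When
#'   `NULL`, the union of all category members is used. Every gene appearing
#'   in a category must be in the universe.
#' @return An object of class `annotation_system` with elements `name`,
#'   `categories` (list of character vectors) and `universe`.
#' @export
annotation_system <- function(name, categories, universe = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(categories) == 0L)
    stop("annotation system '", name, "' has no categories")
  if (is.null(names(categories)) || anyNA(names(categories)) ||
      any(names(categories) == ""))
    stop("categories must be named")
  categories <- lapply(categories, function(g) unique(as.character(g)))
  if (any(lengths(categories) == 0L))
    stop("categories must be non-empty")
  members <- unique(unlist(categories, use.names = FALSE))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- unique(as.character(universe))
    missing <- setdiff(members, universe)
    if (length(missing))
      stop("genes outside the declared universe: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(name = name, categories = categories, universe = universe),
            class = "annotation_system")
}

#' @export
print.annotation_system <- function(x, ...) {
  cat(sprintf("annotation_system '%s': %d categories over %d genes\n",
              x$name, length(x$categories), length(x$universe)))
  invisible(x)
}

#' Enrichment thresholds for category selection
#'
#' Cut-offs applied when selecting categories enriched in the training set.
#' Defaults are deliberately conservative and can be set per system.
#'
#' @param max_p Maximum one-sided hypergeometric p-value.
#' @param min_odds_ratio Minimum odds ratio from the 2x2 membership table.
#' @param min_training Minimum number of training genes annotated.
#' @return A list with class `enrichment_thresholds`.
#' @export
enrichment_thresholds <- function(max_p = 0.01, min_odds_ratio = 2,
                                  min_training = 2) {
  stopifnot(max_p > 0, max_p <= 1, min_odds_ratio >= 0, min_training >= 0)
  structure(list(max_p = max_p, min_odds_ratio = min_odds_ratio,
                 min_training = min_training),
            class = "enrichment_thresholds")
}

#' Select categories enriched among training genes
#'
#' Tests every category of an annotation system for over-representation of
#' the training genes by the one-sided hypergeometric (Fisher) upper tail,
#' and keeps categories passing the p-value, odds-ratio and
#' training-gene-count thresholds. Each selected category carries a weight
#' `-log(p)` used downstream in match scoring.
#'
#' The odds ratio comes from the 2x2 table (in category vs not, training vs
#' not) with a Haldane 0.5 correction applied to all cells whenever any cell
#' is zero. A degenerate category equal to the whole universe is excluded
#' with a warning: its odds ratio is undefined.
#'
#' @param system An [annotation_system()].
#' @param training Character vector of training gene symbols; intersected
#'   with the system universe before testing.
#' @param thresholds An [enrichment_thresholds()] object.
#' @return A data.frame with columns `category`, `p_value`, `odds_ratio`,
#'   `n_training`, `weight`, one row per selected category, ordered by
#'   increasing p-value.
#' @export
select_enriched_categories <- function(system, training,
                                       thresholds = enrichment_thresholds()) {
  stopifnot(inherits(system, "annotation_system"))
  training <- intersect(unique(as.character(training)), system$universe)
  N <- length(system$universe)
  if (N < 2L)
    stop("universe of system '", system$name, "' has fewer than 2 genes")
  if (length(training) == 0L)
    stop("no training gene is covered by annotation system '",
         system$name, "'")
  K <- length(training)

  n_cat <- lengths(system$categories)
  k_cat <- vapply(system$categories,
                  function(g) length(intersect(g, training)), integer(1))

  whole <- n_cat == N
  if (any(whole)) {
    warning("excluding ", sum(whole), " category(ies) equal to the whole ",
            "universe in system '", system$name, "' (odds ratio undefined)")
  }

  # upper-tail P(X >= k) for X ~ Hypergeom(N, K, n)
  p <- stats::phyper(k_cat - 1L, K, N - K, n_cat, lower.tail = FALSE)
  p <- pmin(p, 1)

  or <- mapply(function(k, n) {
    a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
    if (any(c(a, b, c, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    (a * d) / (b * c)
  }, k_cat, n_cat)

  keep <- !whole &
    p <= thresholds$max_p &
    or >= thresholds$min_odds_ratio &
    k_cat >= thresholds$min_training

  out <- data.frame(
    category = names(system$categories)[keep],
    p_value = p[keep],
    odds_ratio = or[keep],
    n_training = k_cat[keep],
    weight = -log(p[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Additive annotation match score
#'
#' Scores genes against an enriched-category table: each gene receives the
#' sum of `-log(p)` weights over the enriched categories that contain it.
#' Genes absent from the system's universe receive `NA` (missing), not zero
#' — absence of evidence is not evidence of absence. Genes in the universe
#' but in no enriched category receive 0.
#'
#' @param genes Character vector of genes to score.
#' @param system The [annotation_system()] the enrichment was computed on.
#' @param enriched Data.frame from [select_enriched_categories()].
#' @return Named numeric vector over `genes`; `NA` marks genes outside the
#'   system universe.
#' @export
annotation_match_scores <- function(genes, system, enriched) {
  stopifnot(inherits(system, "annotation_system"))
  genes <- as.character(genes)
  score <- stats::setNames(rep(NA_real_, length(genes)), genes)
  covered <- genes %in% system$universe
  score[covered] <- 0
  if (nrow(enriched)) {
    bad <- setdiff(enriched$category, names(system$categories))
    if (length(bad))
      stop("enriched categories not present in system '", system$name, "'")
    for (i in seq_len(nrow(enriched))) {
      memb <- genes %in% system$categories[[enriched$category[i]]]
      score[memb & covered] <- score[memb & covered] + enriched$weight[i]
    }
  }
  score
}
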
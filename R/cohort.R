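#' Filter CNV calls to likely true positives
#'
#' Keeps calls spanning less than `max_span` bases, supported by at least
#' `min_probes` variant probes, and with a mean log2 ratio beyond the
#' type-consistent threshold: deletions must satisfy
#' `mean_log2 < del_log2`, duplications `mean_log2 > dup_log2`. A call
#' labelled deletion with a positive ratio (or vice versa) is rejected.
#' The filter is idempotent.
#'
#' @param calls Data.frame of CNV calls with columns `subject`, `cohort`,
#'   `chrom`, `start`, `end` (1-based closed), `type`
#'   (`"deletion"`/`"duplication"`), `n_probes`, `mean_log2`.
#' @param max_span Maximum interval span in bases (default 15 Mb).
#' @param min_probes Minimum variant probe count (default 4).
#' @param del_log2 Deletion log2-ratio threshold (default -0.3).
#' @param dup_log2 Duplication log2-ratio threshold (default 0.21).
#' @return The surviving rows of `calls`.
#' @export
filter_calls <- function(calls, max_span = 15e6, min_probes = 4L,
                         del_log2 = -0.3, dup_log2 = 0.21) {
  stopifnot(all(c("start", "end", "type", "n_probes", "mean_log2") %in%
                  names(calls)))
  keep <- (calls$end - calls$start) < max_span &
    calls$n_probes >= min_probes &
    ifelse(calls$type == "deletion",
           calls$mean_log2 < del_log2,
           calls$mean_log2 > dup_log2)
  calls[keep, , drop = FALSE]
}

calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start, calls$end))
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         gene = genes$gene)
}

#' Genes overlapping a CNV interval
#'
#' A gene is reported when any part of its annotated span intersects the
#' call's probe-bounded minimum interval by at least one base on the same
#' chromosome.
#'
#' @param call Single-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param genes Gene models data.frame with `gene`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @return Character vector of gene symbols.
#' @export
genes_in_interval <- function(call, genes) {
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(call$chrom,
                           IRanges::IRanges(call$start, call$end)),
    genes_granges(genes))
  unique(genes$gene[S4Vectors::subjectHits(hits)])
}

#' Map filtered calls to the genes they hit
#'
#' @param calls Filtered CNV calls.
#' @param genes Gene models data.frame.
#' @return Data.frame with one row per (call, gene) overlap: `subject`,
#'   `cohort`, `type`, `gene`.
#' @export
call_gene_hits <- function(calls, genes) {
  if (nrow(calls) == 0L)
    return(data.frame(subject = character(), cohort = character(),
                      type = character(), gene = character(),
                      stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(calls_granges(calls),
                                      genes_granges(genes))
  i <- S4Vectors::queryHits(hits)
  data.frame(subject = calls$subject[i],
             cohort = calls$cohort[i],
             type = calls$type[i],
             gene = genes$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Distinct-subject deletion counts per gene
#'
#' For every gene model, counts the number of distinct subjects in the
#' requested cohort carrying at least one deletion call overlapping the
#' gene. A subject with several overlapping deletions counts once;
#' duplications never contribute.
#'
#' @param calls Filtered CNV calls.
#' @param genes Gene models data.frame.
#' @param cohort Cohort label to count; `NULL` pools all cohorts.
#' @return Named integer vector over all genes in `genes` (zeros included).
#' @export
gene_deletion_counts <- function(calls, genes, cohort = NULL) {
  sel <- calls$type == "deletion"
  if (!is.null(cohort)) sel <- sel & calls$cohort == cohort
  hits <- call_gene_hits(calls[sel, , drop = FALSE], genes)
  out <- stats::setNames(integer(nrow(genes)), genes$gene)
  if (nrow(hits)) {
    hits <- unique(hits[c("subject", "gene")])
    tab <- table(hits$gene)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Per-gene frequency records from two cohorts
#'
#' Assembles the per-gene case/background deletion-count table consumed by
#' [bayes_factor_table()]. Cohort sizes are passed explicitly because
#' frequency cohorts include subjects without any surviving call.
#'
#' @param calls Filtered CNV calls for both cohorts.
#' @param genes Gene models data.frame.
#' @param n_case,n_bg Cohort sizes (numbers of subjects).
#' @param case_label,bg_label Cohort labels in `calls`.
#' @return Data.frame with `gene`, `k_case`, `n_case`, `k_bg`, `n_bg`.
#' @export
gene_frequency_records <- function(calls, genes, n_case, n_bg,
                                   case_label = "case",
                                   bg_label = "background") {
  k_case <- gene_deletion_counts(calls, genes, case_label)
  k_bg <- gene_deletion_counts(calls, genes, bg_label)
  data.frame(gene = genes$gene,
             k_case = as.integer(k_case[genes$gene]),
             n_case = n_case,
             k_bg = as.integer(k_bg[genes$gene]),
             n_bg = n_bg,
             stringsAsFactors = FALSE)
}

#' Per-subject maximum pathogenicity score
#'
#' The highest composite pathogenicity score among genes hit by each
#' subject's surviving calls of the requested type. Subjects with no
#' surviving call of that type are omitted (they carry no information for
#' the comparison). Training genes can be excluded to test whether a
#' difference persists beyond already-known genes.
#'
#' @param calls Filtered CNV calls.
#' @param genes Gene models data.frame.
#' @param scores Named numeric vector of composite scores (or score table
#'   data.frame with `gene` and `composite`).
#' @param cnv_type `"deletion"`, `"duplication"` or `"both"`.
#' @param exclude_genes Genes removed from consideration (e.g. training
#'   genes).
#' @return Named numeric vector, one entry per subject with data.
#' @export
subject_max_pathogenicity <- function(calls, genes, scores,
                                      cnv_type = c("deletion", "duplication",
                                                   "both"),
                                      exclude_genes = NULL) {
  cnv_type <- match.arg(cnv_type)
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$composite, scores$gene)
  if (cnv_type != "both")
    calls <- calls[calls$type == cnv_type, , drop = FALSE]
  hits <- call_gene_hits(calls, genes)
  if (!is.null(exclude_genes))
    hits <- hits[!(hits$gene %in% exclude_genes), , drop = FALSE]
  hits$score <- scores[hits$gene]
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  vapply(split(hits$score, hits$subject), max, numeric(1))
}

#' Leave-one-subject-out Bayes factors for one subject
#'
#' Recomputes Bayes factors for the genes deleted in a subject after
#' removing the subject's own contribution to the case frequency data (a
#' subject contributes at most 1 to each gene's distinct-subject count).
#' Genes with corrected Bayes factor > 1 are returned sorted in decreasing
#' order, retaining the top `n_top`.
#'
#' @param subject_genes Genes deleted in the subject (to be scored).
#' @param records Global frequency records (see
#'   [gene_frequency_records()]).
#' @param scores Composite scores (named vector or score table).
#' @param config A [bayes_config()].
#' @param contributes Genes whose `k_case` includes this subject; empty for
#'   subjects outside the case frequency cohort.
#' @param n_top Number of top genes retained (default 3).
#' @return List with `top_genes` (data.frame `gene`, `bayes_factor`) and
#'   `max_bf` (1 when no gene exceeds 1).
#' @export
loo_subject_bayes_factors <- function(subject_genes, records, scores,
                                      config = bayes_config(),
                                      contributes = character(),
                                      n_top = 3L) {
  subject_genes <- unique(as.character(subject_genes))
  if (is.null(config$pseudo_rate)) {
    # the pseudo-rate is a cohort-wide quantity; pin it before scoring a
    # gene subset so it does not shift with the subset's minimum
    bg <- records$k_bg / records$n_bg
    nz <- bg[bg > 0]
    if (length(nz))
      config$pseudo_rate <- config$pseudo_fraction * min(nz)
  }
  rows <- records[records$gene %in% subject_genes, , drop = FALSE]
  if (nrow(rows) == 0L)
    return(list(top_genes = data.frame(gene = character(),
                                       bayes_factor = numeric()),
                max_bf = 1))
  dec <- rows$gene %in% contributes
  if (any(rows$k_case[dec] < 1L))
    stop("leave-one-out bookkeeping violation: k_case would drop below 0")
  rows$k_case[dec] <- rows$k_case[dec] - 1L
  bt <- bayes_factor_table(rows, scores, config)
  bt <- bt[bt$bayes_factor > 1, , drop = FALSE]
  bt <- bt[order(-bt$bayes_factor, bt$gene), , drop = FALSE]
  top <- utils::head(bt[c("gene", "bayes_factor")], n_top)
  list(top_genes = top,
       max_bf = if (nrow(top)) top$bayes_factor[1L] else 1)
}

#' Per-subject Bayes-factor loads across an analysis cohort
#'
#' Applies [loo_subject_bayes_factors()] to every subject with at least one
#' surviving deletion call. Subjects listed in `frequency_subjects` have
#' their own contribution removed from the case counts before scoring.
#'
#' @param calls Filtered CNV calls for the analysis cohorts.
#' @param genes Gene models data.frame.
#' @param records Global frequency records.
#' @param scores Composite scores.
#' @param config A [bayes_config()].
#' @param frequency_subjects Subjects that are also members of the case
#'   frequency cohort (their contribution is removed).
#' @param exclude_genes Genes removed before ranking (e.g. training genes).
#' @return Data.frame: `subject`, `cohort`, `max_bf`, `bf2`, `bf3` (1 when
#'   absent), `gene1`, `gene2`, `gene3` (`NA` when absent).
#' @export
subject_bayes_loads <- function(calls, genes, records, scores,
                                config = bayes_config(),
                                frequency_subjects = character(),
                                exclude_genes = NULL) {
  hits <- call_gene_hits(calls[calls$type == "deletion", , drop = FALSE],
                         genes)
  if (!is.null(exclude_genes))
    hits <- hits[!(hits$gene %in% exclude_genes), , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(subject = character(), cohort = character(),
                      max_bf = numeric(), bf2 = numeric(), bf3 = numeric(),
                      gene1 = character(), gene2 = character(),
                      gene3 = character(), stringsAsFactors = FALSE))
  cohort_of <- tapply(hits$cohort, hits$subject, `[`, 1L)
  per_subject <- split(hits$gene, hits$subject)
  rows <- lapply(names(per_subject), function(s) {
    gset <- unique(per_subject[[s]])
    contributes <- if (s %in% frequency_subjects) gset else character()
    load <- loo_subject_bayes_factors(gset, records, scores, config,
                                      contributes = contributes)
    tg <- load$top_genes
    bf <- c(tg$bayes_factor, rep(1, 3L))[1:3]
    gn <- c(tg$gene, rep(NA_character_, 3L))[1:3]
    data.frame(subject = s, cohort = unname(cohort_of[s]),
               max_bf = bf[1L], bf2 = bf[2L], bf3 = bf[3L],
               gene1 = gn[1L], gene2 = gn[2L], gene3 = gn[3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank-based comparison of two cohorts
#'
#' Unpaired two-sample rank-sum (Mann-Whitney) test of a location shift
#' between cohorts. When every value is tied across both groups there is
#' no shift to detect and p = 1 is returned with a warning.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (`"greater"` tests whether `values_a` is shifted above `values_b`).
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
compare_cohorts <- function(values_a, values_b,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values tied across both cohorts; p = 1")
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
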
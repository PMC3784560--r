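#' Select contrast tissues from training-gene expression
#'
#' Ranks tissues by the mean of the training genes' z-scored expression
#' (each gene standardized across tissues so highly expressed genes do not
#' dominate the ranking) and returns the top fraction as "high" tissues and
#' the bottom fraction as "low" tissues. Ties in the ranking are broken by
#' lexicographic tissue label so the result is deterministic.
#'
#' @param expr Numeric matrix, genes in rows (rownames = symbols), tissues
#'   in columns (colnames = labels). `NA` entries permitted.
#' @param training Character vector of training gene symbols; must overlap
#'   the matrix rows.
#' @param q Fraction of tissues on each side; the number of tissues per side
#'   is `max(min_tissues, ceiling(q * n_tissues))`, capped at half the
#'   tissues.
#' @param min_tissues Floor on the number of tissues per side.
#' @return List with character elements `high_tissues` and `low_tissues`
#'   (disjoint, each non-empty).
#' @export
select_contrast_tissues <- function(expr, training, q = 0.1,
                                    min_tissues = 3L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (ncol(expr) < 2L) stop("need at least 2 tissues")
  stopifnot(q > 0, q <= 0.5)
  training <- intersect(unique(as.character(training)), rownames(expr))
  if (length(training) == 0L)
    stop("no training gene present in the expression matrix")

  tr <- expr[training, , drop = FALSE]
  z <- t(apply(tr, 1L, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mean(v, na.rm = TRUE)) / s
  }))
  tissue_mean <- colMeans(z, na.rm = TRUE)

  n_side <- min(max(as.integer(min_tissues), ceiling(q * ncol(expr))),
                floor(ncol(expr) / 2))
  if (n_side < 1L) stop("too few tissues for the requested contrast")

  ord <- order(-tissue_mean, colnames(expr))       # ties: label order
  labels <- colnames(expr)[ord]
  list(high_tissues = labels[seq_len(n_side)],
       low_tissues = rev(labels)[seq_len(n_side)])
}

#' Tissue-contrast expression statistic
#'
#' Welch-type statistic contrasting each gene's expression in the high
#' tissues against the low tissues:
#' `(mean_high - mean_low) / sqrt(s2_high/n_high + s2_low/n_low)`.
#' The denominator is floored to keep the statistic finite for genes with
#' constant expression. Genes absent from the matrix score `NA` (missing).
#'
#' @param genes Character vector of genes to score.
#' @param expr Expression matrix as in [select_contrast_tissues()].
#' @param contrast List with `high_tissues` and `low_tissues`.
#' @param var_floor Floor applied to the denominator before division.
#' @return Named numeric vector over `genes`, `NA` for genes not in `expr`.
#' @export
expression_tstats <- function(genes, expr, contrast, var_floor = 1e-8) {
  stopifnot(is.matrix(expr))
  hi <- contrast$high_tissues
  lo <- contrast$low_tissues
  stopifnot(length(hi) >= 1L, length(lo) >= 1L,
            length(intersect(hi, lo)) == 0L,
            all(c(hi, lo) %in% colnames(expr)))
  genes <- as.character(genes)
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  present <- genes %in% rownames(expr)
  if (!any(present)) return(out)

  xh <- expr[genes[present], hi, drop = FALSE]
  xl <- expr[genes[present], lo, drop = FALSE]
  mh <- rowMeans(xh, na.rm = TRUE)
  ml <- rowMeans(xl, na.rm = TRUE)
  vh <- apply(xh, 1L, stats::var, na.rm = TRUE)
  vl <- apply(xl, 1L, stats::var, na.rm = TRUE)
  vh[!is.finite(vh)] <- 0
  vl[!is.finite(vl)] <- 0
  nh <- rowSums(!is.na(xh))
  nl <- rowSums(!is.na(xl))
  denom <- sqrt(pmax(vh / pmax(nh, 1L) + vl / pmax(nl, 1L), var_floor))
  out[present] <- (mh - ml) / denom
  out
}
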
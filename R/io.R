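#' Read an annotation system from a GMT file
#'
#' GMT (gene matrix transposed): one category per line — identifier,
#' description, then member gene symbols, tab-separated. Duplicate symbols
#' within a line are removed. The universe defaults to the union of
#' members.
#'
#' @param path GMT file path.
#' @param name System label; defaults to the file name without extension.
#' @param universe Optional explicit gene universe.
#' @return An [annotation_system()].
#' @export
read_gmt <- function(path, name = NULL, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  categories <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": need at least 3 tab-separated fields")
    categories[[f[1L]]] <- unique(f[-(1:2)])
  }
  annotation_system(name, categories, universe)
}

#' Write an annotation system to a GMT file
#' @param system An [annotation_system()].
#' @param path Output path.
#' @export
write_gmt <- function(system, path) {
  stopifnot(inherits(system, "annotation_system"))
  lines <- vapply(names(system$categories), function(id) {
    paste(c(id, id, system$categories[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a training gene list (one symbol per line)
#' @param path File path.
#' @return Character vector of unique symbols.
#' @export
read_training_genes <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}

#' Read a gene x tissue expression matrix from TSV
#'
#' First column gene symbol, header row of tissue labels; empty cells are
#' missing values.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (anyDuplicated(df[[1L]])) stop("duplicate gene symbols in ", path)
  m <- as.matrix(df[-1L])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction network from a TSV edge list
#'
#' Two symbol columns; extra columns are ignored. The node universe is the
#' union of endpoints.
#'
#' @param path TSV path (header expected).
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least 2 columns: ", path)
  ppi_network(df[, 1:2])
}

#' Write a network as a TSV edge list
#' @param network A [ppi_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  df <- data.frame(gene_a = network$edges[, 1L],
                   gene_b = network$edges[, 2L], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-subject CNV calls from TSV
#'
#' Required columns: `subject`, `cohort`, `chrom`, `start`, `end`, `type`,
#' `n_probes`, `mean_log2`. Coordinates are normalized to 1-based closed
#' intervals: the `"bed"` dialect (0-based half-open) has 1 added to
#' `start`. Types are parsed case-insensitively; `del`/`deletion` and
#' `dup`/`duplication` are accepted.
#'
#' @param path TSV path.
#' @param dialect `"closed"` (1-based closed, default) or `"bed"`.
#' @return Data.frame of calls with normalized coordinates.
#' @export
read_cnv_table <- function(path, dialect = c("closed", "bed")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "cohort", "chrom", "start", "end", "type",
            "n_probes", "mean_log2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CNV table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  if (dialect == "bed") df$start <- df$start + 1L
  ty <- tolower(df$type)
  ty[ty == "del"] <- "deletion"
  ty[ty == "dup"] <- "duplication"
  bad <- which(!(ty %in% c("deletion", "duplication")))
  if (length(bad))
    stop("unknown CNV type at row ", bad[1L], ": ", df$type[bad[1L]])
  df$type <- ty
  bad <- which(df$start < 1 | df$end < df$start)
  if (length(bad))
    stop("invalid coordinates at row ", bad[1L])
  df$subject <- as.character(df$subject)
  df
}

#' Write CNV calls as TSV (1-based closed coordinates)
#' @param calls CNV call data.frame.
#' @param path Output path.
#' @export
write_cnv_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED
#'
#' BED is 0-based half-open with no header (chrom, start, end, name);
#' coordinates are converted to 1-based closed.
#'
#' @param path BED path.
#' @return Data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("gene BED needs 4 columns: ", path)
  out <- data.frame(gene = df[[4L]], chrom = df[[1L]],
                    start = df[[2L]] + 1L, end = df[[3L]],
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("invalid gene interval in ", path)
  out
}

#' Write gene models as BED
#' @param genes Data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   closed).
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Single source of truth for every tunable threshold of the pipeline, with
#' the published operating values as defaults: 15 Mb maximum call span, at
#' least 4 variant probes, log2-ratio cutoffs of -0.3 (deletions) and 0.21
#' (duplications), walk length 6 for communicability, and a pseudo-rate of
#' one quarter of the lowest observed background rate.
#'
#' @param score A [score_config()].
#' @param bayes A [bayes_config()].
#' @param max_span,min_probes,del_log2,dup_log2 Call-filter settings (see
#'   [filter_calls()]).
#' @param seed Master seed for any randomized step.
#' @return List of class `run_config`.
#' @export
run_config <- function(score = score_config(), bayes = bayes_config(),
                       max_span = 15e6, min_probes = 4L,
                       del_log2 = -0.3, dup_log2 = 0.21, seed = 1L) {
  structure(list(score = score, bayes = bayes, max_span = max_span,
                 min_probes = min_probes, del_log2 = del_log2,
                 dup_log2 = dup_log2, seed = seed),
            class = "run_config")
}
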
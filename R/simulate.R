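# Independent pseudo-random substreams per component so regenerating one
# input does not perturb the others. Derived seeds stay below 2^31.
substream_seed <- function(seed, k) {
  (abs(as.numeric(seed)) * 7 + k * 104729) %% 2147483629
}

#' Configuration of the synthetic-data generator
#'
#' Defaults describe a desk-scale study with the statistical structure the
#' scoring method assumes: training genes over-represented in designated
#' annotation categories, elevated in designated tissues, preferentially
#' interconnected in the interaction network, and a few planted risk genes
#' deleted more often in case subjects.
#'
#' @param seed Master seed; fully determines every generated input.
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_training Number of training genes.
#' @param systems List: `names` (system labels), `n_categories`,
#'   `size_range` (category size bounds), `n_signal` (categories enriched
#'   for training genes), `signal_odds` (sampling odds multiplier for
#'   training genes in signal categories; 1 = no signal), `coverage`
#'   (fraction of genes covered by each system).
#' @param expression List: `n_tissues`, `n_elevated` (tissues where
#'   training genes are elevated), `effect` (mean shift in those tissues;
#'   0 = no signal), `noise_sd`, `coverage`.
#' @param network List: `p_edge` (baseline edge probability),
#'   `p_training` (edge probability between training genes; equal to
#'   `p_edge` = no signal), `coverage`.
#' @param cohorts List: `n_case`, `n_bg`, `base_rate` (per-subject
#'   per-gene deletion probability), `n_risk` (planted risk genes, drawn
#'   from the training set), `risk_multiplier` (deletion-rate multiplier in
#'   case subjects; 1 = null), `dup_fraction` (expected fraction of calls
#'   that are duplications), `fail_probes`, `fail_log2`, `fail_span`
#'   (fractions of calls constructed to fail each filter rule).
#' @param genome List: `n_chrom`, `gene_length`, `gene_gap` (bases).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 500L,
    n_training = 25L,
    systems = list(),
    expression = list(),
    network = list(),
    cohorts = list(),
    genome = list()) {
  systems <- utils::modifyList(list(
    names = c("go", "mgi", "kegg", "mirna"),
    n_categories = 40L, size_range = c(10L, 50L),
    n_signal = 10L, signal_odds = 8, coverage = 0.9), systems)
  expression <- utils::modifyList(list(
    n_tissues = 25L, n_elevated = 4L, effect = 2, noise_sd = 1,
    coverage = 0.9), expression)
  network <- utils::modifyList(list(
    p_edge = 0.01, p_training = 0.35, coverage = 0.9), network)
  cohorts <- utils::modifyList(list(
    n_case = 2000L, n_bg = 2000L, base_rate = 0.5e-3,
    n_risk = 3L, risk_multiplier = 20,
    dup_fraction = 0.3, fail_probes = 0.05, fail_log2 = 0.05,
    fail_span = 0.02), cohorts)
  genome <- utils::modifyList(list(
    n_chrom = 4L, gene_length = 2e4, gene_gap = 8e4), genome)

  stopifnot(n_genes > 0, n_training > 0, n_training < n_genes,
            systems$signal_odds >= 1,
            systems$coverage > 0, systems$coverage <= 1,
            network$p_edge >= 0, network$p_edge <= 1,
            cohorts$base_rate >= 0,
            cohorts$base_rate * cohorts$risk_multiplier <= 1,
            cohorts$risk_multiplier >= 1,
            cohorts$dup_fraction >= 0, cohorts$dup_fraction < 1)
  if (network$p_training > 1 || network$p_training < 0)
    stop("infeasible network config: training edge probability outside [0,1]")
  structure(list(seed = seed, n_genes = n_genes, n_training = n_training,
                 systems = systems, expression = expression,
                 network = network, cohorts = cohorts, genome = genome),
            class = "simulation_config")
}

gene_symbols <- function(n) sprintf("G%05d", seq_len(n))

#' Generate synthetic knowledge sources
#'
#' Draws four annotation systems, an expression matrix and an interaction
#' network over a common gene list, planting the training-set structure
#' configured in [simulation_config()]: training genes enter designated
#' "signal" categories with boosted sampling odds, are shifted upward in
#' designated tissues, and are preferentially interconnected. A configured
#' fraction of genes is absent from each source, exercising
#' missing-feature handling downstream.
#'
#' @param config A [simulation_config()].
#' @return List with `genes`, `training`, `systems` (named list of
#'   [annotation_system()]), `expression` (matrix) and `network`
#'   ([ppi_network()]); the layout [pathogenicity_scores()] consumes.
#' @export
simulate_knowledge <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- gene_symbols(config$n_genes)

  set.seed(substream_seed(config$seed, 1L))
  training <- sort(sample(genes, config$n_training))

  sy <- config$systems
  systems <- list()
  for (s in seq_along(sy$names)) {
    covered <- genes[stats::runif(length(genes)) < sy$coverage]
    covered <- union(covered, sample(training, 2L))  # keep system usable
    tr_in <- intersect(training, covered)
    categories <- list()
    for (ci in seq_len(sy$n_categories)) {
      size <- sample(seq(sy$size_range[1L], sy$size_range[2L]), 1L)
      size <- min(size, length(covered))
      w <- rep(1, length(covered))
      if (ci <= sy$n_signal)
        w[covered %in% tr_in] <- sy$signal_odds
      categories[[sprintf("%s_cat%03d", sy$names[s], ci)]] <-
        sample(covered, size, prob = w)
    }
    systems[[sy$names[s]]] <-
      annotation_system(sy$names[s], categories, universe = covered)
  }

  ex <- config$expression
  covered <- genes[stats::runif(length(genes)) < ex$coverage]
  covered <- union(covered, sample(training, 2L))
  tissues <- sprintf("T%02d", seq_len(ex$n_tissues))
  gene_mean <- stats::rnorm(length(covered), mean = 5, sd = 1)
  expr <- matrix(stats::rnorm(length(covered) * ex$n_tissues,
                              mean = gene_mean, sd = ex$noise_sd),
                 nrow = length(covered), ncol = ex$n_tissues,
                 dimnames = list(covered, tissues))
  elevated <- tissues[seq_len(ex$n_elevated)]
  tr_rows <- intersect(training, covered)
  expr[tr_rows, elevated] <- expr[tr_rows, elevated] + ex$effect

  net <- config$network
  set.seed(substream_seed(config$seed, 2L))
  nodes <- genes[stats::runif(length(genes)) < net$coverage]
  nodes <- union(nodes, sample(training, 2L))
  nodes <- sort(nodes)
  pair <- utils::combn(nodes, 2L)
  is_tr <- matrix(pair %in% training, nrow = 2L)
  p <- ifelse(colSums(is_tr) == 2L, net$p_training, net$p_edge)
  draw <- stats::runif(ncol(pair)) < p
  edges <- t(pair[, draw, drop = FALSE])
  network <- ppi_network(edges, nodes = nodes)

  list(genes = genes, training = training, systems = systems,
       expression = expr, network = network)
}

#' Lay out synthetic gene models
#'
#' Places genes sequentially along chromosomes with fixed length and
#' spacing, so extended deletion calls can span several neighbouring genes.
#'
#' @param config A [simulation_config()].
#' @return Data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   closed).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genome
  genes <- gene_symbols(config$n_genes)
  per_chrom <- ceiling(config$n_genes / g$n_chrom)
  chrom_idx <- rep(seq_len(g$n_chrom), each = per_chrom)[seq_len(config$n_genes)]
  pos_idx <- stats::ave(seq_len(config$n_genes), chrom_idx,
                        FUN = seq_along)
  start <- (pos_idx - 1L) * (g$gene_length + g$gene_gap) + 1
  data.frame(gene = genes, chrom = paste0("chr", chrom_idx),
             start = start, end = start + g$gene_length - 1,
             stringsAsFactors = FALSE)
}

simulate_cohort_calls <- function(cohort, n_subj, rate, gene_models, cfg) {
  n_genes <- nrow(gene_models)
  if (n_subj == 0L || all(rate == 0) && cfg$dup_fraction == 0)
    return(NULL)
  subj_ids <- sprintf("%s_%05d", cohort, seq_len(n_subj))

  dup_rate <- if (cfg$dup_fraction > 0)
    cfg$base_rate * cfg$dup_fraction / (1 - cfg$dup_fraction) else 0

  make_events <- function(per_gene_rate, type) {
    hit <- which(matrix(stats::runif(n_subj * n_genes), n_subj, n_genes) <
                   matrix(per_gene_rate, n_subj, n_genes, byrow = TRUE),
                 arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    gi <- hit[, 2L]
    n <- nrow(hit)
    # extend the probe-bounded interval beyond the gene; exponential tails
    # occasionally reach neighbouring genes, and a small fraction of calls
    # is made oversized to exercise the span filter
    mean_ext <- 0.4 * (cfg$gene_length + cfg$gene_gap)
    ext_l <- stats::rexp(n, rate = 1 / mean_ext)
    ext_r <- stats::rexp(n, rate = 1 / mean_ext)
    huge <- stats::runif(n) < cfg$fail_span
    ext_r[huge] <- ext_r[huge] + 16e6
    start <- pmax(1, round(gene_models$start[gi] - ext_l))
    end <- round(gene_models$end[gi] + ext_r)

    n_probes <- 4L + stats::rpois(n, 12)
    few <- stats::runif(n) < cfg$fail_probes
    n_probes[few] <- sample(1:3, sum(few), replace = TRUE)

    if (type == "deletion") {
      log2 <- stats::rnorm(n, -0.8, 0.15)
      shallow <- stats::runif(n) < cfg$fail_log2
      log2[shallow] <- stats::rnorm(sum(shallow), -0.2, 0.05)
    } else {
      log2 <- stats::rnorm(n, 0.6, 0.15)
      shallow <- stats::runif(n) < cfg$fail_log2
      log2[shallow] <- stats::rnorm(sum(shallow), 0.1, 0.05)
    }
    data.frame(subject = subj_ids[hit[, 1L]], cohort = cohort,
               chrom = gene_models$chrom[gi], start = start, end = end,
               type = type, n_probes = n_probes,
               mean_log2 = round(log2, 3), stringsAsFactors = FALSE)
  }
  rbind(make_events(rate, "deletion"),
        make_events(rep(dup_rate, n_genes), "duplication"))
}

#' Generate synthetic CNV call tables for case and background cohorts
#'
#' Each subject draws deletion events per gene region at the configured
#' baseline rate, multiplied for planted risk genes in case subjects only;
#' duplication events are phenotype-neutral. Calls carry probe counts and
#' mean log2 ratios sampled so a configured fraction fails each filter
#' rule.
#'
#' @param config A [simulation_config()].
#' @param gene_models Gene models from [simulate_gene_models()].
#' @param risk_genes Genes whose deletion rate is multiplied in case
#'   subjects.
#' @return Data.frame of CNV calls (possibly 0 rows) in the layout
#'   [filter_calls()] consumes.
#' @export
simulate_cohorts <- function(config, gene_models,
                             risk_genes = character()) {
  stopifnot(inherits(config, "simulation_config"))
  co <- config$cohorts
  set.seed(substream_seed(config$seed, 3L))
  cfg <- c(co, config$genome)

  base <- rep(co$base_rate, nrow(gene_models))
  case_rate <- base
  case_rate[gene_models$gene %in% risk_genes] <-
    co$base_rate * co$risk_multiplier

  calls <- rbind(
    simulate_cohort_calls("case", co$n_case, case_rate, gene_models, cfg),
    simulate_cohort_calls("background", co$n_bg, base, gene_models, cfg))
  if (is.null(calls))
    calls <- data.frame(subject = character(), cohort = character(),
                        chrom = character(), start = numeric(),
                        end = numeric(), type = character(),
                        n_probes = integer(), mean_log2 = numeric(),
                        stringsAsFactors = FALSE)
  calls
}

#' Generate a complete synthetic study
#'
#' Knowledge sources, gene models and cohort CNV calls from one master
#' seed. Risk genes are drawn from the training set (so the informed prior
#' has a positive score to act on).
#'
#' @param config A [simulation_config()].
#' @return List with `knowledge`, `gene_models`, `calls`, `training`,
#'   `risk_genes` and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  knowledge <- simulate_knowledge(config)
  gene_models <- simulate_gene_models(config)
  set.seed(substream_seed(config$seed, 4L))
  risk_genes <- sort(sample(knowledge$training,
                            min(config$cohorts$n_risk,
                                length(knowledge$training))))
  calls <- simulate_cohorts(config, gene_models, risk_genes)
  list(knowledge = knowledge, gene_models = gene_models, calls = calls,
       training = knowledge$training, risk_genes = risk_genes,
       config = config)
}

#' Write every synthetic input in its on-disk format
#'
#' Emits the exact file formats the readers consume: GMT per annotation
#' system, expression TSV, edge-list TSV, training gene list, gene-model
#' BED and CNV TSV.
#'
#' @param study A bundle from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(study$knowledge$systems)) {
    p <- file.path(dir, paste0(nm, ".gmt"))
    write_gmt(study$knowledge$systems[[nm]], p)
    paths[nm] <- p
  }
  paths["expression"] <- write_expression_tsv(
    study$knowledge$expression, file.path(dir, "expression.tsv"))
  paths["network"] <- write_edge_list(
    study$knowledge$network, file.path(dir, "ppi_edges.tsv"))
  paths["training"] <- file.path(dir, "training_genes.txt")
  writeLines(study$training, paths["training"])
  paths["genes"] <- write_gene_models(
    study$gene_models, file.path(dir, "gene_models.bed"))
  paths["calls"] <- write_cnv_table(
    study$calls, file.path(dir, "cnv_calls.tsv"))
  invisible(paths)
}
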
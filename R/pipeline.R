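# 32-bit FNV-1a over a string, done in 16-bit halves so products stay exact
# in doubles; used to fingerprint configs in every output.
fnv1a_hash <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- bitwXor_num(h, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0)  # low 31 bits, hex
}

bitwXor_num <- function(a, b) {
  # xor on doubles via 16-bit halves (bitwXor needs ints < 2^31)
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer((a %/% 65536) %% 65536), as.integer((b %/% 65536) %% 65536))
  hi * 65536 + lo
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' `counts` may be a [count_matrix()] or a TSV path written by
#' [write_counts()]; `gene_set` optionally restricts inference to a
#' membership list (a character vector or a one-gene-per-line file),
#' standing in for a pathway annotation subset.
#'
#' @param counts A [count_matrix()] or TSV path.
#' @param out_dir Output directory for all artifacts (created if needed).
#' @param gene_set Optional gene subset (character vector or file path).
#' @param alpha,fc_cut,use_adjusted DEG gates (see [classify_degs()]).
#' @param n_trees,threshold_mode,threshold_value Inference settings (see
#'   [genie3_importances()], [threshold_edges()]).
#' @param binarize_method,max_in_degree Boolean-model settings.
#' @param max_exhaustive_genes,perturb_mode Dynamics settings; perturbation
#'   sets are derived from DEG classes (up-regulated genes forced to 1,
#'   down-regulated to 0) unless `up_genes`/`down_genes` override them.
#' @param up_genes,down_genes Optional explicit perturbation sets.
#' @param betweenness_normalized,entropy_base Metric flags.
#' @param seed Master seed, recorded in every output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, out_dir, gene_set = NULL,
                            alpha = 0.05, fc_cut = 1.5, use_adjusted = FALSE,
                            n_trees = 1000,
                            threshold_mode = "top_k_per_target",
                            threshold_value = 2,
                            binarize_method = "kmeans2", max_in_degree = 3,
                            max_exhaustive_genes = 20,
                            perturb_mode = "clamp",
                            up_genes = NULL, down_genes = NULL,
                            betweenness_normalized = TRUE, entropy_base = "e",
                            seed = 1) {
  cfg <- list(counts = counts, out_dir = out_dir, gene_set = gene_set,
              alpha = alpha, fc_cut = fc_cut, use_adjusted = use_adjusted,
              n_trees = n_trees, threshold_mode = threshold_mode,
              threshold_value = threshold_value,
              binarize_method = binarize_method,
              max_in_degree = max_in_degree,
              max_exhaustive_genes = max_exhaustive_genes,
              perturb_mode = perturb_mode,
              up_genes = up_genes, down_genes = down_genes,
              betweenness_normalized = betweenness_normalized,
              entropy_base = entropy_base, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  c2 <- cfg
  c2$out_dir <- NULL                 # hash the analysis, not its location
  if (inherits(c2$counts, "count_matrix"))
    c2$counts <- list(dim = dim(c2$counts$counts),
                      sum = sum(c2$counts$counts))
  fnv1a_hash(jsonlite::toJSON(unclass(c2), auto_unbox = TRUE, force = TRUE))
}

#' Run the full counts-to-dynamics pipeline
#'
#' Executes, in order: size-factor normalization, moderated-t differential
#' expression with DEG classification, optional gene-set restriction,
#' random-forest network inference, edge thresholding, expression
#' binarization and best-fit Boolean rule learning, exhaustive baseline
#' attractor enumeration, a perturbation run forcing up-regulated DEGs to 1
#' and down-regulated DEGs to 0, and topology metrics of the thresholded
#' network. Every intermediate artifact is written to `cfg$out_dir`, and
#' each JSON output embeds the seed and config hash.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: list holding the in-memory stage outputs
#'   (`deg_table`, `graph_full`, `graph`, `network`, `states`,
#'   `attractors_baseline`, `attractors_perturbed`, `metrics`) plus summary
#'   counts, `seed`, `config_hash` and artifact `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  m <- stage("input", {
    if (inherits(cfg$counts, "count_matrix")) cfg$counts
    else read_counts(cfg$counts)
  })
  hash <- config_hash(cfg)
  pth <- function(f) file.path(cfg$out_dir, f)

  sf <- stage("preprocessing", size_factors(m))
  utils::write.table(data.frame(sample = names(sf), size_factor = sf),
                     pth("size_factors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  deg <- stage("diffexpr", classify_degs(moderated_t(m, sf),
                                         alpha = cfg$alpha, fc_cut = cfg$fc_cut,
                                         use_adjusted = cfg$use_adjusted))
  write_deg_table(deg, pth("deg_table.tsv"))

  gene_set <- cfg$gene_set
  if (is.character(gene_set) && length(gene_set) == 1 && file.exists(gene_set))
    gene_set <- readLines(gene_set)

  graph_full <- stage("grn_inference",
                      genie3_importances(m, candidates = gene_set,
                                         n_trees = cfg$n_trees,
                                         seed = cfg$seed, factors = sf))
  write_edges(graph_full, pth("edges_full.tsv"))
  graph <- stage("threshold",
                 threshold_edges(graph_full, mode = cfg$threshold_mode,
                                 value = cfg$threshold_value))
  write_edges(graph, pth("edges_thresholded.tsv"))

  states <- stage("binarize", binarize(m, sf, method = cfg$binarize_method))
  write_states(states, pth("binary_states.tsv"))
  net <- stage("boolean_model",
               build_boolean_model(graph, states,
                                   max_in_degree = cfg$max_in_degree))
  write_rules(net, pth("network_rules.txt"))
  network_to_json(net, pth("network.json"))

  att_base <- stage("dynamics",
                    enumerate_attractors(net, "exhaustive",
                                         cfg$max_exhaustive_genes))
  attractors_to_json(att_base, pth("attractors_baseline.json"))

  up <- if (is.null(cfg$up_genes)) deg$gene[deg$class == "up"] else cfg$up_genes
  down <- if (is.null(cfg$down_genes)) deg$gene[deg$class == "down"] else cfg$down_genes
  up <- intersect(up, net$genes); down <- intersect(down, net$genes)
  att_pert <- stage("perturb",
                    perturb(net, up, down, mode = cfg$perturb_mode,
                            max_exhaustive_genes = cfg$max_exhaustive_genes))
  attractors_to_json(att_pert, pth("attractors_perturbed.json"))

  metrics <- stage("net_metrics",
                   compute_metrics(graph,
                                   betweenness_normalized = cfg$betweenness_normalized,
                                   entropy_base = cfg$entropy_base))
  metrics_to_json(metrics, pth("metrics.json"))

  report <- list(
    n_genes = nrow(m$counts), n_samples = ncol(m$counts),
    deg_counts = as.list(table(factor(deg$class, c("up", "down", "ns")))),
    network_nodes = length(net$genes),
    network_edges = nrow(graph$edges),
    n_attractors_baseline = length(att_base$attractors),
    n_attractors_perturbed = length(att_pert$attractors),
    perturbed_up = up, perturbed_down = down,
    metrics = unclass(metrics),
    seed = cfg$seed, config_hash = hash,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    deg_table = deg, graph_full = graph_full, graph = graph,
    network = net, states = states,
    attractors_baseline = att_base, attractors_perturbed = att_pert,
    paths = list(out_dir = cfg$out_dir))
  class(report) <- "run_report"
  json <- report[c("n_genes", "n_samples", "deg_counts", "network_nodes",
                   "network_edges", "n_attractors_baseline",
                   "n_attractors_perturbed", "perturbed_up", "perturbed_down",
                   "metrics", "seed", "config_hash", "r_version")]
  json$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(json, pth("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d genes, %d samples; DEGs up/down = %d/%d\n",
              x$n_genes, x$n_samples, x$deg_counts$up, x$deg_counts$down))
  cat(sprintf("  network: %d nodes, %d edges; attractors baseline/perturbed = %d/%d\n",
              x$network_nodes, x$network_edges,
              x$n_attractors_baseline, x$n_attractors_perturbed))
  invisible(x)
}

# Canonical signature of an attractor projected onto a gene subset: the
# sorted set of projected bitstrings (a cycle is a set of states here).
attractor_signatures <- function(att, genes_subset) {
  idx <- match(genes_subset, att$genes)
  vapply(att$attractors, function(a) {
    proj <- vapply(a$states, function(s)
      paste(unpack_bits(s, length(att$genes))[idx], collapse = ""), character(1))
    paste(sort(unique(proj)), collapse = "|")
  }, character(1))
}

#' Score a pipeline run against the planted ground truth
#'
#' Three recovery scores for synthetic runs: `edge_aupr` (area under the
#' precision-recall curve of the full importance ranking against the
#' planted edge list, with `prevalence` as the no-skill baseline),
#' `rule_agreement` (mean over genes of the fraction of input combinations,
#' over the union of planted and fitted parents, on which the fitted rule
#' matches the planted rule), and `attractor_jaccard` (Jaccard index
#' between baseline attractor signatures of the fitted and planted
#' networks, projected onto their common genes).
#'
#' @param report A `run_report` from [run_pipeline()] or
#'   [report_from_truth()].
#' @param truth The [ground_truth()] that generated the data.
#' @return List with `edge_aupr`, `prevalence`, `rule_agreement`,
#'   `attractor_jaccard`.
#' @export
score_recovery <- function(report, truth) {
  stopifnot(inherits(report, "run_report"), inherits(truth, "ground_truth"))
  tnet <- truth$network
  if (!all(report$graph_full$nodes %in% tnet$genes))
    stop("report genes do not match the ground truth")
  er <- edge_recovery(report$graph_full, tnet)

  fitted <- report$network
  agree <- vapply(fitted$genes, function(g) {
    rel <- union(tnet$parents[[g]], fitted$parents[[g]])
    k <- length(rel)
    hits <- 0
    for (row in 0:(2^k - 1)) {
      bits <- if (k) as.integer(intToBits(row))[k:1] else integer(0)
      env <- stats::setNames(as.list(bits), rel)
      tv <- eval_table(tnet$parents[[g]], tnet$tables[[g]], env)
      fv <- eval_table(fitted$parents[[g]], fitted$tables[[g]], env)
      hits <- hits + (tv == fv)
    }
    hits / 2^k
  }, numeric(1))

  base_truth <- enumerate_attractors(tnet, "exhaustive",
                                     max_exhaustive_genes = 25)
  common <- intersect(fitted$genes, tnet$genes)
  sig_fit <- attractor_signatures(report$attractors_baseline, common)
  sig_tru <- attractor_signatures(base_truth, common)
  jac <- length(intersect(sig_fit, sig_tru)) /
    length(union(sig_fit, sig_tru))

  list(edge_aupr = er$aupr, prevalence = er$prevalence,
       rule_agreement = mean(agree), attractor_jaccard = jac)
}

eval_table <- function(parents, table, env) {
  row <- table_row(vapply(parents, function(p) env[[p]], numeric(1)))
  table[row + 1]
}

#' Build a run report directly from the planted truth
#'
#' The self-recovery reference: the importance graph contains exactly the
#' planted edges (weight 1), the Boolean model is the planted network, and
#' the attractor sets are its exact baseline and clamped dynamics. Scoring
#' this report with [score_recovery()] must give perfect scores.
#'
#' @param truth A [ground_truth()].
#' @return A `run_report` containing the fields used by [score_recovery()].
#' @export
report_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  net <- truth$network
  edges <- do.call(rbind, lapply(net$genes, function(g) {
    if (length(net$parents[[g]]) == 0) return(NULL)
    data.frame(regulator = net$parents[[g]], target = g, weight = 1,
               stringsAsFactors = FALSE)
  }))
  g <- weighted_digraph(net$genes, edges)
  up <- names(truth$clamp_spec)[truth$clamp_spec == 1]
  down <- names(truth$clamp_spec)[truth$clamp_spec == 0]
  report <- list(
    graph_full = g, graph = g, network = net,
    attractors_baseline = enumerate_attractors(net, "exhaustive", 25),
    attractors_perturbed = perturb(net, up, down, "clamp", 25),
    seed = truth$seed)
  class(report) <- "run_report"
  report
}
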
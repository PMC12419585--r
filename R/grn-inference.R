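#' Construct a weighted directed gene network
#'
#' @param nodes Character vector of gene identifiers.
#' @param edges Data frame with columns `regulator`, `target`, `weight`
#'   (weights >= 0, no self-loops).
#' @return An object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (is.null(edges))
    edges <- data.frame(regulator = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "weight") %in% names(edges)))
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (!all(edges$regulator %in% nodes) || !all(edges$target %in% nodes))
    stop("edge endpoints must be among the nodes")
  if (any(edges$regulator == edges$target)) stop("self-loops are not allowed")
  if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  structure(list(nodes = nodes, edges = edges), class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat(sprintf("weighted_digraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Directed network inference by per-target random-forest importance
#'
#' For every target gene a random-forest regression predicts the target's
#' standardized log-normalized expression from all other candidate genes;
#' the importance of a regulator is the total variance reduction attributed
#' to splits on it, summed over trees (the node-purity importance) and
#' normalized to sum to 1 per target. The union over targets yields a
#' complete weighted digraph ranking all possible directed edges.
#'
#' Samples are put in a canonical (sorted-ID) order and each target's
#' forest gets a sub-seed derived from `seed` and the target's rank in the
#' sorted gene list, so results do not depend on sample or iteration order.
#'
#' @param m A [count_matrix()] (>= 3 samples).
#' @param candidates Optional character vector restricting the analysis to a
#'   gene subset (e.g. a pathway membership list); default all genes.
#' @param n_trees Trees per forest (default 1000).
#' @param k_features `"sqrt"` (default: floor(sqrt(p)) candidate features
#'   per split) or an integer.
#' @param seed Integer master seed.
#' @param factors Optional precomputed size factors.
#' @return A `weighted_digraph` with one weighted edge for every ordered
#'   candidate pair; constant-expression targets get zero importance rows
#'   and are listed in `attr(, "degenerate_targets")`.
#' @examples
#' \donttest{
#' sim <- simulate_expression(ground_truth(generate_network(8, 1.5, 2, seed = 1),
#'                                         n_control = 20, n_treated = 0, seed = 2))
#' g <- genie3_importances(sim$counts, n_trees = 100, seed = 3)
#' }
#' @export
genie3_importances <- function(m, candidates = NULL, n_trees = 1000,
                               k_features = "sqrt", seed = 1, factors = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) < 3) stop("need at least 3 samples")
  y <- log_normalized(m, factors)
  if (!is.null(candidates)) {
    missing_genes <- setdiff(candidates, rownames(y))
    if (length(missing_genes))
      stop("candidate genes absent from the matrix: ",
           paste(utils::head(missing_genes, 3), collapse = ", "))
    y <- y[candidates, , drop = FALSE]
  }
  if (nrow(y) < 2) stop("need at least 2 candidate genes")
  y <- y[, order(colnames(y)), drop = FALSE]       # canonical sample order
  genes <- rownames(y)
  sds <- apply(y, 1, stats::sd)
  z <- (y - rowMeans(y)) / ifelse(sds > 0, sds, 1)  # per-gene standardization
  expr <- t(z)                                      # samples x genes
  p <- length(genes) - 1
  mtry <- if (identical(k_features, "sqrt")) max(1, floor(sqrt(p)))
          else max(1, min(p, as.integer(k_features)))
  gene_rank <- match(genes, sort(genes))
  degenerate <- character(0)
  edge_list <- vector("list", length(genes))
  for (ti in seq_along(genes)) {
    target <- genes[ti]
    regs <- genes[genes != target]
    w <- stats::setNames(numeric(length(regs)), regs)
    if (sds[target] == 0) {
      degenerate <- c(degenerate, target)
    } else {
      set.seed((seed + 7919 * gene_rank[ti]) %% .Machine$integer.max)
      # near-Boolean expression profiles legitimately have few unique values;
      # silence the forest's regression-response nudge for that case
      rf <- withCallingHandlers(
        randomForest::randomForest(
          x = expr[, regs, drop = FALSE], y = expr[, target],
          ntree = n_trees, mtry = mtry, importance = FALSE),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      imp <- rf$importance[, "IncNodePurity"]
      imp[imp < 0] <- 0
      if (sum(imp) > 0) w[names(imp)] <- imp / sum(imp)
    }
    edge_list[[ti]] <- data.frame(regulator = regs, target = target,
                                  weight = as.numeric(w),
                                  stringsAsFactors = FALSE)
  }
  g <- weighted_digraph(genes, do.call(rbind, edge_list))
  attr(g, "degenerate_targets") <- degenerate
  g
}

#' Threshold the edges of a weighted digraph
#'
#' @param g A `weighted_digraph`.
#' @param mode `"top_k_edges"` (keep the k highest-weight edges overall),
#'   `"weight_min"` (keep edges with weight >= value), or
#'   `"top_k_per_target"` (keep each target's k strongest regulators;
#'   default mode with k = 2 keeps truth tables small and attractor search
#'   exact).
#' @param value Threshold (k or minimum weight; must be non-negative).
#' @param keep_isolated Retain nodes left without edges (default FALSE: the
#'   network shrinks to its connected gene set).
#' @return The thresholded `weighted_digraph`.
#' @export
threshold_edges <- function(g, mode = c("top_k_per_target", "top_k_edges",
                                        "weight_min"),
                            value = 2, keep_isolated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "weighted_digraph"))
  if (value < 0) stop("threshold value must be non-negative")
  e <- g$edges
  # deterministic tie-breaks: weight desc, then regulator/target name
  ord <- order(-e$weight, e$regulator, e$target)
  e <- e[ord, , drop = FALSE]
  keep <- switch(mode,
    weight_min = e$weight >= value,
    top_k_edges = seq_len(nrow(e)) <= value,
    top_k_per_target = stats::ave(seq_len(nrow(e)), e$target,
                                  FUN = seq_along) <= value)
  out <- e[keep & e$weight > 0, , drop = FALSE]
  nodes <- if (keep_isolated) g$nodes
           else intersect(g$nodes, unique(c(out$regulator, out$target)))
  weighted_digraph(nodes, out[order(out$target, out$regulator), , drop = FALSE])
}

#' Convert a weighted digraph to igraph
#' @param g A `weighted_digraph`.
#' @return An igraph directed graph with a `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  igraph::graph_from_data_frame(
    g$edges[, c("regulator", "target", "weight")],
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

#' Read / write an edge list TSV
#' @param g A `weighted_digraph`.
#' @param path TSV path (columns regulator, target, weight).
#' @param nodes Optional node set for `read_edges` (default: genes seen in
#'   the edge list).
#' @export
write_edges <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(e$regulator, e$target))
  weighted_digraph(nodes, e)
}

#' Area under the precision-recall curve for an edge ranking
#'
#' Average-precision estimator: edges are sorted by decreasing score (ties
#' broken deterministically by edge name) and AP is the mean of the
#' precision values at each true edge's rank. The no-skill baseline equals
#' the prevalence of true edges.
#'
#' @param scores Numeric scores, one per candidate edge.
#' @param labels Logical/0-1 vector: is the candidate a true edge?
#' @param names Optional edge names for deterministic tie-breaking.
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, labels, names = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels)) stop("no positive labels")
  ord <- if (is.null(names)) order(-scores) else order(-scores, names)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  mean(prec[lab])
}

#' Score an inferred edge ranking against a planted network
#'
#' @param g A `weighted_digraph` (complete importance graph).
#' @param truth_net The planted [boolean_network()].
#' @return List with `aupr`, `prevalence`, and `n_edges` (planted).
#' @export
edge_recovery <- function(g, truth_net) {
  stopifnot(inherits(g, "weighted_digraph"), inherits(truth_net, "boolean_network"))
  genes <- g$nodes
  if (!all(genes %in% truth_net$genes))
    stop("graph genes missing from the planted network")
  pairs <- expand.grid(regulator = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  key <- paste(pairs$regulator, pairs$target, sep = "->")
  wkey <- paste(g$edges$regulator, g$edges$target, sep = "->")
  scores <- stats::setNames(rep(0, nrow(pairs)), key)
  scores[wkey[wkey %in% key]] <- g$edges$weight[wkey %in% key]
  truth_edges <- unlist(lapply(truth_net$genes, function(gn)
    paste(truth_net$parents[[gn]], gn, sep = "->")))
  labels <- key %in% truth_edges
  if (!any(labels)) stop("planted network has no edges among the graph's genes")
  list(aupr = aupr(as.numeric(scores), labels, names = key),
       prevalence = mean(labels),
       n_edges = sum(labels))
}
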
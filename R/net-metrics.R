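#' Topology metrics of a directed gene network
#'
#' Summarizes an inferred regulatory digraph: hub genes (maximum total
#' degree, ties included), mean total degree (`2E/N`), directed edge
#' density (`E / (N (N - 1))`), mean closeness and mean betweenness on the
#' undirected view, and the Shannon entropy of the total-degree
#' distribution. Path metrics use the undirected view because inferred edge
#' directions are statistical estimates; closeness is computed within each
#' node's reachable set and normalized to [0, 1] per component, and
#' betweenness is optionally normalized by `(N - 1)(N - 2) / 2`.
#'
#' @param g A `weighted_digraph` (>= 2 nodes).
#' @param betweenness_normalized Normalize betweenness (default TRUE).
#' @param entropy_base `"e"` (natural log, default) or `"2"`.
#' @return An object of class `network_metrics`: list with `hubs`,
#'   `mean_degree`, `edge_density`, `mean_closeness`, `mean_betweenness`,
#'   `degree_entropy`, `n_nodes`, `n_edges`.
#' @examples
#' g <- weighted_digraph(c("a", "b", "c"),
#'                       data.frame(regulator = c("a", "b"),
#'                                  target = c("b", "c"), weight = 1))
#' compute_metrics(g)
#' @export
compute_metrics <- function(g, betweenness_normalized = TRUE,
                            entropy_base = c("e", "2")) {
  entropy_base <- match.arg(entropy_base)
  stopifnot(inherits(g, "weighted_digraph"))
  N <- length(g$nodes)
  if (N < 2) stop("need at least 2 nodes")
  E <- nrow(g$edges)
  ig <- as_igraph(g)
  und <- igraph::as_undirected(ig, mode = "collapse")
  deg <- igraph::degree(ig, mode = "all")           # in + out
  # closeness within the reachable set, normalized per component
  D <- igraph::distances(und, weights = NA)
  closeness_n <- vapply(seq_len(N), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) return(0)
    length(d) / sum(d)
  }, numeric(1))
  btw <- igraph::betweenness(und, directed = FALSE, weights = NA)
  if (betweenness_normalized && N > 2)
    btw <- btw / ((N - 1) * (N - 2) / 2)
  pk <- table(deg) / N
  logf <- if (entropy_base == "e") log else log2
  entropy <- -sum(pk * logf(pk))
  structure(list(
    hubs = g$nodes[deg == max(deg)],
    mean_degree = mean(deg),
    edge_density = E / (N * (N - 1)),
    mean_closeness = mean(closeness_n),
    mean_betweenness = mean(btw),
    degree_entropy = as.numeric(entropy),
    n_nodes = N, n_edges = E), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("network_metrics\n")
  cat(sprintf("  hubs:             %s\n", paste(x$hubs, collapse = ", ")))
  cat(sprintf("  mean degree:      %.3f\n", x$mean_degree))
  cat(sprintf("  edge density:     %.3f\n", x$edge_density))
  cat(sprintf("  mean closeness:   %.3f\n", x$mean_closeness))
  cat(sprintf("  mean betweenness: %.3f\n", x$mean_betweenness))
  cat(sprintf("  degree entropy:   %.3f\n", x$degree_entropy))
  invisible(x)
}

#' Write metrics as JSON
#' @param metrics A `network_metrics` object.
#' @param path Output path.
#' @export
metrics_to_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
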
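#' Binarize expression into Boolean gene states
#'
#' Per gene, log-normalized values are split into two clusters; the cluster
#' with the higher center maps to 1 (ON). The default `kmeans2` method is
#' the exact one-dimensional two-cluster solution: the within-cluster
#' sum-of-squares minimizer over all sorted split points (optimal 1-D
#' 2-means). `mean_split` thresholds at the gene's mean. Constant genes are
#' assigned all-0 and flagged.
#'
#' @param m A [count_matrix()] or matrix of counts.
#' @param factors Optional size factors.
#' @param method `"kmeans2"` (default) or `"mean_split"`.
#' @return Genes x samples 0/1 integer matrix with attribute `degenerate`
#'   (character vector of constant genes).
#' @examples
#' m <- matrix(c(1, 1, 10, 10), 1, dimnames = list("g1", paste0("s", 1:4)))
#' binarize(count_matrix(m, c("ND", "ND", "HFD", "HFD")), factors = rep(1, 4))
#' @export
binarize <- function(m, factors = NULL, method = c("kmeans2", "mean_split")) {
  method <- match.arg(method)
  y <- log_normalized(m, factors)
  out <- matrix(0L, nrow(y), ncol(y), dimnames = dimnames(y))
  degenerate <- character(0)
  for (i in seq_len(nrow(y))) {
    v <- y[i, ]
    if (max(v) - min(v) < 1e-12) {
      degenerate <- c(degenerate, rownames(y)[i])
      next
    }
    out[i, ] <- switch(method,
                       kmeans2 = split_1d_2means(v),
                       mean_split = as.integer(v > mean(v)))
  }
  attr(out, "degenerate") <- degenerate
  out
}

# Exact 1-D 2-means: evaluate within-SS at every split of the sorted values
# and label the higher-center cluster 1.
split_1d_2means <- function(v) {
  n <- length(v)
  ord <- order(v)
  s <- v[ord]
  best_ss <- Inf; best_cut <- 1
  for (cut in seq_len(n - 1)) {
    lo <- s[1:cut]; hi <- s[(cut + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss - 1e-15) { best_ss <- ss; best_cut <- cut }
  }
  thr <- (s[best_cut] + s[best_cut + 1]) / 2
  as.integer(v > thr)
}

#' Best-fit Boolean rule learning
#'
#' Returns the truth table over the given parents that disagrees with the
#' target's observed state in the fewest samples. Ties (and unobserved
#' parent-input rows) are resolved deterministically in favour of output 0,
#' which simultaneously selects, among all minimizers, the table with the
#' fewest ON outputs and the lexicographically smallest one.
#'
#' @param target Target gene name.
#' @param parents Character vector of parent genes (at most `max_in_degree`).
#' @param states A genes x samples 0/1 matrix ([binarize()] output or latent
#'   simulation states).
#' @param max_in_degree In-degree cap (default 3: with ~8 samples larger
#'   tables are unidentifiable, and small tables keep dynamics exact).
#' @return Integer 0/1 truth table of length `2^length(parents)`, with
#'   attribute `errors` (number of mismatched samples).
#' @examples
#' st <- rbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1), y = c(0, 0, 0, 1))
#' fit_boolean_rule("y", c("a", "b"), st)  # AND
#' @export
fit_boolean_rule <- function(target, parents, states, max_in_degree = 3) {
  k <- length(parents)
  if (k > max_in_degree)
    stop("in-degree ", k, " exceeds the cap of ", max_in_degree)
  if (ncol(states) < 1) stop("need at least one sample")
  if (!all(c(target, parents) %in% rownames(states)))
    stop("target and parents must be rows of the state matrix")
  tv <- states[target, ]
  if (k == 0) {
    # constant rule: majority value, ties -> 0
    tab <- as.integer(sum(tv == 1) > sum(tv == 0))
    attr(tab, "errors") <- min(sum(tv == 1), sum(tv == 0))
    return(tab)
  }
  pm <- states[parents, , drop = FALSE]
  rows <- as.integer(t(pm) %*% 2^((k - 1):0))       # row index per sample
  tab <- integer(2^k)
  errors <- 0L
  for (r in 0:(2^k - 1)) {
    sel <- rows == r
    ones <- sum(tv[sel] == 1); zeros <- sum(sel) - ones
    tab[r + 1] <- as.integer(ones > zeros)
    errors <- errors + min(ones, zeros)
  }
  attr(tab, "errors") <- errors
  tab
}

#' Build a Boolean network from a thresholded digraph and binary states
#'
#' Fits a best-fit rule for every node of the digraph using its inferred
#' regulators as parents (ranked by importance; at most `max_in_degree`
#' kept). Nodes without regulators get a constant (majority-state) rule.
#'
#' @param g A thresholded `weighted_digraph`.
#' @param states Genes x samples 0/1 matrix covering the digraph's nodes.
#' @param max_in_degree Parent cap per gene (default 3).
#' @return A [boolean_network()] over the digraph's nodes.
#' @export
build_boolean_model <- function(g, states, max_in_degree = 3) {
  stopifnot(inherits(g, "weighted_digraph"))
  genes <- g$nodes
  if (!all(genes %in% rownames(states)))
    stop("state matrix is missing digraph genes")
  parents <- list(); tables <- list()
  for (gn in genes) {
    e <- g$edges[g$edges$target == gn, , drop = FALSE]
    e <- e[order(-e$weight, e$regulator), , drop = FALSE]
    p <- utils::head(e$regulator, max_in_degree)
    parents[[gn]] <- p
    tables[[gn]] <- as.integer(fit_boolean_rule(gn, p, states, max_in_degree))
  }
  boolean_network(genes, parents, tables)
}
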
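# Independent oracles: these re-implement the quantities under test with
# naive algorithms and share no code path with the package internals.

# -- Boolean dynamics ---------------------------------------------------------

# Successor of one packed state by direct rule evaluation.
oracle_successor <- function(net, s) {
  n <- length(net$genes)
  bits <- as.integer(intToBits(s))[1:n]
  nxt <- integer(n)
  for (i in seq_len(n)) {
    g <- net$genes[i]
    if (g %in% names(net$clamped)) {
      nxt[i] <- net$clamped[[g]]
    } else {
      p <- match(net$parents[[g]], net$genes)
      k <- length(p)
      row <- if (k) sum(bits[p] * 2^(k - seq_len(k))) else 0
      nxt[i] <- net$tables[[g]][row + 1]
    }
  }
  sum(nxt * 2^(seq_len(n) - 1))
}

# Naive exhaustive attractor search: walk every state's trajectory with
# per-state successor evaluation and colouring.
oracle_attractors <- function(net) {
  n <- length(net$genes)
  free <- setdiff(net$genes, names(net$clamped))
  fidx <- match(free, net$genes)
  base <- if (length(net$clamped))
    sum(net$clamped * 2^(match(names(net$clamped), net$genes) - 1)) else 0
  f <- length(free)
  full_of <- vapply(0:(2^f - 1), function(sf) {
    bits <- as.integer(intToBits(sf))[seq_len(max(f, 1))]
    if (f == 0) return(base)
    base + sum(bits[1:f] * 2^(fidx - 1))
  }, numeric(1))
  idx_of <- new.env(hash = TRUE)
  for (i in seq_len(2^f)) idx_of[[as.character(full_of[i])]] <- i
  succ <- vapply(full_of, function(s) oracle_successor(net, s), numeric(1))
  succ_i <- vapply(succ, function(s) idx_of[[as.character(s)]], numeric(1))
  att_id <- integer(2^f)
  cycles <- list()
  for (start in seq_len(2^f)) {
    if (att_id[start] != 0) next
    path <- integer(0)
    pos <- new.env(hash = TRUE)
    s <- start
    while (att_id[s] == 0 && is.null(pos[[as.character(s)]])) {
      pos[[as.character(s)]] <- length(path) + 1L
      path <- c(path, s)
      s <- succ_i[s]
    }
    if (att_id[s] != 0) {
      id <- att_id[s]
    } else {
      cyc <- path[pos[[as.character(s)]]:length(path)]
      id <- length(cycles) + 1L
      cycles[[id]] <- full_of[cyc]
    }
    att_id[path] <- id
  }
  basins <- tabulate(att_id, nbins = length(cycles))
  list(cycles = cycles, basins = basins)
}

# Canonical signature of a cycle: rotate so the smallest state leads.
canon_cycle <- function(states) {
  i <- which.min(states)
  paste(c(states[i:length(states)], states[seq_len(i - 1)]), collapse = ",")
}

# Compare a package attractor_set with the oracle's output.
same_attractors <- function(att, oracle) {
  pkg <- vapply(att$attractors, function(a) canon_cycle(a$states), character(1))
  ora <- vapply(oracle$cycles, canon_cycle, character(1))
  if (!setequal(pkg, ora)) return(FALSE)
  m <- match(pkg, ora)
  all(vapply(att$attractors, `[[`, numeric(1), "basin") == oracle$basins[m])
}

# -- graph path metrics -------------------------------------------------------

# Floyd-Warshall distances on an undirected unweighted adjacency matrix.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0 | t(adj) > 0] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Shortest-path counts by DP over distance levels (unweighted, undirected).
oracle_path_counts <- function(adj, D) {
  n <- nrow(adj)
  und <- (adj > 0 | t(adj) > 0) * 1
  N <- matrix(0, n, n)
  for (s in 1:n) {
    N[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (v in which(D[s, ] == d)) {
        pred <- which(und[, v] > 0 & D[s, ] == d - 1)
        N[s, v] <- sum(N[s, pred])
      }
    }
  }
  N
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  N <- oracle_path_counts(adj, D)
  btw <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t]) || N[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + N[s, v] * N[v, t] / N[s, t]
    }
    btw[v] <- tot
  }
  btw
}

oracle_closeness <- function(adj) {
  D <- oracle_distances(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

# -- misc ---------------------------------------------------------------------

# Median-of-ratios by direct per-gene loops.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / ref))
}

# Random adjacency matrix digraph as a weighted_digraph
random_digraph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  adj <- matrix(rbinom(n_nodes^2, 1, p_edge), n_nodes)
  diag(adj) <- 0
  idx <- which(adj > 0, arr.ind = TRUE)
  edges <- data.frame(regulator = nodes[idx[, 1]], target = nodes[idx[, 2]],
                      weight = 1, stringsAsFactors = FALSE)
  list(g = weighted_digraph(nodes, edges), adj = adj)
}
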
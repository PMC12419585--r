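#' Synchronous successor of a network state
#'
#' All unclamped genes update simultaneously from their truth tables
#' evaluated on the current state; clamped genes keep their clamped value.
#' States are packed as non-negative integers with gene `i` at bit `i - 1`.
#'
#' @param net A [boolean_network()].
#' @param state Packed state, `0 <= state < 2^n_genes`.
#' @return The packed successor state (exactly one per state).
#' @examples
#' net <- read_rules(textConnection(c("targets, factors", "a, b", "b, a")))
#' successor(net, 1)  # a=1,b=0 -> a=0,b=1
#' @export
successor <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  n <- n_genes(net)
  if (state < 0 || state >= 2^n) stop("state out of range for ", n, " genes")
  bits <- unpack_bits(state, n)
  names(bits) <- net$genes
  nxt <- numeric(n)
  for (i in seq_len(n)) {
    g <- net$genes[i]
    if (g %in% names(net$clamped)) {
      nxt[i] <- net$clamped[[g]]
    } else {
      row <- table_row(bits[net$parents[[g]]])
      nxt[i] <- net$tables[[g]][row + 1]
    }
  }
  pack_bits(nxt)
}

# Vectorized transition map over the free (unclamped) state space.
# Returns free gene indices, the full packed state for every free-state
# index 0..2^f-1, and the successor as a free-state index vector.
transition_map <- function(net) {
  n <- n_genes(net)
  free <- setdiff(net$genes, names(net$clamped))
  f <- length(free)
  free_idx <- match(free, net$genes)
  states_free <- 0:(2^f - 1)
  full <- numeric(2^f)
  if (length(net$clamped))
    full <- full + sum(net$clamped * 2^(match(names(net$clamped), net$genes) - 1))
  for (j in seq_len(f))
    full <- full + state_bit(states_free, j) * 2^(free_idx[j] - 1)
  succ_free <- numeric(2^f)
  for (j in seq_len(f)) {
    g <- free[j]
    pars <- net$parents[[g]]
    k <- length(pars)
    if (k == 0) {
      nxt_bit <- rep(net$tables[[g]][1], 2^f)
    } else {
      row <- numeric(2^f)
      pidx <- match(pars, net$genes)
      for (q in seq_len(k))
        row <- row + state_bit(full, pidx[q]) * 2^(k - q)
      nxt_bit <- net$tables[[g]][row + 1]
    }
    succ_free <- succ_free + nxt_bit * 2^(j - 1)
  }
  list(free = free, free_idx = free_idx, full = full, succ = succ_free)
}

free_to_full <- function(tm, free_states) tm$full[free_states + 1]

#' Enumerate the attractors of a synchronous Boolean network
#'
#' Under synchronous update every state has exactly one successor, so the
#' dynamics form a functional graph whose terminal cycles are the
#' attractors and whose weakly connected components are their basins.
#' Exhaustive mode resolves every free state by iterated map-squaring
#' (composing the successor map with itself `f` times reaches the cycle
#' from any transient) and returns exact basin sizes; sampled mode follows
#' trajectories from random initial states and reports estimated basins.
#'
#' Clamped genes are removed from the free state space: enumeration runs
#' over the `2^f` assignments of the `f` unclamped genes, and every reported
#' attractor state carries the clamped values.
#'
#' @param net A [boolean_network()].
#' @param mode `"exhaustive"` (exact, requires `f <= max_exhaustive_genes`)
#'   or `"sampled"`.
#' @param max_exhaustive_genes Cap on the exhaustive free-gene count;
#'   default 20 (about 1M states), configurable up to 25.
#' @param n_samples Number of random initial states in sampled mode.
#' @param seed Seed for sampled mode.
#' @return An `attractor_set`: list with `attractors` (each a list with
#'   `states`, the ordered packed cycle starting at its smallest state, and
#'   `basin`), `genes`, `clamped`, `total_states` (`2^f`, or the number of
#'   sampled trajectories' start set), and `estimated`.
#' @examples
#' net <- generate_network(8, 1.5, 2, seed = 3)
#' att <- enumerate_attractors(net)
#' sum(vapply(att$attractors, `[[`, numeric(1), "basin")) == att$total_states
#' @export
enumerate_attractors <- function(net, mode = c("exhaustive", "sampled"),
                                 max_exhaustive_genes = 20, n_samples = 1000,
                                 seed = NULL) {
  mode <- match.arg(mode)
  enumerate_attractors_impl(net, mode, max_exhaustive_genes, n_samples, seed,
                            initial_free = NULL)
}

enumerate_attractors_impl <- function(net, mode, max_exhaustive_genes,
                                      n_samples, seed, initial_free = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (max_exhaustive_genes > 25)
    stop("max_exhaustive_genes cannot exceed 25")
  free <- setdiff(net$genes, names(net$clamped))
  f <- length(free)
  if (mode == "exhaustive" && f > max_exhaustive_genes)
    stop("exhaustive enumeration over ", f, " free genes exceeds the cap of ",
         max_exhaustive_genes, "; use mode = 'sampled'")
  if (f > max_exhaustive_genes && mode == "sampled")
    return(sampled_attractors(net, n_samples, seed))
  tm <- transition_map(net)
  if (mode == "sampled") {
    if (is.null(seed)) stop("sampled mode requires a seed")
    set.seed(seed)
    starts <- sample.int(2^f, n_samples, replace = TRUE) - 1
  } else {
    starts <- if (is.null(initial_free)) 0:(2^f - 1) else initial_free
  }
  # Map every state onto its cycle: compose the successor map with itself f
  # times, giving succ^(2^f), which exceeds any transient length.
  v <- tm$succ + 1
  for (i in seq_len(f)) v <- v[v]
  on_cycle <- sort(unique(v[starts + 1]))   # 1-based free states on reached cycles
  att_of <- integer(2^f)
  attractors <- list()
  for (s1 in on_cycle) {
    if (att_of[s1] != 0) next
    cyc <- s1
    s <- tm$succ[s1] + 1
    while (s != s1) { cyc <- c(cyc, s); s <- tm$succ[s] + 1 }
    id <- length(attractors) + 1L
    att_of[cyc] <- id
    attractors[[id]] <- list(states = free_to_full(tm, cyc - 1), basin = 0)
  }
  ids <- att_of[v[starts + 1]]
  tab <- tabulate(ids, nbins = length(attractors))
  for (i in seq_along(attractors)) attractors[[i]]$basin <- tab[i]
  structure(list(attractors = attractors, genes = net$genes,
                 clamped = net$clamped, total_states = length(starts),
                 estimated = identical(mode, "sampled")),
            class = "attractor_set")
}

# Trajectory-following fallback for networks too large for a full
# transition vector; basin sizes are sample counts.
sampled_attractors <- function(net, n_samples, seed) {
  if (is.null(seed)) stop("sampled mode requires a seed")
  set.seed(seed)
  n <- n_genes(net)
  free <- setdiff(net$genes, names(net$clamped))
  free_idx <- match(free, net$genes)
  base <- if (length(net$clamped))
    sum(net$clamped * 2^(match(names(net$clamped), net$genes) - 1)) else 0
  canon <- character(0)
  attractors <- list()
  counts <- integer(0)
  for (rep in seq_len(n_samples)) {
    bits <- stats::rbinom(length(free), 1, 0.5)
    s <- base + sum(bits * 2^(free_idx - 1))
    seen <- new.env(hash = TRUE)
    path <- numeric(0)
    while (is.null(seen[[as.character(s)]])) {
      seen[[as.character(s)]] <- length(path) + 1L
      path <- c(path, s)
      s <- successor(net, s)
    }
    cyc <- path[seen[[as.character(s)]]:length(path)]
    shift <- which.min(cyc)
    cyc <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1)])
    key <- paste(cyc, collapse = ",")
    j <- match(key, canon)
    if (is.na(j)) {
      canon <- c(canon, key)
      attractors[[length(canon)]] <- list(states = cyc, basin = 0)
      counts <- c(counts, 1L)
    } else counts[j] <- counts[j] + 1L
  }
  ord <- order(vapply(attractors, function(a) a$states[1], numeric(1)))
  attractors <- attractors[ord]; counts <- counts[ord]
  for (i in seq_along(attractors)) attractors[[i]]$basin <- counts[i]
  structure(list(attractors = attractors, genes = net$genes,
                 clamped = net$clamped, total_states = n_samples,
                 estimated = TRUE),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  lens <- vapply(x$attractors, function(a) length(a$states), numeric(1))
  cat(sprintf("attractor_set: %d attractor(s) over %s states%s\n",
              length(x$attractors), format(x$total_states, big.mark = ","),
              if (x$estimated) " (sampled; basins estimated)" else ""))
  cat(sprintf("  cycle lengths: %s\n", paste(lens, collapse = ", ")))
  invisible(x)
}

#' Perturb a Boolean network by forcing gene values
#'
#' Models over-expression (value 1) and knockout (value 0) of gene sets. In
#' `clamp` mode the genes are held fixed throughout the dynamics and drop
#' out of the free state space; in `initial_state` mode they are only
#' initialized to the given values and evolve freely, with enumeration
#' restricted to initial states consistent with the assignment.
#'
#' @param net A [boolean_network()].
#' @param up_genes Genes forced to 1 (over-expression).
#' @param down_genes Genes forced to 0 (knockout); must be disjoint from
#'   `up_genes`.
#' @param mode `"clamp"` (default) or `"initial_state"`.
#' @inheritParams enumerate_attractors
#' @return An `attractor_set` (see [enumerate_attractors()]).
#' @export
perturb <- function(net, up_genes = character(0), down_genes = character(0),
                    mode = c("clamp", "initial_state"),
                    max_exhaustive_genes = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "boolean_network"))
  up_genes <- as.character(up_genes); down_genes <- as.character(down_genes)
  if (length(intersect(up_genes, down_genes)))
    stop("up_genes and down_genes must be disjoint")
  if (!all(c(up_genes, down_genes) %in% net$genes))
    stop("perturbed genes must belong to the network")
  assign_ <- c(stats::setNames(rep(1L, length(up_genes)), up_genes),
               stats::setNames(rep(0L, length(down_genes)), down_genes))
  if (mode == "clamp") {
    clamped <- net$clamped
    clamped[names(assign_)] <- assign_
    net2 <- boolean_network(net$genes, net$parents, net$tables, clamped)
    return(enumerate_attractors(net2, "exhaustive", max_exhaustive_genes))
  }
  # initial_state: restrict initial states, dynamics unchanged
  conflict <- intersect(names(assign_), names(net$clamped))
  if (length(conflict) && any(assign_[conflict] != net$clamped[conflict]))
    stop("initial-state assignment conflicts with an existing clamp")
  free <- setdiff(net$genes, names(net$clamped))
  f <- length(free)
  if (f > max_exhaustive_genes)
    stop("initial_state mode requires exhaustive enumeration within the cap")
  fixed <- intersect(names(assign_), free)
  fixed_pos <- match(fixed, free)
  states <- 0:(2^f - 1)
  keep <- rep(TRUE, 2^f)
  for (i in seq_along(fixed))
    keep <- keep & (state_bit(states, fixed_pos[i]) == assign_[fixed[i]])
  enumerate_attractors_impl(net, "exhaustive", max_exhaustive_genes,
                            n_samples = 0, seed = NULL,
                            initial_free = states[keep])
}

#' Summarize attractor cycles and their oscillating genes
#'
#' Fixed points have cycle length 1 and an empty oscillating set; for limit
#' cycles the oscillating set is the genes whose Boolean value differs
#' between consecutive cycle states (union over the cycle).
#'
#' @param attractors An `attractor_set` from [enumerate_attractors()] or
#'   [perturb()].
#' @return A data frame with one row per attractor: `attractor`, `length`,
#'   `basin`, and `oscillating` (comma-separated gene names, `""` for fixed
#'   points).
#' @export
report_cycles <- function(attractors) {
  stopifnot(inherits(attractors, "attractor_set"))
  genes <- attractors$genes
  rows <- lapply(seq_along(attractors$attractors), function(i) {
    a <- attractors$attractors[[i]]
    L <- length(a$states)
    osc <- character(0)
    if (L >= 2) {
      diff_mask <- 0
      nxt <- c(a$states[-1], a$states[1])
      for (j in seq_len(L)) {
        x <- bitwXor(as.integer(a$states[j]), as.integer(nxt[j]))
        diff_mask <- bitwOr(as.integer(diff_mask), x)
      }
      osc <- genes[which(unpack_bits(diff_mask, length(genes)) == 1)]
    }
    data.frame(attractor = i, length = L, basin = a$basin,
               oscillating = paste(osc, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export an attractor set as JSON
#'
#' Cycles are written as lists of bitstrings in gene order (gene 1 first),
#' with basin sizes, oscillating gene sets and the clamp assignment.
#'
#' @param attractors An `attractor_set`.
#' @param path JSON file path.
#' @export
attractors_to_json <- function(attractors, path) {
  stopifnot(inherits(attractors, "attractor_set"))
  n <- length(attractors$genes)
  rep_ <- report_cycles(attractors)
  obj <- list(
    genes = attractors$genes,
    clamped = as.list(attractors$clamped),
    total_states = attractors$total_states,
    estimated = attractors$estimated,
    attractors = lapply(seq_along(attractors$attractors), function(i) {
      a <- attractors$attractors[[i]]
      list(states = vapply(a$states, function(s)
             paste(unpack_bits(s, n), collapse = ""), character(1)),
           basin = a$basin,
           length = length(a$states),
           oscillating = strsplit(rep_$oscillating[i], ",")[[1]])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
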
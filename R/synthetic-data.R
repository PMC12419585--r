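#' Generate a random planted Boolean regulatory network
#'
#' Each gene receives a Poisson-distributed number of parents (truncated at
#' `max_in_degree`, drawn without self-loops unless allowed) and a Boolean
#' update rule sampled uniformly over the non-constant functions of those
#' parents; genes with in-degree 0 get a constant rule. Used as the planted
#' ground truth for benchmarking inference and rule fitting.
#'
#' @param n_genes Number of genes (>= 2).
#' @param mean_in_degree Mean in-degree before truncation (>= 0; 0 forces an
#'   all-constant network).
#' @param max_in_degree Maximum in-degree, at most 4.
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @param allow_self_loops Permit a gene among its own parents (default FALSE).
#' @param gene_names Optional identifiers (default `g01, g02, ...`).
#' @return A [boolean_network()].
#' @examples
#' net <- generate_network(10, 1.5, 3, seed = 7)
#' mean(lengths(net$parents))
#' @export
generate_network <- function(n_genes, mean_in_degree, max_in_degree, seed,
                             allow_self_loops = FALSE, gene_names = NULL) {
  if (n_genes < 2) stop("n_genes must be at least 2")
  if (mean_in_degree < 0 || max_in_degree < mean_in_degree || max_in_degree > 4)
    stop("need 0 <= mean_in_degree <= max_in_degree <= 4")
  set.seed(seed)
  genes <- if (is.null(gene_names)) sprintf("g%02d", seq_len(n_genes))
           else as.character(gene_names)
  stopifnot(length(genes) == n_genes)
  parents <- list(); tables <- list()
  for (i in seq_len(n_genes)) {
    k <- min(stats::rpois(1, mean_in_degree), max_in_degree)
    pool <- if (allow_self_loops) genes else genes[-i]
    p <- if (k > 0) sample(pool, k) else character(0)
    if (k == 0) {
      tab <- sample(0:1, 1)
    } else {
      repeat {
        tab <- sample(0:1, 2^k, replace = TRUE)
        if (length(unique(tab)) == 2) break
      }
    }
    parents[[genes[i]]] <- p
    tables[[genes[i]]] <- tab
  }
  boolean_network(genes, parents, tables)
}

#' Define the ground truth for a synthetic two-group experiment
#'
#' Bundles a planted network, the treated-group clamp assignment (the
#' "high-fat diet" perturbation: genes held over-expressed at 1 or knocked
#' out at 0), the negative-binomial emission parameters and the design.
#' Defaults reflect a small-n bulk RNA-seq diet study: 4 control vs 4
#' treated animals, off-state mean 20 counts, on-state mean 200, NB size 10
#' (dispersion 0.1), and per-sample log-normal library-size factors with
#' sigma 0.3 so that size-factor normalization is non-trivially exercised.
#'
#' @param network A [boolean_network()] (the planted truth).
#' @param clamp_spec Named 0/1 vector over a subset of network genes,
#'   applied to treated samples only.
#' @param mean_low,mean_high NB mean counts for OFF/ON genes
#'   (`mean_high > mean_low > 0`).
#' @param dispersion NB size parameter (> 0); larger = less overdispersion.
#' @param n_control,n_treated Samples per group.
#' @param library_sigma SD of the per-sample log-normal depth factor.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(network, clamp_spec = integer(0),
                         mean_low = 20, mean_high = 200, dispersion = 10,
                         n_control = 4, n_treated = 4,
                         library_sigma = 0.3, seed = 1) {
  stopifnot(inherits(network, "boolean_network"))
  if (!(mean_high > mean_low && mean_low > 0)) stop("need mean_high > mean_low > 0")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_control < 0 || n_treated < 0 || n_control + n_treated < 1)
    stop("need at least one sample")
  if (length(clamp_spec)) {
    if (is.null(names(clamp_spec)) || !all(names(clamp_spec) %in% network$genes))
      stop("clamp_spec keys must be genes of the network")
    if (!all(clamp_spec %in% c(0, 1))) stop("clamp values must be 0 or 1")
  }
  structure(list(network = network, clamp_spec = clamp_spec,
                 mean_low = mean_low, mean_high = mean_high,
                 dispersion = dispersion, n_control = n_control,
                 n_treated = n_treated, library_sigma = library_sigma,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Walk the (possibly clamped) network from a random free-state start to its
# attractor and return the ordered cycle of full packed states.
walk_to_cycle <- function(net, start) {
  seen <- new.env(hash = TRUE)
  path <- numeric(0)
  s <- start
  limit <- 2^length(setdiff(net$genes, names(net$clamped))) + 1
  for (step in seq_len(limit + 1)) {
    key <- as.character(s)
    if (!is.null(seen[[key]])) {
      return(path[seen[[key]]:length(path)])
    }
    seen[[key]] <- length(path) + 1L
    path <- c(path, s)
    s <- successor(net, s)
  }
  stop("internal error: trajectory did not close within the state-space bound")
}

#' Simulate a steady-state RNA-seq experiment from a planted network
#'
#' For each sample a random initial state is iterated to an attractor of the
#' planted network (with the clamp assignment applied in treated samples),
#' one attractor state is drawn uniformly, and counts are emitted per gene:
#' NB(`mean_high`, `dispersion`) when the gene is ON, NB(`mean_low`,
#' `dispersion`) when OFF, with both means scaled by the sample's log-normal
#' library-size factor. Steady-state (attractor) sampling reflects a design
#' of independent animals rather than a time series.
#'
#' @param truth A [ground_truth()].
#' @param deterministic If TRUE, emit the (rounded) expected counts instead
#'   of NB draws — a noiseless limit used to test state recovery.
#' @return A list with `counts` (a [count_matrix()]; control samples labelled
#'   ND, treated HFD) and `states` (the latent genes x samples 0/1 matrix).
#' @examples
#' net <- generate_network(6, 1.5, 2, seed = 2)
#' sim <- simulate_expression(ground_truth(net, seed = 5))
#' dim(sim$counts)
#' @export
simulate_expression <- function(truth, deterministic = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  net <- truth$network
  n <- n_genes(net)
  n_samp <- truth$n_control + truth$n_treated
  cond <- rep(c("ND", "HFD"), c(truth$n_control, truth$n_treated))
  samp_ids <- paste0(cond, stats::ave(seq_len(n_samp), cond, FUN = seq_along))
  clamped_net <- net
  if (length(truth$clamp_spec)) {
    cl <- net$clamped
    cl[names(truth$clamp_spec)] <- as.integer(truth$clamp_spec)
    clamped_net <- boolean_network(net$genes, net$parents, net$tables, cl)
  }
  states <- matrix(0L, n, n_samp, dimnames = list(net$genes, samp_ids))
  counts <- matrix(0L, n, n_samp, dimnames = list(net$genes, samp_ids))
  for (j in seq_len(n_samp)) {
    net_j <- if (cond[j] == "HFD") clamped_net else net
    free <- setdiff(net_j$genes, names(net_j$clamped))
    bits <- stats::rbinom(length(free), 1, 0.5)
    start <- sum(bits * 2^(match(free, net_j$genes) - 1))
    if (length(net_j$clamped))
      start <- start + sum(net_j$clamped *
                             2^(match(names(net_j$clamped), net_j$genes) - 1))
    cyc <- walk_to_cycle(net_j, start)
    s <- cyc[[sample.int(length(cyc), 1)]]
    gbits <- as.integer(unpack_bits(s, n))
    states[, j] <- gbits
    lf <- stats::rlnorm(1, 0, truth$library_sigma)
    mu <- ifelse(gbits == 1, truth$mean_high, truth$mean_low) * lf
    counts[, j] <- if (deterministic) as.integer(round(mu))
                   else stats::rnbinom(n, mu = mu, size = truth$dispersion)
  }
  list(counts = count_matrix(counts, cond), states = states)
}

#' Write latent Boolean states as TSV
#'
#' @param states Genes x samples 0/1 matrix.
#' @param path Output path.
#' @export
write_states <- function(states, path) {
  df <- data.frame(gene = rownames(states), states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
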
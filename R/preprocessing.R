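#' Median-of-ratios size factors
#'
#' The standard depth-normalization estimator for RNA-seq count matrices:
#' each gene with strictly positive counts in every sample contributes the
#' ratio of its count to its across-sample geometric mean, and a sample's
#' size factor is the median of those ratios. Normalized counts are
#' `counts / factor`.
#'
#' Because the reference is re-estimated from the matrix at hand, adding or
#' rescaling a sample perturbs every factor by a common power of the scale
#' change. When factors must be comparable across matrices (or exactly
#' equivariant under rescaling of a single sample), pass a fixed external
#' reference via `geo_means`, as depth-normalization tools expose for
#' cross-batch use.
#'
#' @param m A [count_matrix()] or plain count matrix.
#' @param geo_means Optional fixed per-gene geometric means to use as the
#'   reference (named by gene or aligned with the rows of `m`); by default
#'   the reference is the per-gene geometric mean of `m` itself.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(m, geo_means = NULL) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!is.null(geo_means)) ok <- ok & is.finite(geo_means) & geo_means > 0
  if (!any(ok))
    stop("cannot normalize: no gene has strictly positive counts in every sample")
  logc <- log(counts[ok, , drop = FALSE])
  ref <- if (is.null(geo_means)) rowMeans(logc) else log(geo_means[ok])
  sf <- apply(logc - ref, 2, function(z) exp(stats::median(z)))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene geometric means (the size-factor reference)
#' @param m A [count_matrix()] or matrix.
#' @return Named vector of geometric means (0 where any count is 0).
#' @export
geometric_means <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  gm <- exp(rowMeans(log(counts)))
  gm[rowSums(counts > 0) < ncol(counts)] <- 0
  stats::setNames(gm, rownames(counts))
}

#' Normalized and log-normalized expression
#'
#' `normalize_counts` divides each sample by its size factor;
#' `log_normalized` applies `log2(normalized + 1)` (pseudocount fixed at 1).
#'
#' @param m A [count_matrix()] or matrix.
#' @param factors Size factors from [size_factors()]; computed if missing.
#' @return Numeric matrix, genes x samples.
#' @export
normalize_counts <- function(m, factors = NULL) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (is.null(factors)) factors <- size_factors(counts)
  sweep(counts, 2, factors, "/")
}

#' @rdname normalize_counts
#' @export
log_normalized <- function(m, factors = NULL) {
  log2(normalize_counts(m, factors) + 1)
}

#' Mean-SD trend of log-normalized expression
#'
#' A QC diagnostic: per-gene mean and standard deviation of
#' `log2(normalized + 1)` values, with a running-median trend of the SDs
#' over rank-ordered means. Flat trends indicate a roughly
#' variance-stabilized scale; rising trends indicate residual
#' mean-variance coupling.
#'
#' @param m A [count_matrix()] or matrix.
#' @param window Odd-sized running-median window (>= 3) in rank space; even
#'   values are rounded up.
#' @param factors Optional precomputed size factors.
#' @return A data frame ordered by increasing mean with columns `gene`,
#'   `mean`, `sd`, `trend`.
#' @export
mean_sd_trend <- function(m, window = 51, factors = NULL) {
  if (window < 3) stop("window must be at least 3")
  y <- log_normalized(m, factors)
  if (nrow(y) < window) stop("need at least ", window, " genes")
  mu <- rowMeans(y)
  sd_ <- apply(y, 1, stats::sd)
  ord <- order(mu)
  trend <- running_median(sd_[ord], window)
  data.frame(gene = rownames(y)[ord], mean = mu[ord], sd = sd_[ord],
             trend = trend, row.names = NULL, stringsAsFactors = FALSE)
}

# Symmetric running median with window truncation at the ends.
running_median <- function(x, window) {
  h <- if (window %% 2 == 1) (window - 1) / 2 else window / 2  # round up to odd
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    stats::median(x[lo:hi])
  }, numeric(1))
}
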
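# Invert the trigamma function by Newton iteration on 1/trigamma (which is
# nearly linear), the standard approach for empirical-Bayes variance models.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t differential expression
#'
#' Two-group comparison (HFD vs ND) on `log2(normalized + 1)` expression.
#' Per-gene pooled residual variances `s^2` with `d` residual df are shrunk
#' toward a common prior: hyperparameters `(d0, s0^2)` are fitted by the
#' method of moments on `log s^2` (mean and variance of
#' `log s^2 - digamma(d/2) + log(d/2)`, with `d0` from trigamma inversion),
#' the posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)`, and the
#' moderated t with `d0 + d` degrees of freedom tests the group-mean
#' difference. Benjamini-Hochberg adjusted p-values are appended.
#'
#' @param m A [count_matrix()] with at least 2 samples per condition.
#' @param factors Size factors; computed from `m` if missing.
#' @param d0_override `NULL` (estimate), `0` (no shrinkage: ordinary pooled
#'   t), or `Inf` (full shrinkage: all genes share `s0^2`).
#' @return A `deg_table` data frame with columns `gene`, `log2FC` (HFD minus
#'   ND mean), `t`, `p`, `p_adj`, `class` (filled by [classify_degs()],
#'   initialized to `"ns"`), plus attributes `d0` and `s0_sq`.
#' @examples
#' sim <- simulate_expression(ground_truth(generate_network(12, 1.5, 2, seed = 1),
#'                                         seed = 3))
#' head(moderated_t(sim$counts))
#' @export
moderated_t <- function(m, factors = NULL, d0_override = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  cond <- m$condition
  n1 <- sum(cond == "ND"); n2 <- sum(cond == "HFD")
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per condition")
  d <- n1 + n2 - 2
  if (d <= 0) stop("zero residual degrees of freedom")
  y <- log_normalized(m, factors)
  m1 <- rowMeans(y[, cond == "ND", drop = FALSE])
  m2 <- rowMeans(y[, cond == "HFD", drop = FALSE])
  v1 <- apply(y[, cond == "ND", drop = FALSE], 1, stats::var)
  v2 <- apply(y[, cond == "HFD", drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  # hyperparameters from the marginal distribution of log s^2
  pos <- s2 > 1e-12
  if (!any(pos)) stop("all genes have zero residual variance")
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (sum(pos) > 1) stats::var(e) else 0
  excess <- evar - trigamma(d / 2)
  if (is.null(d0_override)) {
    d0 <- if (excess > 0) 2 * trigamma_inverse(excess) else Inf
    d0 <- min(max(d0, 0.01), 1e6)             # keep posterior df finite
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else if (identical(d0_override, 0)) {
    d0 <- 0
    s0_sq <- exp(emean)
  } else if (is.infinite(d0_override)) {
    d0 <- 1e6
    s0_sq <- exp(emean)
  } else stop("d0_override must be NULL, 0 or Inf")
  s2_post <- if (d0 == 0) s2 else (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- lfc / se
  tstat[se == 0 & lfc == 0] <- 0   # degenerate all-equal gene
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tab <- data.frame(gene = rownames(y), log2FC = lfc, t = tstat, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    class = "ns", row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "d0") <- d0
  attr(tab, "s0_sq") <- s0_sq
  attr(tab, "df_residual") <- d
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Classify differentially expressed genes
#'
#' Applies the significance and fold-change gates: a gene is `up` when its
#' p-value is below `alpha` and `log2FC > fc_cut`, `down` when the p-value
#' is below `alpha` and `log2FC < -fc_cut`, otherwise `ns`.
#'
#' @param table A `deg_table` from [moderated_t()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param fc_cut Log2 fold-change magnitude gate (>= 0); default 1.5.
#' @param use_adjusted Gate on BH-adjusted p-values instead of raw p.
#' @param verbose Report up/down counts via `message()`.
#' @return The table with its `class` column assigned.
#' @export
classify_degs <- function(table, alpha = 0.05, fc_cut = 1.5,
                          use_adjusted = FALSE, verbose = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (fc_cut < 0) stop("fc_cut must be non-negative")
  p <- if (use_adjusted) table$p_adj else table$p
  cls <- rep("ns", nrow(table))
  cls[p < alpha & table$log2FC > fc_cut] <- "up"
  cls[p < alpha & table$log2FC < -fc_cut] <- "down"
  table$class <- cls
  if (verbose)
    message(sum(cls == "up"), " up-regulated, ", sum(cls == "down"),
            " down-regulated of ", nrow(table), " genes")
  table
}

#' Write a DEG table as TSV
#' @param table A `deg_table`.
#' @param path Output path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
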
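#' Construct a labelled count matrix
#'
#' The pipeline's entry point: an integer gene-by-sample matrix of RNA-seq
#' counts with a two-group condition label per sample. `"ND"` (normal diet)
#' is the control level and `"HFD"` (high-fat diet) the treated level.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames
#'   required), samples in columns (colnames required).
#' @param condition Character or factor of length `ncol(counts)` with values
#'   in `c("ND", "HFD")`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `condition` (factor with levels ND, HFD).
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("ND", "ND", "HFD", "HFD"))
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("condition must have one label per sample")
  if (!all(condition %in% c("ND", "HFD")))
    stop("condition labels must be 'ND' or 'HFD'")
  structure(
    list(counts = counts,
         condition = factor(condition, levels = c("ND", "HFD"))),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d ND, %d HFD)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "ND"), sum(x$condition == "HFD")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write a count matrix as TSV with a JSON sidecar
#'
#' The TSV holds genes in rows with a `gene` first column and sample IDs as
#' the remaining header fields. Condition labels (and optionally the
#' generator seed) live in a JSON sidecar at `<path>.json`.
#'
#' @param m A [count_matrix()].
#' @param path TSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param seed Optional integer recorded in the sidecar.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   [count_matrix()].
#' @export
write_counts <- function(m, path, seed = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(samples = colnames(m$counts),
               condition = as.character(m$condition))
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$samples, colnames(counts)))
    stop("sidecar sample IDs do not match the TSV header")
  count_matrix(counts, side$condition)
}
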
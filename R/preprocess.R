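#' Quantile normalization across samples
#'
#' Forces every sample column to share one empirical distribution: the
#' value at rank r in each column is replaced by the mean over columns of
#' the r-th smallest values. Within-column rank order is preserved. Tied
#' values within a column receive the mean of the reference values over
#' their tied rank span (fractional average ranks are interpolated
#' between the two bracketing reference values), which keeps the
#' operation idempotent on tie-free data.
#'
#' @param x A numeric matrix, [expression_matrix()] or [probe_matrix()].
#' @param ... Passed to methods.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(x, ...) UseMethod("quantile_normalize")

#' @export
quantile_normalize.matrix <- function(x, ...) {
  if (ncol(x) < 1L) stop("need at least one column")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop(sprintf("non-finite input at %d cell(s), first at row %d, column %d",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

#' @export
quantile_normalize.expression_matrix <- function(x, ...) {
  x$values <- quantile_normalize(x$values)
  x
}

#' @export
quantile_normalize.probe_matrix <- function(x, ...) {
  x$values <- quantile_normalize(x$values)
  x
}

# One Tukey median-polish fit on a complete block. Returns the additive
# decomposition; convergence when the total absolute residual changes by
# less than eps * number of cells between sweeps (or residuals hit zero).
median_polish_fit <- function(block, eps = 1e-6, max_sweeps = 10L) {
  nr <- nrow(block); nc <- ncol(block)
  z <- block
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  oldsum <- Inf
  for (sweep in seq_len(max_sweeps)) {
    rdelta <- apply(z, 1, stats::median)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(z, 2, stats::median)
    z <- sweep(z, 2, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * length(z)) break
    oldsum <- newsum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = z)
}

#' Summarize probe-level data to gene level by median polish
#'
#' For each gene, fits the robust additive model
#' `value = overall + probe effect + sample effect + residual` by Tukey
#' median polish on the gene's complete probes x samples block; the
#' gene-level summary for a sample is `overall + sample effect`. This is
#' the standard robust summarization step used by RMA-style microarray
#' preprocessing. Single-probe genes pass through unchanged.
#'
#' @param probes A [probe_matrix()].
#' @param dataset_id Dataset label for the returned matrix.
#' @param eps Convergence tolerance on the change in total absolute
#'   residual, per cell (default 1e-6).
#' @param max_sweeps Maximum polish sweeps per gene (default 10).
#' @return An [expression_matrix()]-shaped object with one row per gene.
#'   Group labels are not carried by probe matrices, so the result is a
#'   plain numeric matrix; attach groups with [expression_matrix()].
#' @export
median_polish_summarize <- function(probes, dataset_id = "dataset1",
                                    eps = 1e-6, max_sweeps = 10L) {
  stopifnot(inherits(probes, "probe_matrix"))
  genes <- unique(probes$probe_gene)
  out <- matrix(NA_real_, length(genes), ncol(probes$values),
                dimnames = list(genes, colnames(probes$values)))
  for (g in genes) {
    block <- probes$values[probes$probe_gene == g, , drop = FALSE]
    if (nrow(block) == 0L) stop(sprintf("empty probe block for gene '%s'", g))
    if (nrow(block) == 1L) {
      out[g, ] <- block[1, ]
    } else {
      fit <- median_polish_fit(block, eps = eps, max_sweeps = max_sweeps)
      out[g, ] <- fit$overall + fit$col
    }
  }
  out
}

#' Log2-transform raw-scale intensities
#'
#' `log2(x + offset)` for input still on the raw intensity scale; the
#' default offset of 1 keeps zeros finite. Matrices and
#' [expression_matrix()] objects are both accepted.
#'
#' @param x Numeric matrix or [expression_matrix()] of non-negative
#'   raw intensities.
#' @param offset Pseudocount added before the log (default 1).
#' @return Same type as `x`, log2-transformed.
#' @export
log2_transform <- function(x, offset = 1) {
  if (inherits(x, "expression_matrix")) {
    x$values <- log2_transform(x$values, offset)
    return(x)
  }
  if (any(x + offset <= 0)) stop("values + offset must be positive")
  log2(x + offset)
}

#' Collapse duplicate gene rows
#'
#' When a matrix carries several rows for one gene id, keeps the row with
#' the highest mean value; ties keep the first of the tied rows in
#' original order.
#'
#' @param em An [expression_matrix()] whose row names may repeat.
#'   (Because [expression_matrix()] itself permits duplicated gene ids,
#'   this is the canonical cleanup step after loading.)
#' @return An [expression_matrix()] with unique gene rows.
#' @export
collapse_duplicate_genes <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  ids <- rownames(em$values)
  if (!anyDuplicated(ids)) return(em)
  means <- rowMeans(em$values)
  # stable: order by gene, then descending mean, then original position
  ord <- order(ids, -means, seq_along(ids))
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)  # preserve original row order of the winners
  expression_matrix(em$values[keep, , drop = FALSE], em$groups, em$dataset_id)
}
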
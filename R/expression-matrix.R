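#' Expression matrix with tumor/normal group labels
#'
#' The central container of the genomic arm of the pipeline: a genes x
#' samples matrix of log2 intensities together with a per-sample group
#' label (`"tumor"` or `"normal"`) and a dataset identifier.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row
#'   names are gene identifiers, column names sample identifiers; both
#'   must be present and unique. All values must be finite.
#' @param groups Character vector of length `ncol(values)` with entries
#'   `"tumor"` or `"normal"`, in column order (or named by sample id).
#' @param dataset_id Scalar label for the dataset (e.g. a cohort name).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `groups` (named character) and `dataset_id`.
#' @export
expression_matrix <- function(values, groups, dataset_id = "dataset1") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (gene ids) and column names (sample ids)")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop(sprintf("non-finite values at %d cell(s), first at gene '%s', sample '%s'",
                 nrow(bad), rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per sample")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(values)))
      stop("names of `groups` do not match sample ids")
    groups <- groups[colnames(values)]
  } else {
    names(groups) <- colnames(values)
  }
  if (!all(groups %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (length(dataset_id) != 1L)
    stop("`dataset_id` must be a single label")
  structure(
    list(values = values, groups = groups, dataset_id = as.character(dataset_id)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s': %d genes x %d samples (%d tumor, %d normal)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Probe-level matrix with a probe-to-gene map
#'
#' Holds probe x sample log2 intensities prior to gene-level
#' summarization. Every probe maps to exactly one gene.
#'
#' @param values Numeric matrix, probes in rows (unique row names),
#'   samples in columns.
#' @param probe_gene Character vector mapping probe id to gene id; either
#'   named by probe id or in row order.
#'
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probe_gene) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique probe row names")
  if (length(probe_gene) != nrow(values))
    stop("`probe_gene` must map every probe")
  probe_gene <- as.character(probe_gene)
  if (!is.null(names(probe_gene))) {
    if (!setequal(names(probe_gene), rownames(values)))
      stop("names of `probe_gene` do not match probe ids")
    probe_gene <- probe_gene[rownames(values)]
  } else {
    names(probe_gene) <- rownames(values)
  }
  if (!all(is.finite(values)))
    stop("non-finite probe values")
  structure(list(values = values, probe_gene = probe_gene),
            class = "probe_matrix")
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' Expects the dialect the synthetic generator writes: an expression
#' table whose first column is `gene_id` followed by one column per
#' sample, and a metadata table with columns `sample_id` and `group`
#' (`tumor`/`normal`).
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @param dataset_id Dataset label; defaults to the expression file name.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(expr_path, meta_path,
                                dataset_id = sub("\\.tsv$", "", basename(expr_path))) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(expr)[1] != "gene_id")
    stop(sprintf("expression TSV must start with a 'gene_id' column, found '%s'",
                 names(expr)[1]))
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata TSV must have columns 'sample_id' and 'group'")
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$gene_id
  groups <- stats::setNames(meta$group, meta$sample_id)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop(sprintf("samples without metadata: %s", paste(missing, collapse = ", ")))
  expression_matrix(values, groups[colnames(values)], dataset_id)
}

#' Write an expression matrix and its metadata as TSV
#'
#' @param em An [expression_matrix()].
#' @param expr_path,meta_path Output paths.
#' @return Invisibly, `em`.
#' @export
write_expression_tsv <- function(em, expr_path, meta_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = names(em$groups), group = unname(em$groups),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}

#' Read the expression block of a GEO series-matrix text file
#'
#' Convenience reader for the tab-delimited block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` in a GEO
#' series-matrix file. Values are returned as a numeric matrix with
#' probe/gene ids as row names; no normalization is applied. Never
#' required by the pipeline, which consumes plain TSV.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @return Numeric matrix (features x samples).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("no series-matrix table block found")
  block <- lines[(begin + 1L):(end - 1L)]
  tab <- utils::read.delim(text = block, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- as.character(tab[[1]])
  values
}
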
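#' A single proteomic identification run
#'
#' One (cell line, method) mass-spec identification list, reduced to the
#' set of canonicalized gene symbols detected.
#'
#' @param cell_line Cell-line label.
#' @param method Method label, conventionally `"membrane_enrichment"` or
#'   `"biotinylation"`.
#' @param proteins Character vector of identifiers (canonicalized on
#'   construction).
#' @return Object of class `proteomic_run`.
#' @export
proteomic_run <- function(cell_line, method, proteins) {
  if (length(cell_line) != 1L || length(method) != 1L)
    stop("`cell_line` and `method` must be single labels")
  structure(
    list(cell_line = as.character(cell_line), method = as.character(method),
         proteins = unique(canonicalize(proteins))),
    class = "proteomic_run"
  )
}

#' Read a proteomic run from TSV
#'
#' Expects columns `protein_id`, `gene_symbol`, `cell_line`, `method`
#' (the dialect the synthetic generator writes); the run's identifier
#' set is the gene-symbol column.
#'
#' @param path Path to the TSV.
#' @return A [proteomic_run()].
#' @export
read_proteomic_run_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "gene_symbol", "cell_line", "method")
  if (!all(need %in% names(tab)))
    stop(sprintf("proteomic TSV needs columns %s; found: %s",
                 paste(need, collapse = ", "), paste(names(tab), collapse = ", ")))
  cl <- unique(tab$cell_line); me <- unique(tab$method)
  if (length(cl) != 1L || length(me) != 1L)
    stop("a proteomic run file must hold exactly one (cell_line, method) pair")
  proteomic_run(cl, me, tab$gene_symbol)
}

#' Assemble the multi-channel evidence matrix
#'
#' Builds the proteins x channels boolean presence table over the union
#' universe of all inputs. Columns are the genomic datasets in the given
#' order, then one channel per (cell line, method) proteomic run in the
#' given order; with the default study design of three datasets and
#' three cell lines times two methods this yields nine channels.
#'
#' @param genomic_sets Named list of identifier vectors, one per
#'   genomic dataset (names are the dataset ids; must be unique).
#' @param proteomic_runs List of [proteomic_run()] objects; the
#'   (cell_line, method) pairs must be unique.
#' @return Object of class `evidence_matrix`: list with `presence`
#'   (logical matrix, sorted protein rows), `channel_kind` (`"genomic"`
#'   or `"proteomic"` per column).
#' @export
build_evidence_matrix <- function(genomic_sets, proteomic_runs) {
  if (is.null(names(genomic_sets)) || any(names(genomic_sets) == ""))
    stop("`genomic_sets` must be a named list (dataset ids)")
  if (anyDuplicated(names(genomic_sets)))
    stop("duplicate dataset id in `genomic_sets`")
  if (!all(vapply(proteomic_runs, inherits, logical(1), "proteomic_run")))
    stop("`proteomic_runs` must be proteomic_run objects")
  pm_labels <- vapply(proteomic_runs,
                      function(r) paste(r$cell_line, r$method, sep = ":"),
                      character(1))
  if (anyDuplicated(pm_labels))
    stop("duplicate (cell_line, method) pair in `proteomic_runs`")
  sets <- c(lapply(genomic_sets, function(s) unique(canonicalize(s))),
            stats::setNames(lapply(proteomic_runs, `[[`, "proteins"), pm_labels))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  presence <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
  if (length(universe) == 1L) presence <- matrix(presence, nrow = 1L,
                                                 dimnames = list(NULL, names(sets)))
  rownames(presence) <- universe
  structure(
    list(presence = presence,
         channel_kind = stats::setNames(
           rep(c("genomic", "proteomic"),
               c(length(genomic_sets), length(proteomic_runs))),
           colnames(presence))),
    class = "evidence_matrix"
  )
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf("evidence_matrix: %d proteins x %d channels (%d genomic, %d proteomic)\n",
              nrow(x$presence), ncol(x$presence),
              sum(x$channel_kind == "genomic"), sum(x$channel_kind == "proteomic")))
  invisible(x)
}

#' Score and rank candidate targets
#'
#' Each protein in the universe scores one point per channel in which it
#' is present (maximum = number of channels; nine in the default
#' design). The prerequisite requires presence in at least one genomic
#' and at least one proteomic channel: genomic presence guarantees
#' tumor-vs-normal differential expression, proteomic presence provides
#' a cell-line model for preclinical validation. Candidates are the
#' proteins passing the prerequisite (when required) with
#' `score >= min_score`, ranked by score descending, then genomic count
#' descending, then protein id; ranks are dense from 1.
#'
#' @param em An [build_evidence_matrix()] result.
#' @param min_score Minimum total score to report (default 5).
#' @param require_prerequisite Enforce the dual-evidence prerequisite
#'   (default TRUE).
#' @return Data frame with columns `protein`, `genomic_count`,
#'   `proteomic_count`, `score`, `passes_prerequisite`, `rank`,
#'   containing the selected candidates. The full per-protein scoring
#'   table (unfiltered, unranked) is attached as attribute
#'   `"all_scores"` so prerequisite failures remain visible.
#' @export
score_candidates <- function(em, min_score = 5L, require_prerequisite = TRUE) {
  stopifnot(inherits(em, "evidence_matrix"))
  gcols <- em$channel_kind == "genomic"
  gcount <- as.integer(rowSums(em$presence[, gcols, drop = FALSE]))
  pcount <- as.integer(rowSums(em$presence[, !gcols, drop = FALSE]))
  all_scores <- data.frame(
    protein = rownames(em$presence),
    genomic_count = gcount,
    proteomic_count = pcount,
    score = gcount + pcount,
    passes_prerequisite = gcount >= 1L & pcount >= 1L,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (min_score > ncol(em$presence)) {
    warning(sprintf("min_score %d exceeds the channel count %d; no candidate can qualify",
                    min_score, ncol(em$presence)))
  }
  keep <- all_scores$score >= min_score
  if (require_prerequisite) keep <- keep & all_scores$passes_prerequisite
  cand <- all_scores[keep, , drop = FALSE]
  ord <- order(-cand$score, -cand$genomic_count, cand$protein)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "all_scores") <- all_scores
  cand
}

#' Venn region counts for a family of sets
#'
#' Partitions the union of k sets (2 <= k <= 6) into its 2^k - 1 exact
#' membership regions and counts the elements in each; every element of
#' the union is counted in exactly one region. Regions are keyed by
#' their sorted member-set indices joined with `+` (e.g. `"1+3"`).
#'
#' @param sets List of k identifier vectors.
#' @return Named integer vector over all 2^k - 1 regions (zero counts
#'   included), ordered by region size then indices.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L) stop("need at least 2 sets")
  if (k > 6L) stop("at most 6 sets are supported")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  # all non-empty subsets of 1..k, ordered by size then lexicographically
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, paste, collapse = "+", simplify = FALSE)), use.names = FALSE)
  counts <- stats::setNames(integer(length(subsets)), subsets)
  if (length(universe) > 0L) {
    patterns <- apply(membership, 1, function(row)
      paste(which(row), collapse = "+"))
    tab <- table(patterns)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Per-channel and cross-cell-line presence summaries
#'
#' Mirrors the count tables that accompany multi-channel screens:
#' per-channel totals, the pairwise channel overlap table, and, for each
#' proteomic method, the number of proteins detected in every cell line
#' assayed with that method.
#'
#' @param em An [build_evidence_matrix()] result whose proteomic channel
#'   labels follow the `cell_line:method` convention.
#' @return List with `per_channel` (named totals), `pairwise` (channels
#'   x channels overlap matrix) and `method_core` (per proteomic
#'   method, the count of proteins present in all of its cell lines).
#' @export
channel_presence_report <- function(em) {
  stopifnot(inherits(em, "evidence_matrix"))
  pres <- em$presence
  per_channel <- colSums(pres)
  pairwise <- t(pres) %*% pres
  pm <- names(em$channel_kind)[em$channel_kind == "proteomic"]
  methods <- unique(sub("^.*:", "", pm))
  method_core <- stats::setNames(integer(length(methods)), methods)
  for (m in methods) {
    cols <- pm[sub("^.*:", "", pm) == m]
    method_core[m] <- sum(rowSums(pres[, cols, drop = FALSE]) == length(cols))
  }
  list(per_channel = per_channel, pairwise = pairwise, method_core = method_core)
}

#' Write the candidate table as TSV
#'
#' @param candidates Result of [score_candidates()].
#' @param path Output path.
#' @return Invisibly, `candidates`.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(candidates)
}
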
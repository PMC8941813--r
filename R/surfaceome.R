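#' Canonicalize gene/protein identifiers
#'
#' Strips surrounding whitespace and uppercases. Idempotent; vectorized.
#'
#' @param id Character vector of identifiers; empty (or all-whitespace)
#'   entries are an error.
#' @return Canonicalized character vector.
#' @export
canonicalize <- function(id) {
  if (length(id) == 0L) return(character(0))
  id <- as.character(id)
  out <- toupper(trimws(id))
  if (any(is.na(out) | out == ""))
    stop("empty identifier cannot be canonicalized")
  out
}

#' Surfaceome catalog of plasma-membrane proteins
#'
#' A local stand-in for a curated surface-protein database: a set of
#' (accession, gene symbol) pairs with lookup by either field. Symbols
#' are stored canonicalized (trimmed, uppercased); accessions are
#' trimmed but keep their case. Duplicate accessions are collapsed to
#' their first occurrence with a warning.
#'
#' @param accession Character vector of protein accessions.
#' @param gene_symbol Character vector of gene symbols, same length.
#' @return Object of class `surfaceome_catalog`: a data frame with
#'   columns `accession` and `gene_symbol`.
#' @export
surfaceome_catalog <- function(accession, gene_symbol) {
  if (length(accession) != length(gene_symbol))
    stop("`accession` and `gene_symbol` must have the same length")
  if (length(accession) == 0L) stop("catalog must not be empty")
  accession <- trimws(as.character(accession))
  gene_symbol <- canonicalize(gene_symbol)
  if (any(accession == "")) stop("empty accession in catalog")
  if (anyDuplicated(accession)) {
    warning(sprintf("%d duplicated accession(s) collapsed to first occurrence",
                    sum(duplicated(accession))))
    keep <- !duplicated(accession)
    accession <- accession[keep]
    gene_symbol <- gene_symbol[keep]
  }
  structure(
    data.frame(accession = accession, gene_symbol = gene_symbol,
               stringsAsFactors = FALSE),
    class = c("surfaceome_catalog", "data.frame")
  )
}

#' Read a surfaceome catalog from TSV
#'
#' Expects a header line `accession<TAB>gene_symbol`.
#'
#' @param path Path to the catalog TSV.
#' @param quiet Suppress the row-count message.
#' @return A [surfaceome_catalog()].
#' @export
read_catalog <- function(path, quiet = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("catalog file is empty")
  if (!all(c("accession", "gene_symbol") %in% names(tab)))
    stop(sprintf("catalog needs columns 'accession' and 'gene_symbol'; found: %s",
                 paste(names(tab), collapse = ", ")))
  if (!quiet) message(sprintf("read %d catalog rows from %s", nrow(tab), path))
  surfaceome_catalog(tab$accession, tab$gene_symbol)
}

#' Write a surfaceome catalog as TSV
#'
#' @param catalog A [surfaceome_catalog()].
#' @param path Output path.
#' @return Invisibly, `catalog`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalog)
}

#' Write an identifier set as a one-column TSV
#'
#' The dialect consumed by `surfscore score` for genomic channels: a
#' `gene_id` header followed by one identifier per line.
#'
#' @param genes Character vector of identifiers.
#' @param path Output path.
#' @return Invisibly, `genes`.
#' @export
write_gene_set_tsv <- function(genes, path) {
  utils::write.table(data.frame(gene_id = genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(genes)
}

#' Restrict an identifier set to catalog-annotated surface proteins
#'
#' An identifier is kept when its canonical form matches a catalog gene
#' symbol, or when it matches a catalog accession (trimmed exact form,
#' or canonical form for all-uppercase accessions). Matching by either
#' field reflects the mixed symbol/protein nomenclature of surface
#' proteins (e.g. SLC3A2 vs CD98hc accessions).
#'
#' @param genes Character vector of gene/protein identifiers.
#' @param catalog A [surfaceome_catalog()].
#' @return Unique canonicalized identifiers present in the catalog;
#'   always a subset of the canonicalized input.
#' @export
filter_surface <- function(genes, catalog) {
  stopifnot(inherits(catalog, "surfaceome_catalog"))
  if (length(genes) == 0L) return(character(0))
  canon <- canonicalize(genes)
  trimmed <- trimws(as.character(genes))
  hit <- canon %in% catalog$gene_symbol |
    trimmed %in% catalog$accession |
    canon %in% catalog$accession
  unique(canon[hit])
}
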
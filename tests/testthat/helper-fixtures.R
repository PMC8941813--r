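# Shared fixture builders. All fixtures are built in code; no data files.

# Small expression matrix from a plain matrix and group counts.
make_em <- function(values, n_tumor, n_normal, dataset_id = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  expression_matrix(values,
                    c(rep("tumor", n_tumor), rep("normal", n_normal)),
                    dataset_id)
}

# Random Gaussian expression matrix (all-null unless shifted by caller).
rand_em <- function(n_genes, n_tumor, n_normal, sd = 1, seed = 1) {
  set.seed(seed)
  make_em(matrix(rnorm(n_genes * (n_tumor + n_normal), 7, sd), n_genes),
          n_tumor, n_normal)
}

# Random evidence matrix fixture: k_g genomic + k_p proteomic channels
# over n proteins, each protein present in >= 1 channel.
rand_evidence <- function(n, k_g = 3, k_p = 6, seed = 1, p = 0.4) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  repeat {
    pres <- matrix(runif(n * (k_g + k_p)) < p, n)
    if (all(rowSums(pres) >= 1)) break
  }
  genomic <- lapply(seq_len(k_g), function(j) ids[pres[, j]])
  names(genomic) <- sprintf("DS%d", seq_len(k_g))
  runs <- list()
  idx <- k_g
  for (cl in sprintf("CL%d", seq_len(ceiling(k_p / 2)))) {
    for (m in c("membrane_enrichment", "biotinylation")) {
      if (idx >= k_g + k_p) break
      idx <- idx + 1
      runs[[length(runs) + 1]] <- proteomic_run(cl, m, ids[pres[, idx]])
    }
  }
  list(ids = ids, presence = pres, genomic = genomic, runs = runs)
}

quiet_pipeline <- function(...) suppressMessages(run_pipeline(...))
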
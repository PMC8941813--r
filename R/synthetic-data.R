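#' Configuration for the synthetic multi-omic study
#'
#' Describes the simulated world the pipeline is exercised on: three
#' tumor-vs-normal expression cohorts with planted upregulated genes,
#' and six proteomic presence channels (three cell lines x two surface
#' proteomics methods) with abundance-dependent detection and a small
#' non-surface contamination rate.
#'
#' Defaults describe a microarray-scale world: 2000 genes of which 15%
#' are surface proteins (roughly the human surfaceome fraction), 25
#' planted true targets with a +2 log2-unit tumor shift against a
#' within-group standard deviation of 0.5, and cohorts of 15 tumor vs 5
#' normal samples. An equal number of non-surface decoy genes receives
#' the same planted shift, so the surfaceome filter has something real
#' to remove.
#'
#' @param n_genes Number of genes (>= 1).
#' @param surface_fraction Fraction of genes that are surface proteins,
#'   in (0, 1).
#' @param n_planted Number of planted surface targets (and of
#'   non-surface decoys); must not exceed the surface gene count.
#' @param effect_delta Mean log2 shift added to planted/decoy genes in
#'   tumor samples.
#' @param sigma Within-group standard deviation (log2 units, > 0).
#' @param n_tumor,n_normal Per-dataset sample counts.
#' @param n_genomic_datasets Number of expression cohorts (default 3).
#' @param cell_lines Labels of the proteomic cell lines (default 3).
#' @param methods Labels of the proteomic methods (default
#'   `"membrane_enrichment"` and `"biotinylation"`).
#' @param detect_slope,detect_intercept Logistic detection parameters:
#'   a surface protein with standardized latent abundance `a` is
#'   detected with probability `plogis(detect_intercept +
#'   detect_slope * a)`.
#' @param contamination_rate Probability that a non-surface protein
#'   appears in a proteomic channel, in `[0, 1]`.
#' @param seed Integer seed; every generator in the module is a
#'   deterministic function of (config, seed).
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000L,
                              surface_fraction = 0.15,
                              n_planted = 25L,
                              effect_delta = 2,
                              sigma = 0.5,
                              n_tumor = 15L,
                              n_normal = 5L,
                              n_genomic_datasets = 3L,
                              cell_lines = c("MDAMB231", "BT549", "HS578T"),
                              methods = c("membrane_enrichment", "biotinylation"),
                              detect_slope = 1.5,
                              detect_intercept = 1,
                              contamination_rate = 0.02,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              surface_fraction = surface_fraction,
              n_planted = as.integer(n_planted),
              effect_delta = effect_delta, sigma = sigma,
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_genomic_datasets = as.integer(n_genomic_datasets),
              cell_lines = as.character(cell_lines),
              methods = as.character(methods),
              detect_slope = detect_slope, detect_intercept = detect_intercept,
              contamination_rate = contamination_rate,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid simulation config: `%s` %s", field, why))
  chk(cfg$n_genes >= 1L, "n_genes", "must be >= 1")
  chk(is.numeric(cfg$surface_fraction) &&
        cfg$surface_fraction > 0 && cfg$surface_fraction < 1,
      "surface_fraction", "must be in (0, 1)")
  chk(cfg$n_planted >= 1L, "n_planted", "must be >= 1")
  chk(cfg$n_planted <= floor(cfg$n_genes * cfg$surface_fraction),
      "n_planted", "must not exceed the surface gene count")
  chk(is.numeric(cfg$sigma) && cfg$sigma > 0, "sigma", "must be > 0")
  chk(cfg$n_tumor >= 1L, "n_tumor", "must be >= 1")
  chk(cfg$n_normal >= 1L, "n_normal", "must be >= 1")
  chk(cfg$n_genomic_datasets >= 1L, "n_genomic_datasets", "must be >= 1")
  chk(length(cfg$cell_lines) >= 1L && !anyDuplicated(cfg$cell_lines),
      "cell_lines", "must be a non-empty set of unique labels")
  chk(length(cfg$methods) >= 1L && !anyDuplicated(cfg$methods),
      "methods", "must be a non-empty set of unique labels")
  chk(is.numeric(cfg$contamination_rate) &&
        cfg$contamination_rate >= 0 && cfg$contamination_rate <= 1,
      "contamination_rate", "must be in [0, 1]")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

#' Generate a synthetic surfaceome catalog with ground truth
#'
#' Deterministically (given the config seed) partitions the gene
#' universe into surface and non-surface genes, assigns each surface
#' gene a unique accession, draws the per-gene latent abundance
#' `mu_g ~ Normal(7, 1)` (log2 units, a typical microarray baseline),
#' and plants `n_planted` true targets among the surface genes plus the
#' same number of upregulated non-surface decoys.
#'
#' @param config A [simulation_config()].
#' @return List with `catalog` (a [surfaceome_catalog()] of the surface
#'   genes) and `truth`: a list with `gene_ids`, `surface_genes`,
#'   `planted_targets`, `decoy_targets` and the named `abundance`
#'   vector (the baseline means, reused by both omics layers).
#' @export
generate_surfaceome_catalog <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))
  n_surface <- round(config$n_genes * config$surface_fraction)
  surface <- sort(sample(gene_ids, n_surface))
  non_surface <- setdiff(gene_ids, surface)
  planted <- sort(sample(surface, config$n_planted))
  decoys <- sort(sample(non_surface, min(config$n_planted, length(non_surface))))
  abundance <- stats::setNames(stats::rnorm(config$n_genes, 7, 1), gene_ids)
  accession <- sprintf("SA%05d", match(surface, gene_ids))
  list(
    catalog = surfaceome_catalog(accession, surface),
    truth = list(gene_ids = gene_ids, surface_genes = surface,
                 planted_targets = planted, decoy_targets = decoys,
                 abundance = abundance)
  )
}

#' Simulate one tumor-vs-normal expression cohort
#'
#' Gene g, sample s is `Normal(mu_g + delta * planted(g) * tumor(s),
#' sigma^2)` where `mu_g` is the shared latent baseline from
#' [generate_surfaceome_catalog()] and `planted(g)` is true for planted
#' surface targets and non-surface decoys alike. The noise stream is
#' seeded with `seed + dataset_index`, so each cohort is independent of
#' the others yet reproducible in isolation.
#'
#' @param config A [simulation_config()].
#' @param dataset_index Cohort number in `1..n_genomic_datasets`.
#' @param truth Optional ground truth from
#'   [generate_surfaceome_catalog()]; regenerated from `config` when
#'   omitted (it is itself deterministic).
#' @return An [expression_matrix()] with dataset id `"DS<k>"`.
#' @export
simulate_expression_dataset <- function(config, dataset_index, truth = NULL) {
  validate_simulation_config(config)
  if (dataset_index < 1L || dataset_index > config$n_genomic_datasets)
    stop("`dataset_index` must be in 1..n_genomic_datasets")
  if (config$n_tumor < 2L || config$n_normal < 2L)
    stop("need n_tumor >= 2 and n_normal >= 2 (group variance undefined otherwise)")
  if (is.null(truth)) truth <- generate_surfaceome_catalog(config)$truth
  set.seed(config$seed + as.integer(dataset_index))
  n_s <- config$n_tumor + config$n_normal
  groups <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
  shift_gene <- truth$gene_ids %in% c(truth$planted_targets, truth$decoy_targets)
  mu <- matrix(truth$abundance, config$n_genes, n_s)
  mu[shift_gene, groups == "tumor"] <- mu[shift_gene, groups == "tumor"] +
    config$effect_delta
  values <- mu + matrix(stats::rnorm(config$n_genes * n_s, 0, config$sigma),
                        config$n_genes, n_s)
  dataset_id <- sprintf("DS%d", dataset_index)
  sample_ids <- sprintf("%s_%s%02d", dataset_id,
                        ifelse(groups == "tumor", "T", "N"),
                        c(seq_len(config$n_tumor), seq_len(config$n_normal)))
  dimnames(values) <- list(truth$gene_ids, sample_ids)
  expression_matrix(values, groups, dataset_id)
}

#' Simulate one proteomic identification run
#'
#' A surface protein with standardized latent abundance `a` is detected
#' with probability `plogis(detect_intercept + detect_slope * a)`; each
#' non-surface protein is included as contamination with probability
#' `contamination_rate`. The stream is seeded with
#' `seed + 1000 + 10 * cell_line_index + method_index`, so any single
#' run is reproducible in isolation.
#'
#' @param config A [simulation_config()].
#' @param cell_line,method Labels drawn from the config lists.
#' @param truth Optional ground truth (regenerated when omitted).
#' @return A [proteomic_run()]; the full identification table
#'   (`protein_id`, `gene_symbol`, `cell_line`, `method`) is attached
#'   as attribute `"table"`.
#' @export
simulate_proteomic_run <- function(config, cell_line, method, truth = NULL) {
  validate_simulation_config(config)
  li <- match(cell_line, config$cell_lines)
  mi <- match(method, config$methods)
  if (is.na(li)) stop(sprintf("unknown cell line '%s'", cell_line))
  if (is.na(mi)) stop(sprintf("unknown method '%s'", method))
  gen <- if (is.null(truth)) generate_surfaceome_catalog(config)$truth else truth
  catalog_acc <- stats::setNames(sprintf("SA%05d", match(gen$surface_genes, gen$gene_ids)),
                                 gen$surface_genes)
  set.seed(config$seed + 1000L + 10L * li + mi)
  ab <- gen$abundance
  ab_std <- (ab - mean(ab)) / stats::sd(ab)
  surface <- gen$surface_genes
  p_detect <- stats::plogis(config$detect_intercept +
                              config$detect_slope * ab_std[surface])
  detected <- surface[stats::runif(length(surface)) < p_detect]
  non_surface <- setdiff(gen$gene_ids, surface)
  contam <- non_surface[stats::runif(length(non_surface)) < config$contamination_rate]
  ids <- c(detected, contam)
  tab <- data.frame(
    protein_id = c(unname(catalog_acc[detected]), contam),
    gene_symbol = ids,
    cell_line = rep(cell_line, length(ids)),
    method = rep(method, length(ids)),
    stringsAsFactors = FALSE
  )
  run <- proteomic_run(cell_line, method, tab$gene_symbol)
  attr(run, "table") <- tab
  run
}

#' Simulate the full multi-omic study
#'
#' Convenience wrapper: generates the catalog and ground truth, all
#' expression cohorts, and all (cell line x method) proteomic runs.
#'
#' @param config A [simulation_config()].
#' @return List with `catalog`, `truth`, `expression` (list of
#'   [expression_matrix()]) and `proteomic_runs` (list of
#'   [proteomic_run()]).
#' @export
simulate_study <- function(config) {
  gen <- generate_surfaceome_catalog(config)
  expression <- lapply(seq_len(config$n_genomic_datasets),
                       function(i) simulate_expression_dataset(config, i, gen$truth))
  runs <- list()
  for (cl in config$cell_lines)
    for (m in config$methods)
      runs[[paste(cl, m, sep = ":")]] <-
        simulate_proteomic_run(config, cl, m, gen$truth)
  list(catalog = gen$catalog, truth = gen$truth,
       expression = expression, proteomic_runs = runs)
}

#' Write a proteomic run as TSV
#'
#' @param run A [proteomic_run()] carrying a `"table"` attribute (as
#'   produced by [simulate_proteomic_run()]), or any run (a minimal
#'   table is synthesized from its protein set).
#' @param path Output path.
#' @return Invisibly, `run`.
#' @export
write_proteomic_run_tsv <- function(run, path) {
  tab <- attr(run, "table")
  if (is.null(tab))
    tab <- data.frame(protein_id = run$proteins, gene_symbol = run$proteins,
                      cell_line = run$cell_line, method = run$method,
                      stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(run)
}

#' Write the simulation ground truth as JSON
#'
#' @param truth Ground truth from [generate_surfaceome_catalog()].
#' @param path Output path.
#' @return Invisibly, `truth`.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(surface_genes = truth$surface_genes,
         planted_targets = truth$planted_targets,
         decoy_targets = truth$decoy_targets,
         abundance = as.list(truth$abundance)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(truth)
}
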
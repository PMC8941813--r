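# Non-cryptographic rolling hash (FNV-style) of a deparsed R object;
# enough to make the recorded hash change whenever a config field does.
config_hash <- function(config) {
  txt <- paste(deparse(config, control = c("exact")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  mod <- 2^31 - 1
  for (b in bytes) h <- (h * 131 + b) %% mod
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Either a simulation block (a [simulation_config()]) or the full set
#' of real-input paths (expression + metadata TSVs, proteomic run TSVs,
#' catalog TSV) must be supplied.
#'
#' @param simulation A [simulation_config()], or a plain list of its
#'   arguments, or `NULL` when real inputs are given.
#' @param expression List of `list(expr=, meta=, id=)` path triples, one
#'   per dataset (ignored when simulating).
#' @param proteomic Character vector of proteomic-run TSV paths.
#' @param catalog Path to the surfaceome catalog TSV.
#' @param stat `"moderated"` (default) or `"ordinary"` test statistic.
#' @param p_max,lfc_min,use_adjusted,lfc_units Differential-expression
#'   thresholds, see [select_upregulated()].
#' @param normalize Quantile-normalize each expression matrix first
#'   (default TRUE).
#' @param min_score,require_prerequisite Scoring options, see
#'   [score_candidates()].
#' @param seed Integer seed; overrides the simulation block's seed.
#' @param out_dir Output directory (optional; no files written if NULL).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, expression = NULL,
                            proteomic = NULL, catalog = NULL,
                            stat = c("moderated", "ordinary"),
                            p_max = 0.05, lfc_min = 1.5,
                            use_adjusted = FALSE,
                            lfc_units = c("log2", "fold"),
                            normalize = TRUE,
                            min_score = 5L, require_prerequisite = TRUE,
                            seed = 1L, out_dir = NULL) {
  stat <- match.arg(stat)
  lfc_units <- match.arg(lfc_units)
  if (p_max <= 0 || lfc_min <= 0) stop("thresholds must be positive")
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, simulation)
  if (!is.null(simulation)) {
    simulation$seed <- as.integer(seed)
  } else if (is.null(expression) || is.null(proteomic) || is.null(catalog)) {
    stop("supply either a `simulation` block or all of `expression`, `proteomic` and `catalog`")
  }
  structure(
    list(simulation = simulation, expression = expression,
         proteomic = proteomic, catalog = catalog,
         stat = stat, p_max = p_max, lfc_min = lfc_min,
         use_adjusted = use_adjusted, lfc_units = lfc_units,
         normalize = normalize,
         min_score = as.integer(min_score),
         require_prerequisite = require_prerequisite,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON (or YAML)
#'
#' JSON is always supported; `.yaml`/`.yml` files are parsed when the
#' optional yaml package is installed.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    raw <- yaml::read_yaml(path)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.data.frame(raw$expression))
    raw$expression <- split(raw$expression, seq_len(nrow(raw$expression)))
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[surfscore] %-12s %6.2fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full target-prioritization pipeline
#'
#' Simulation (optional) -> quantile normalization -> per-dataset
#' differential expression -> upregulation filter -> surfaceome filter
#' -> proteomic surfaceome filter -> evidence matrix -> scoring ->
#' report. Deterministic given the config and seed. When `out_dir` is
#' set, writes `candidates.tsv`, `de_<dataset>.tsv`, `venn.json` and
#' `report.json` there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; defaults to the config's.
#' @return A run report: list with per-dataset filter counts
#'   (`datasets`), per-channel proteomic counts, universe size, the
#'   candidate table, Venn region counts of the genomic surface sets,
#'   and provenance (config hash, seed, timestamp).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    study <- run_stage("simulate", simulate_study(config$simulation))
    expr_list <- study$expression
    runs <- study$proteomic_runs
    catalog <- study$catalog
  } else {
    loaded <- run_stage("load", {
      expr_list <- lapply(config$expression, function(e)
        read_expression_tsv(e$expr, e$meta,
                            dataset_id = if (!is.null(e$id)) e$id else
                              sub("\\.tsv$", "", basename(e$expr))))
      runs <- lapply(config$proteomic, read_proteomic_run_tsv)
      list(expr = expr_list, runs = runs,
           catalog = read_catalog(config$catalog, quiet = TRUE))
    })
    expr_list <- loaded$expr; runs <- loaded$runs; catalog <- loaded$catalog
  }

  de_tables <- list()
  genomic_sets <- list()
  dataset_counts <- list()
  for (em in expr_list) {
    id <- em$dataset_id
    de <- run_stage(paste0("diffexp:", id), {
      em2 <- collapse_duplicate_genes(
        if (config$normalize) quantile_normalize(em) else em)
      de <- if (config$stat == "moderated") moderated_t(em2) else ordinary_t(em2)
      de$q <- bh_adjust(de$p)
      de
    })
    up <- select_upregulated(de, config$p_max, config$lfc_min,
                             config$use_adjusted, config$lfc_units)
    surf_up <- filter_surface(up, catalog)
    de_tables[[id]] <- de
    genomic_sets[[id]] <- surf_up
    dataset_counts[[id]] <- data.frame(
      dataset = id, tested = nrow(de), upregulated = length(up),
      surface_upregulated = length(surf_up), stringsAsFactors = FALSE)
  }

  evidence <- run_stage("evidence", {
    runs_f <- lapply(runs, function(r)
      proteomic_run(r$cell_line, r$method, filter_surface(r$proteins, catalog)))
    build_evidence_matrix(genomic_sets, runs_f)
  })
  candidates <- run_stage("score",
    score_candidates(evidence, config$min_score, config$require_prerequisite))
  venn <- if (length(genomic_sets) >= 2L && length(genomic_sets) <= 6L)
    venn_counts(genomic_sets) else NULL

  datasets <- do.call(rbind, dataset_counts)
  rownames(datasets) <- NULL
  report <- list(
    datasets = datasets,
    proteomic_counts = colSums(
      evidence$presence[, evidence$channel_kind == "proteomic", drop = FALSE]),
    universe_size = nrow(evidence$presence),
    n_candidates = nrow(candidates),
    candidates = candidates,
    venn = venn,
    provenance = list(config_hash = config_hash(unclass(config)),
                      seed = config$seed,
                      timestamp = format(Sys.time(), tz = "UTC"),
                      package_version = as.character(utils::packageVersion("surfscore")))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    for (id in names(de_tables))
      write_de_tsv(de_tables[[id]], file.path(out_dir, sprintf("de_%s.tsv", id)))
    if (!is.null(venn))
      jsonlite::write_json(as.list(venn), file.path(out_dir, "venn.json"),
                           auto_unbox = TRUE)
    jsonlite::write_json(
      report[c("datasets", "proteomic_counts", "universe_size",
               "n_candidates", "candidates", "provenance")],
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
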
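small_cfg <- function(...) {
  simulation_config(n_genes = 200L, surface_fraction = 0.2, n_planted = 10L,
                    n_tumor = 6L, n_normal = 4L, seed = 1L, ...)
}

test_that("simulation config validation names the offending field", {
  expect_s3_class(small_cfg(), "simulation_config")
  expect_error(small_cfg(surface_fraction = 1.5), "surface_fraction")
  expect_error(small_cfg(sigma = 0), "sigma")
  expect_error(small_cfg(n_planted = 1000), "n_planted")
  expect_error(small_cfg(contamination_rate = -0.1), "contamination_rate")
  expect_error(simulation_config(n_genes = 0), "n_genes")
})

test_that("catalog generation is seeded, sized, and internally consistent", {
  cfg <- simulation_config(n_genes = 100L, surface_fraction = 0.2,
                           n_planted = 5L, seed = 1L)
  gen <- generate_surfaceome_catalog(cfg)
  expect_equal(nrow(gen$catalog), 20)  # round(100 * 0.2)
  expect_false(anyDuplicated(gen$catalog$accession) > 0)
  expect_false(anyDuplicated(gen$catalog$gene_symbol) > 0)
  # planted targets are surface genes; decoys are not
  expect_true(all(gen$truth$planted_targets %in% gen$truth$surface_genes))
  expect_false(any(gen$truth$decoy_targets %in% gen$truth$surface_genes))
  expect_true(all(is.finite(gen$truth$abundance)))

  # same config, same seed -> identical output
  gen2 <- generate_surfaceome_catalog(cfg)
  expect_identical(gen, gen2)
  # different seed -> different surface set (with overwhelming probability)
  gen3 <- generate_surfaceome_catalog(
    simulation_config(n_genes = 100L, surface_fraction = 0.2,
                      n_planted = 5L, seed = 2L))
  expect_false(identical(gen$truth$surface_genes, gen3$truth$surface_genes))
})

test_that("expression simulation is seeded and plants the stated shift", {
  cfg <- small_cfg(effect_delta = 2, sigma = 0.5)
  em1 <- simulate_expression_dataset(cfg, 1)
  em1b <- simulate_expression_dataset(cfg, 1)
  expect_identical(em1$values, em1b$values)  # bit-identical
  em2 <- simulate_expression_dataset(cfg, 2)
  expect_false(identical(em1$values, em2$values))
  expect_error(simulate_expression_dataset(cfg, 9), "dataset_index")
  expect_error(
    simulate_expression_dataset(small_cfg(n_normal = 1L), 1),
    "n_normal")

  # planted genes (targets + decoys) carry the mean shift; others do not
  truth <- generate_surfaceome_catalog(cfg)$truth
  planted <- c(truth$planted_targets, truth$decoy_targets)
  lfc <- log_fold_change(em1)
  expect_gt(min(lfc[planted]), 0.5)     # delta = 2, noise sd ~0.32
  expect_lt(max(abs(lfc[setdiff(names(lfc), planted)])), 1.5)
})

test_that("high power regime: every planted gene passes the filter", {
  cfg <- simulation_config(n_genes = 300L, surface_fraction = 0.2,
                           n_planted = 15L, effect_delta = 2.5, sigma = 0.5,
                           n_tumor = 10L, n_normal = 10L, seed = 5L)
  truth <- generate_surfaceome_catalog(cfg)$truth
  em <- simulate_expression_dataset(cfg, 1, truth)
  sel <- select_upregulated(ordinary_t(em))
  planted <- c(truth$planted_targets, truth$decoy_targets)
  expect_true(all(planted %in% sel))  # power ~ 1 at delta = 5 sigma
})

test_that("proteomic simulation respects its limit parameters", {
  cfg <- small_cfg(detect_slope = 0, detect_intercept = 20,
                   contamination_rate = 0)
  truth <- generate_surfaceome_catalog(cfg)$truth
  run <- simulate_proteomic_run(cfg, cfg$cell_lines[1], cfg$methods[1], truth)
  # saturated logistic: every surface protein detected, contamination off
  expect_setequal(run$proteins, truth$surface_genes)

  cfg0 <- small_cfg(detect_slope = 0, detect_intercept = -20,
                    contamination_rate = 0)
  run0 <- simulate_proteomic_run(cfg0, cfg0$cell_lines[1], cfg0$methods[1])
  expect_length(run0$proteins, 0)

  expect_error(simulate_proteomic_run(cfg, "NOT_A_LINE", cfg$methods[1]),
               "cell line")
  expect_error(simulate_proteomic_run(cfg, cfg$cell_lines[1], "sonication"),
               "method")

  # determinism per (cell line, method); different channels differ
  r1 <- simulate_proteomic_run(cfg0, cfg0$cell_lines[1], cfg0$methods[2])
  r2 <- simulate_proteomic_run(cfg0, cfg0$cell_lines[1], cfg0$methods[2])
  expect_identical(r1$proteins, r2$proteins)
})

test_that("empirical detection frequency follows the logistic curve", {
  # one large simulated proteome, binomial check within each abundance bin
  cfg <- simulation_config(n_genes = 4000L, surface_fraction = 0.5,
                           n_planted = 10L, detect_slope = 1.5,
                           detect_intercept = 0.5, contamination_rate = 0,
                           seed = 11L)
  truth <- generate_surfaceome_catalog(cfg)$truth
  run <- simulate_proteomic_run(cfg, cfg$cell_lines[1], cfg$methods[1], truth)
  ab <- truth$abundance
  ab_std <- (ab - mean(ab)) / sd(ab)
  surface <- truth$surface_genes
  bins <- cut(ab_std[surface], breaks = c(-Inf, -1, -0.3, 0.3, 1, Inf))
  for (b in levels(bins)) {
    genes <- surface[bins == b]
    p_mean <- mean(plogis(0.5 + 1.5 * ab_std[genes]))
    phat <- mean(genes %in% run$proteins)
    se <- sqrt(p_mean * (1 - p_mean) / length(genes))
    expect_lt(abs(phat - p_mean), 4 * se + 0.02)
  }
})

test_that("contamination is bounded and absent when turned off", {
  cfg <- small_cfg(contamination_rate = 0.5, detect_intercept = 20,
                   detect_slope = 0)
  truth <- generate_surfaceome_catalog(cfg)$truth
  run <- simulate_proteomic_run(cfg, cfg$cell_lines[2], cfg$methods[1], truth)
  contam <- setdiff(run$proteins, truth$surface_genes)
  n_non <- length(setdiff(truth$gene_ids, truth$surface_genes))
  # binomial(n_non, 0.5) within 4 SE
  expect_lt(abs(length(contam) / n_non - 0.5), 4 * sqrt(0.25 / n_non))

  cfg0 <- small_cfg(contamination_rate = 0)
  run0 <- simulate_proteomic_run(cfg0, cfg0$cell_lines[2], cfg0$methods[1])
  expect_length(setdiff(run0$proteins, truth$surface_genes), 0)
})

test_that("study writers round-trip through the TSV/JSON dialects", {
  cfg <- small_cfg()
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()

  cf <- file.path(dir, "catalog.tsv")
  write_catalog_tsv(study$catalog, cf)
  expect_equal(read_catalog(cf, quiet = TRUE), study$catalog)

  run <- study$proteomic_runs[[1]]
  rf <- file.path(dir, "run.tsv")
  write_proteomic_run_tsv(run, rf)
  back <- read_proteomic_run_tsv(rf)
  expect_equal(back$proteins, run$proteins)
  expect_equal(back$cell_line, run$cell_line)

  tf <- file.path(dir, "truth.json")
  write_ground_truth_json(study$truth, tf)
  truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_setequal(truth$planted_targets, study$truth$planted_targets)
})
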
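## a small, fast configuration used across generator tests
smallConfig <- function(seed = 1, ...) {
  args <- list(n_tfs = 12L, n_genes = 150L, targets_per_tf = 5,
               n_cell_lines = 12L, n_drivers = 6L, n_core_drivers = 3L,
               n_background_proteins = 40L, n_patients = 60L,
               n_cancer_specific = 5L, n_decoys = 2L,
               secreted_size = 12L, transmembrane_size = 15L,
               n_cohorts = 1L, patients_per_cohort = 30L,
               n_survival_genes = 3L, rng_seed = seed)
  do.call(syntheticConfig, utils::modifyList(args, list(...)))
}

test_that("configuration validation names the offending field", {
  expect_error(syntheticConfig(replicates_per_line = 4), "replicates_per_line")
  expect_error(syntheticConfig(phenotype_props = c(cancer = 0.5,
                 inflammation = 0.3, healthy = 0.3)), "phenotype_props")
  expect_error(syntheticConfig(censoring_rate = 1), "censoring_rate")
  expect_error(syntheticConfig(n_tfs = 0), "n_tfs")
  expect_error(syntheticConfig(n_drivers = 200), "n_drivers")
  expect_error(syntheticConfig(banana = 1), "banana")
})

test_that("catalogue generation covers saturation and scale", {
  ## single TF with targets_per_tf = n_genes targets the whole pool
  cfg1 <- syntheticConfig(n_tfs = 1L, n_genes = 30L, targets_per_tf = 30,
                          n_drivers = 1L, n_core_drivers = 1L, rng_seed = 1)
  cat1 <- generateCatalogue(cfg1)
  expect_length(targetsOf(cat1, "TF001"), 29)  # every gene but itself
  ## determinism under a fixed seed
  cfg <- smallConfig(7)
  expect_identical(catalogueEntries(generateCatalogue(cfg)),
                   catalogueEntries(generateCatalogue(cfg)))
  ## catalogue-scale run: 345 TFs x ~20 targets gives ~6,800 regulations
  cfgBig <- syntheticConfig(n_tfs = 345L, n_genes = 2650L,
                            targets_per_tf = 20, rng_seed = 3)
  n <- nrow(catalogueEntries(generateCatalogue(cfgBig)))
  expect_gt(n, 6500); expect_lt(n, 7300)
  ## every TF keeps at least one target
  expect_length(tfUniverse(generateCatalogue(cfg)), 12)
})

test_that("zero-noise limit ties driver activity to its inputs exactly", {
  cfg <- smallConfig(4, b1 = 0, b2 = 1, activity_noise_sd = 0)
  cl <- generateCellLineData(generateCatalogue(cfg), cfg)
  dr <- cl$truth$driver_tfs
  expect_equal(cl$activity[dr, ], cl$cnv[dr, ], tolerance = 1e-12)
})

test_that("an active driver shifts its targets in the replicate columns", {
  cfg <- smallConfig(5, response_base = 1, response_gain = 0,
                     replicate_noise_sd = 0, target_shift = 4)
  catalogue <- generateCatalogue(cfg)
  cl <- generateCellLineData(catalogue, cfg)
  act <- cl$activity
  thr <- apply(act, 1, quantile, probs = cfg$activation_quantile)
  dr <- cl$truth$driver_tfs[1]
  line <- colnames(act)[which(act[dr, ] > thr[dr])[1]]
  v <- SummarizedExperiment::assay(cl$expression)
  map <- cellLines(cl$expression)
  ## replicate columns of the active line sit well above the per-gene median
  for (g in targetsOf(catalogue, dr)) {
    delta <- v[g, map == line] - median(v[g, ])
    expect_true(all(delta > cfg$target_shift / 2))
  }
})

test_that("cell-line generation is bit-reproducible under a seed", {
  cfg <- smallConfig(9)
  catalogue <- generateCatalogue(cfg)
  a <- generateCellLineData(catalogue, cfg)
  b <- generateCellLineData(catalogue, cfg)
  expect_identical(SummarizedExperiment::assay(a$expression),
                   SummarizedExperiment::assay(b$expression))
  expect_identical(a$regions, b$regions)
  expect_identical(a$truth$driver_tfs, b$truth$driver_tfs)
  expect_identical(a$truth$survival_genes, b$truth$survival_genes)
})

test_that("planted biomarkers are targets of core drivers, sets cover them", {
  cfg <- smallConfig(2)
  catalogue <- generateCatalogue(cfg)
  cl <- generateCellLineData(catalogue, cfg)
  truth <- cl$truth
  coreTargets <- targetsOf(catalogue, truth$core_drivers)
  expect_true(all(truth$cancer_specific_genes %in% coreTargets))
  expect_true(all(truth$decoy_genes %in% coreTargets))
  expect_length(intersect(truth$cancer_specific_genes, truth$decoy_genes), 0)
  expect_true(all(rownames(truth$survival_genes) %in%
                  truth$cancer_specific_genes))
  ann <- generateAnnotationSets(catalogue, truth, cfg)
  allSet <- unique(unlist(ann$sets))
  expect_true(all(truth$cancer_specific_genes %in% allSet))
  expect_true(all(truth$decoy_genes %in% allSet))
  expect_true(all(ann$truth$background_genes %in% allSet))
  expect_true(all(universalBiomarkers(truth) %in%
                  truth$cancer_specific_genes))
})

test_that("PPI module wiring follows the configured densities", {
  cfg <- smallConfig(3, ppi_p1 = 1, ppi_p0 = 0)
  catalogue <- generateCatalogue(cfg)
  truth <- generateCellLineData(catalogue, cfg)$truth
  ppi <- generatePpi(truth, cfg)
  g <- ppiGraph(ppi$network)
  core <- ppi$truth$core_drivers
  ## p1 = 1: the core drivers form a clique
  for (p in combn(core, 2, simplify = FALSE))
    expect_true(igraph::are_adjacent(g, p[1], p[2]))
  ## p0 = 0: every edge touches the planted module
  el <- igraph::as_edgelist(g)
  expect_true(all(el[, 1] %in% ppi$truth$module_nodes &
                  el[, 2] %in% ppi$truth$module_nodes))
  expect_true(all(igraph::E(g)$evidence >= 2))
  ## module must be denser than background
  expect_error(generatePpi(truth, smallConfig(3, ppi_p1 = 0.005)),
               "denser")
})

test_that("patient cohorts follow the 78/8/14 split and planted shifts", {
  cfg <- smallConfig(6, n_patients = 500L)
  catalogue <- generateCatalogue(cfg)
  truth <- generateCellLineData(catalogue, cfg)$truth
  genes <- syntheticGeneUniverse(cfg)$genes[1:50]
  pc <- generatePatientCohort(genes, truth, cfg)
  expect_equal(as.vector(table(factor(pc$phenotypes$phenotype,
                                      c("cancer", "inflammation",
                                        "healthy")))),
               c(390, 40, 70))
  ## zero effect size with recovery assertions on warns
  expect_warning(generatePatientCohort(genes, truth,
                                       smallConfig(6, cancer_shift = 0)),
                 "cancer_shift")
  ## decoys are shifted in cancer and (more strongly) inflammation
  cfg2 <- smallConfig(8, n_patients = 2000L)
  dg <- truth$decoy_genes[1]
  pc2 <- generatePatientCohort(c(dg, "TF001"), truth, cfg2)
  v <- SummarizedExperiment::assay(pc2$cohort)
  ph <- unname(phenotypes(pc2$cohort))
  expect_gt(mean(v[dg, ph == "inflammation"]) - mean(v[dg, ph == "healthy"]),
            2)
  expect_gt(mean(v[dg, ph == "cancer"]) - mean(v[dg, ph == "healthy"]),
            0.3)
})

test_that("survival cohorts censor at the configured rate and plant hazards", {
  cfg <- smallConfig(10, censoring_rate = 0, patients_per_cohort = 200L)
  catalogue <- generateCatalogue(cfg)
  truth <- generateCellLineData(catalogue, cfg)$truth
  genes <- rownames(truth$survival_genes)
  sc <- generateSurvivalCohort(genes, truth, cfg, cohort = 1)
  expect_true(all(sc$clinical$event == 1))      # no censoring
  expect_true(all(sc$clinical$time > 0))
  cfg2 <- smallConfig(10, censoring_rate = 0.5, patients_per_cohort = 400L)
  sc2 <- generateSurvivalCohort(genes, truth, cfg2, cohort = 1)
  expect_gt(mean(sc2$clinical$event == 0), 0.2)  # censoring present
  expect_error(generateSurvivalCohort(genes, truth,
               smallConfig(1, censoring_rate = -0.1)), "censoring_rate")
})

test_that("null-gene rejection rates are unchanged by label permutation", {
  set.seed(123)
  nSim <- 200
  rej <- matrix(FALSE, nSim, 2)
  ph <- rep(c("cancer", "inflammation", "healthy"), c(40, 10, 14))
  for (i in seq_len(nSim)) {
    x <- rnorm(64)
    for (arm in 1:2) {
      lab <- if (arm == 1) ph else sample(ph)
      p <- t.test(x[lab == "cancer"], x[lab != "cancer"])$p.value
      rej[i, arm] <- p <= 0.05
    }
  }
  ## two-sided binomial comparison of the two arms' rejection counts
  ct <- colSums(rej)
  p <- fisher.test(rbind(ct, nSim - ct))$p.value
  expect_gt(p, 0.01)
})
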
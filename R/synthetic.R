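## Synthetic-data generator: every pipeline input with planted ground truth,
## so each downstream stage can be validated without external downloads.

## Evaluate `expr` under a temporary RNG state seeded with `seed` (restoring
## the caller's stream), or with the ambient stream when seed is NULL.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(expr)
}

.cfgStop <- function(field, why)
  stop("invalid configuration: '", field, "' ", why, call. = FALSE)

#' Configuration of the synthetic study
#'
#' Defaults define the study conditions emulated by the generator: a panel
#' of cancer cell lines profiled in duplicate, a regulation catalogue whose
#' driver TFs have latent activity `b1*expression + b2*CNV + noise`
#' (thresholded at an activation quantile to shift their targets), a PPI
#' module densely wiring the drivers, a patient cohort with 78% cancer / 8%
#' inflammation / 14% healthy samples, and survival cohorts with
#' expression-dependent hazards.
#'
#' @param ... overrides of the default fields, e.g. `n_tfs`, `n_genes`,
#'   `targets_per_tf`, `n_cell_lines`, `replicates_per_line` (2 or 3),
#'   `n_drivers`, `b1`, `b2`, `activity_noise_sd`, `activation_quantile`,
#'   `target_shift`, `replicate_noise_sd`, `null_activity`,
#'   `n_background_proteins`, `n_hubs`, `ppi_p0`, `ppi_p1`, `ppi_hub_p`,
#'   `phenotype_props`, `n_patients`, `cancer_shift`, `decoy_cancer_shift`,
#'   `decoy_infl_shift`, `inflammation_sd`, `n_cancer_specific`, `n_decoys`,
#'   `n_cohorts`, `patients_per_cohort`, `log_hr`, `n_survival_genes`,
#'   `latent_loading`, `censoring_rate`, `rng_seed`.  Unknown names are an
#'   error.
#' @return Validated list of class `synthetic_config`.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    ## catalogue / cell-line panel
    n_tfs = 140L, n_genes = 5000L, targets_per_tf = 30,
    n_cell_lines = 180L, replicates_per_line = 3L, n_drivers = 80L,
    n_core_drivers = 10L,
    ## latent lineage structure shared by expression, CNV and activation
    n_factors_expr = 4L, n_factors_cnv = 4L, factor_loading = 0.97,
    ## driver mechanism
    b1 = 1, b2 = 1, activity_noise_sd = 0.2, activation_quantile = 0.85,
    response_base = 0.6, response_gain = 0.5,
    target_shift = 3, replicate_noise_sd = 0.5, line_noise_sd = 0.4,
    baseline_mean = 7, cnv_sd = 1, cnv_tf_fraction = 0.9,
    null_activity = FALSE,
    ## interactome
    n_background_proteins = 300L, n_hubs = 2L,
    ppi_p0 = 0.01, ppi_p1 = 0.95, ppi_spoke_k = 3L, ppi_hub_k = 4L,
    ## patient cohort
    phenotype_props = c(cancer = 0.78, inflammation = 0.08, healthy = 0.14),
    n_patients = 1000L, cancer_shift = 1.15, decoy_cancer_shift = 0.8,
    decoy_infl_shift = 5, inflammation_sd = 6,
    background_cancer_shift = 0.65, background_fraction = 0.85,
    n_cancer_specific = 25L, n_decoys = 2L,
    secreted_size = 90L, transmembrane_size = 110L,
    expect_recovery = TRUE,
    ## survival cohorts
    n_cohorts = 2L, patients_per_cohort = 350L, log_hr = log(3),
    n_survival_genes = 12L, latent_loading = 0.8, censoring_rate = 0.3,
    rng_seed = NULL)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(cfg, ov)
  counts <- c("n_tfs", "n_genes", "n_cell_lines", "n_drivers",
              "n_background_proteins", "n_patients", "n_cohorts",
              "patients_per_cohort")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      .cfgStop(f, "must be a positive count")
  if (!cfg$replicates_per_line %in% c(2L, 3L))
    .cfgStop("replicates_per_line", "must be 2 or 3")
  if (cfg$n_genes <= cfg$n_tfs)
    .cfgStop("n_genes", "must exceed n_tfs (target pool would be empty)")
  if (cfg$n_drivers > cfg$n_tfs)
    .cfgStop("n_drivers", "cannot exceed n_tfs")
  if (cfg$n_core_drivers > cfg$n_drivers)
    .cfgStop("n_core_drivers", "cannot exceed n_drivers")
  if (abs(sum(cfg$phenotype_props) - 1) > 1e-8)
    .cfgStop("phenotype_props", "must sum to 1")
  if (!all(names(cfg$phenotype_props) == .PHENOTYPES))
    .cfgStop("phenotype_props",
             "must be named cancer, inflammation, healthy")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    .cfgStop("censoring_rate", "must lie in [0, 1)")
  if (cfg$activation_quantile <= 0 || cfg$activation_quantile >= 1)
    .cfgStop("activation_quantile", "must lie in (0, 1)")
  if (cfg$latent_loading <= 0 || cfg$latent_loading > 1)
    .cfgStop("latent_loading", "must lie in (0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Gene and TF identifier universe of a configuration
#'
#' A TF's protein node and its encoding gene share the same id; non-TF
#' genes fill up the universe to `n_genes`.
#'
#' @param config a [syntheticConfig()] object.
#' @return List with `tfs`, `other_genes`, `genes` (the full universe).
#' @export
syntheticGeneUniverse <- function(config) {
  tfs <- sprintf("TF%03d", seq_len(config$n_tfs))
  other <- sprintf("G%04d", seq_len(config$n_genes - config$n_tfs))
  list(tfs = tfs, other_genes = other, genes = c(tfs, other))
}

#' Planted ground truth of a synthetic study
#'
#' @param driver_tfs TFs planted as correlatively regulated.
#' @param tf_universe all TF ids.
#' @param core_drivers the most richly annotated drivers; they anchor the
#'   planted PPI module and the planted biomarkers are drawn from their
#'   targets.
#' @param module_nodes proteins in the planted PPI module (filled by
#'   [generatePpi()]).
#' @param cancer_specific_genes genes strongly shifted in cancer patients
#'   only (the planted biomarker pool).
#' @param decoy_genes genes shifted in both cancer and inflammation.
#' @param background_genes accessible genes carrying a moderate cancer-only
#'   shift (the broad tumor dysregulation background; filled by
#'   [generateAnnotationSets()]).
#' @param survival_genes numeric matrix gene x cohort of planted log hazard
#'   ratios per expression SD.
#' @return List of class `ground_truth`.
#' @export
groundTruth <- function(driver_tfs, tf_universe,
                        core_drivers = driver_tfs,
                        module_nodes = character(0),
                        cancer_specific_genes = character(0),
                        decoy_genes = character(0),
                        background_genes = character(0),
                        survival_genes = matrix(0, 0, 0)) {
  stopifnot(all(driver_tfs %in% tf_universe),
            all(core_drivers %in% driver_tfs),
            length(intersect(cancer_specific_genes, decoy_genes)) == 0L)
  structure(list(driver_tfs = driver_tfs, tf_universe = tf_universe,
                 core_drivers = core_drivers,
                 module_nodes = module_nodes,
                 cancer_specific_genes = cancer_specific_genes,
                 decoy_genes = decoy_genes,
                 background_genes = background_genes,
                 survival_genes = survival_genes),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth:\n",
      " drivers:", length(x$driver_tfs),
      "| module nodes:", length(x$module_nodes),
      "| cancer-specific:", length(x$cancer_specific_genes),
      "| decoys:", length(x$decoy_genes),
      "| survival genes:", nrow(x$survival_genes), "\n")
  invisible(x)
}

#' Planted universal biomarkers
#'
#' Genes carrying every planted property at once: targets of driver TFs,
#' annotated secreted/transmembrane, shifted in cancer patients only, and
#' hazard-associated in at least one survival cohort.
#'
#' @param truth a [groundTruth()] object.
#' @return Character vector of gene ids.
#' @export
universalBiomarkers <- function(truth) {
  sg <- truth$survival_genes
  if (nrow(sg) == 0L) return(character(0))
  rownames(sg)[rowSums(sg != 0) > 0]
}

#' Generate a synthetic regulation catalogue
#'
#' Each TF draws `targets_per_tf` targets on average (Poisson, at least 1)
#' without replacement from the non-TF gene pool.
#'
#' @param config a [syntheticConfig()] object.
#' @return A [RegulationCatalogue-class].
#' @export
generateCatalogue <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- syntheticGeneUniverse(config)
  pool <- if (config$n_tfs == 1L) setdiff(ids$genes, ids$tfs)
          else ids$other_genes
  .withSeed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 101L, {
    sizes <- pmin(length(pool),
                  pmax(1L, rpois(config$n_tfs, config$targets_per_tf)))
    if (config$targets_per_tf >= length(pool))
      sizes[] <- length(pool)  # saturation: every TF targets the whole pool
    entries <- do.call(rbind, lapply(seq_len(config$n_tfs), function(i)
      data.frame(tf = ids$tfs[i], target = sample(pool, sizes[i]))))
    RegulationCatalogue(entries)
  })
}

## Toy genome: genes laid consecutively on autosomes, 400 genes per
## chromosome, 1 kb spacing, 800 bp gene bodies (0-based half-open).
.syntheticLocations <- function(genes) {
  i <- seq_along(genes) - 1L
  data.frame(gene = genes, chrom = paste0("chr", i %/% 400L + 1L),
             start = (i %% 400L) * 1000L,
             end = (i %% 400L) * 1000L + 800L)
}

#' Generate cell-line expression, CNV regions and ground truth
#'
#' Cell lines carry latent lineage factors that structure TF expression and
#' locus CNV (co-expression and co-amplification patterns).  For each driver
#' TF `t` and cell line `s` a latent activity
#' `a(t,s) = b1*expr(t,s) + b2*cnv(t,s) + noise` is drawn; when it exceeds
#' the TF's activation quantile the TF is active in that line and each of
#' its catalogue targets responds (receives an expression shift of
#' `target_shift`) with a probability that grows with the activity excess.
#' Non-driver TFs receive activity of the same marginal distribution but
#' independent of their expression and CNV.  Replicate columns share the
#' cell-line value plus replicate noise.  GISTIC-style regions cover the
#' altered TF loci (drivers always, and `cnv_tf_fraction` of the others)
#' and carry the planted per-line CNV values; decoy regions
#' (non-significant, or significant but covering no gene) exercise the
#' filters.
#'
#' @param catalogue a [RegulationCatalogue-class] from [generateCatalogue()].
#' @param config a [syntheticConfig()] object.
#' @return List: `expression` ([LineExpression-class]), `regions` (table for
#'   [geneCnvMatrix()]), `locations`, `truth` ([groundTruth()]), plus the
#'   planted `activity` and `cnv` matrices for diagnostics.
#' @export
generateCellLineData <- function(catalogue, config) {
  stopifnot(is(catalogue, "RegulationCatalogue"),
            inherits(config, "synthetic_config"))
  if (config$n_drivers < 1L)
    .cfgStop("n_drivers", "at least one driver TF is required")
  ids <- syntheticGeneUniverse(config)
  tfs <- intersect(ids$tfs, tfUniverse(catalogue))
  if (length(tfs) == 0L) stop("catalogue shares no TFs with the universe")
  .withSeed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 202L, {
    L <- config$n_cell_lines
    lines <- sprintf("L%03d", seq_len(L))
    drivers <- sort(sample(tfs, min(config$n_drivers, length(tfs))))
    ## core drivers: the most richly annotated drivers anchor the planted
    ## PPI module and the biomarker targets
    nTargets <- table(factor(catalogueEntries(catalogue)$tf, levels = tfs))
    core <- drivers[order(-as.integer(nTargets[drivers]),
                          runif(length(drivers)))]
    core <- sort(core[seq_len(min(config$n_core_drivers, length(core)))])
    genes <- ids$genes
    nG <- length(genes)
    ## latent lineage factors
    lam <- matrix(rnorm(length(tfs) * config$n_factors_expr),
                  length(tfs), config$n_factors_expr)
    lam <- lam / sqrt(rowSums(lam^2))
    mus <- matrix(rnorm(length(tfs) * config$n_factors_cnv),
                  length(tfs), config$n_factors_cnv)
    mus <- mus / sqrt(rowSums(mus^2))
    fac <- matrix(rnorm(config$n_factors_expr * L), ncol = L)
    hac <- matrix(rnorm(config$n_factors_cnv * L), ncol = L)
    w <- config$factor_loading
    ## line-level expression: per-gene baseline + line noise; TF rows get
    ## the factor structure (unit marginal variance)
    mu <- config$baseline_mean + rnorm(nG)
    lineExpr <- matrix(mu + rnorm(nG * L, 0, config$line_noise_sd),
                       nG, L, dimnames = list(genes, lines))
    tfIdx <- match(tfs, genes)
    lineExpr[tfIdx, ] <- mu[tfIdx] + w * (lam %*% fac) +
      sqrt(1 - w^2) * matrix(rnorm(length(tfs) * L), length(tfs), L)
    ## planted CNV: driver loci always altered; most other TF loci too
    ## (independently of their activity), mirroring the pervasive alteration
    ## of DNA-binding loci across cancer cell lines
    nonDrivers <- setdiff(tfs, drivers)
    altered <- c(drivers,
                 sample(nonDrivers,
                        round(config$cnv_tf_fraction * length(nonDrivers))))
    cnvTrue <- matrix(0, nG, L, dimnames = list(genes, lines))
    aIdx <- match(altered, tfs)
    cnvTrue[altered, ] <- config$cnv_sd *
      (w * (mus[aIdx, , drop = FALSE] %*% hac) +
       sqrt(1 - w^2) * matrix(rnorm(length(altered) * L),
                              length(altered), L))
    ## latent activity
    sdA <- sqrt(config$b1^2 + config$b2^2 * config$cnv_sd^2 +
                config$activity_noise_sd^2)
    act <- matrix(rnorm(length(tfs) * L, 0, sdA), length(tfs), L,
                  dimnames = list(tfs, lines))
    if (!config$null_activity) {
      act[drivers, ] <-
        config$b1 * (lineExpr[drivers, ] - mu[match(drivers, genes)]) +
        config$b2 * cnvTrue[drivers, ] +
        rnorm(length(drivers) * L, 0, config$activity_noise_sd)
    }
    thr <- apply(act, 1L, quantile, probs = config$activation_quantile)
    active <- act > thr
    ## graded target response per (TF, line)
    targetsByTf <- split(catalogueEntries(catalogue)$target,
                         catalogueEntries(catalogue)$tf)
    for (l in seq_len(L)) {
      on <- rownames(active)[active[, l]]
      if (length(on) == 0L) next
      sh <- unique(unlist(lapply(on, function(tf) {
        tg <- targetsByTf[[tf]]
        pi <- min(1, config$response_base +
                  config$response_gain * (act[tf, l] - thr[tf]))
        tg[runif(length(tg)) < pi]
      })))
      lineExpr[sh, l] <- lineExpr[sh, l] + config$target_shift
    }
    ## replicate columns
    r <- config$replicates_per_line
    repCols <- paste0(rep(lines, each = r), "_r", seq_len(r))
    vals <- lineExpr[, rep(seq_len(L), each = r)] +
      rnorm(nG * L * r, 0, config$replicate_noise_sd)
    dimnames(vals) <- list(genes, repCols)
    expr <- LineExpression(vals, rep(lines, each = r))
    ## locations and regions (narrow peaks, one per altered TF locus, so
    ## neighboring loci keep their own values)
    locations <- .syntheticLocations(genes)
    regionRows <- lapply(altered, function(d) {
      loc <- locations[locations$gene == d, ]
      v <- cnvTrue[d, ]
      cbind(data.frame(chrom = loc$chrom, start = max(0L, loc$start - 50L),
                       end = loc$end + 50L,
                       region_id = paste0("REG_", d),
                       type = if (mean(v) >= 0) "amp" else "del",
                       q = round(runif(1, 0, 0.1), 4)),
            as.data.frame(as.list(setNames(round(v, 4), lines))))
    })
    ## decoys: one non-significant region and one significant region in
    ## gene-free space between chromosomes' tails
    decoyGene <- sample(setdiff(ids$other_genes,
                                targetsOf(catalogue, drivers)), 1L)
    dl <- locations[locations$gene == decoyGene, ]
    regionRows <- c(regionRows, list(
      cbind(data.frame(chrom = dl$chrom, start = dl$start, end = dl$end,
                       region_id = "REG_NONSIG", type = "amp",
                       q = round(runif(1, 0.3, 0.9), 4)),
            as.data.frame(as.list(setNames(round(rnorm(L, 0, 0.5), 4),
                                           lines)))),
      cbind(data.frame(chrom = "chr1", start = 399L * 1000L + 900L,
                       end = 399L * 1000L + 950L,
                       region_id = "REG_EMPTY", type = "del",
                       q = round(runif(1, 0, 0.1), 4)),
            as.data.frame(as.list(setNames(round(rnorm(L, 0, 0.5), 4),
                                           lines))))))
    regions <- do.call(rbind, regionRows)
    rownames(regions) <- NULL
    ## planted biomarker genes among core-driver targets, preferring genes
    ## targeted by several core drivers (robust to a missed driver)
    dt <- catalogueEntries(catalogue)
    dt <- dt$target[dt$tf %in% core]
    mult <- table(dt)
    ranked <- names(mult)[order(-as.integer(mult), runif(length(mult)))]
    nCS <- min(config$n_cancer_specific, length(ranked))
    cs <- ranked[seq_len(nCS)]
    rest <- setdiff(ranked, cs)
    decoys <- rest[seq_len(min(config$n_decoys, length(rest)))]
    nS <- min(config$n_survival_genes, length(cs))
    sgenes <- sample(cs, nS)
    sg <- matrix(0, nS, config$n_cohorts,
                 dimnames = list(sgenes,
                                 sprintf("cohort%d", seq_len(config$n_cohorts))))
    for (i in seq_len(nS)) {
      k <- sample(config$n_cohorts,
                  min(config$n_cohorts, 1L + rbinom(1L, 1L, 0.7)))
      sg[i, k] <- config$log_hr
    }
    truth <- groundTruth(driver_tfs = drivers, tf_universe = ids$tfs,
                         core_drivers = core,
                         cancer_specific_genes = cs, decoy_genes = decoys,
                         survival_genes = sg)
    list(expression = expr, regions = regions, locations = locations,
         truth = truth, activity = act, cnv = cnvTrue)
  })
}

#' Generate a synthetic PPI network with a planted module
#'
#' Erdos-Renyi background at edge probability `ppi_p0` over all proteins
#' (TFs plus background proteins plus hub intermediates).  The planted
#' module wires the core drivers into a near-clique at `ppi_p1 >> ppi_p0`,
#' attaches every other driver to `ppi_spoke_k` random core drivers
#' (spokes), and connects each hub intermediate to `ppi_hub_k` core
#' drivers, so that the core drivers dominate betweenness within the
#' module.  All evidence counts are at least 2 so the curated evidence
#' filter keeps the graph intact.
#'
#' @param truth a [groundTruth()] (drivers, core drivers, TF universe).
#' @param config a [syntheticConfig()] object.
#' @return List: `network` ([PpiNetwork-class]) and `truth` with
#'   `module_nodes` filled (drivers plus hubs).
#' @export
generatePpi <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  if (length(truth$driver_tfs) == 0L)
    .cfgStop("n_drivers", "module seed set is empty")
  if (config$ppi_p1 <= config$ppi_p0)
    .cfgStop("ppi_p1", "module must be denser than background (ppi_p1 > ppi_p0)")
  .withSeed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 303L, {
    hubs <- if (config$n_hubs > 0) sprintf("HUB%d", seq_len(config$n_hubs))
            else character(0)
    nodes <- c(truth$tf_universe,
               sprintf("P%04d", seq_len(config$n_background_proteins)), hubs)
    pairs <- t(utils::combn(nodes, 2L))
    keep <- runif(nrow(pairs)) < config$ppi_p0
    edges <- data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
                        evidence = 2L + rpois(sum(keep), 1))
    modEdge <- function(a, b)
      data.frame(a = a, b = b, evidence = 3L + rpois(length(a), 2))
    core <- truth$core_drivers
    spokes <- setdiff(truth$driver_tfs, core)
    if (length(core) >= 2L) {
      cp <- t(utils::combn(core, 2L))
      on <- runif(nrow(cp)) < config$ppi_p1
      if (any(on)) edges <- rbind(edges, modEdge(cp[on, 1L], cp[on, 2L]))
    }
    for (s in spokes) {
      k <- min(config$ppi_spoke_k, length(core))
      edges <- rbind(edges, modEdge(rep(s, k), sample(core, k)))
    }
    for (h in hubs) {
      k <- min(config$ppi_hub_k, length(core))
      edges <- rbind(edges, modEdge(rep(h, k), sample(core, k)))
    }
    truth$module_nodes <- c(truth$driver_tfs, hubs)
    list(network = PpiNetwork(edges, nodes = nodes), truth = truth)
  })
}

#' Generate secreted/transmembrane annotation sets
#'
#' The planted cancer-specific genes and decoys are split between the
#' `secreted` and `transmembrane` sets (so the accessible-gene filter keeps
#' them); the sets are filled up with unplanted driver targets and random
#' genes.  A `background_fraction` of the fillers is marked in the ground
#' truth as carrying a moderate cancer-only dysregulation (the broad tumor
#' response seen in real accessible target genes); the rest remain null.
#'
#' @param catalogue the [RegulationCatalogue-class].
#' @param truth a [groundTruth()] object.
#' @param config a [syntheticConfig()] object.
#' @return List with `sets` (named gene sets `secreted`, `transmembrane`)
#'   and `truth` with `background_genes` filled.
#' @export
generateAnnotationSets <- function(catalogue, truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  .withSeed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 404L, {
    planted <- c(truth$cancer_specific_genes, truth$decoy_genes)
    half <- seq_along(planted) %% 2L == 1L
    ids <- syntheticGeneUniverse(config)
    ## fill preferentially with core-driver targets: the annotation sets
    ## should cover the central targets (that is where accessible
    ## candidates come from downstream), then other driver targets
    core <- setdiff(targetsOf(catalogue, truth$core_drivers), planted)
    dt <- setdiff(targetsOf(catalogue, truth$driver_tfs),
                  c(planted, core))
    filler <- c(sample(core), sample(dt),
                sample(setdiff(ids$other_genes, c(planted, core, dt))))
    sec <- planted[half]
    tm <- planted[!half]
    nSec <- max(0L, config$secreted_size - length(sec))
    sec <- c(sec, filler[seq_len(min(nSec, length(filler)))])
    filler <- setdiff(filler, sec)
    nTm <- max(0L, config$transmembrane_size - length(tm))
    tm <- c(tm, filler[seq_len(min(nTm, length(filler)))])
    fillerUsed <- setdiff(c(sec, tm), planted)
    truth$background_genes <-
      sort(sample(fillerUsed,
                  round(config$background_fraction * length(fillerUsed))))
    list(sets = list(secreted = sort(sec), transmembrane = sort(tm)),
         truth = truth)
  })
}

#' Generate a patient cohort with planted cancer-specific shifts
#'
#' Phenotype counts follow the configured proportions (78/8/14 by default,
#' rounded).  Cancer-specific genes are shifted by `cancer_shift` in cancer
#' samples only; background genes carry the moderate
#' `background_cancer_shift` in cancer only; decoy genes are shifted in
#' cancer (`decoy_cancer_shift`) and, more strongly, in inflammation
#' (`decoy_infl_shift`); all other genes are null.  Inflammation samples
#' carry larger biological variance (`inflammation_sd`), reflecting the
#' heterogeneity of inflammatory and septic expression profiles.
#'
#' @param genes genes to emit (rows).
#' @param truth a [groundTruth()] object.
#' @param config a [syntheticConfig()] object.
#' @return List: `cohort` ([PatientCohort-class]) and `phenotypes`
#'   (data.frame `sample`, `phenotype`).
#' @export
generatePatientCohort <- function(genes, truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  if (config$cancer_shift == 0 && config$expect_recovery)
    warning("cancer_shift is 0: planted genes cannot be recovered ",
            "(set expect_recovery = FALSE to silence)")
  .withSeed(if (is.null(config$rng_seed)) NULL else config$rng_seed + 505L, {
    n <- config$n_patients
    pr <- config$phenotype_props
    nc <- round(pr[["cancer"]] * n); ni <- round(pr[["inflammation"]] * n)
    nh <- n - nc - ni
    ph <- rep(.PHENOTYPES, c(nc, ni, nh))
    samples <- sprintf("S%04d", seq_len(n))
    nG <- length(genes)
    sds <- ifelse(ph == "inflammation", config$inflammation_sd, 1)
    v <- 8 + matrix(rnorm(nG * n, 0, rep(sds, each = nG)), nG, n,
                    dimnames = list(genes, samples))
    cs <- intersect(truth$cancer_specific_genes, genes)
    v[cs, ph == "cancer"] <- v[cs, ph == "cancer"] + config$cancer_shift
    bg <- intersect(truth$background_genes, genes)
    v[bg, ph == "cancer"] <-
      v[bg, ph == "cancer"] + config$background_cancer_shift
    dc <- intersect(truth$decoy_genes, genes)
    v[dc, ph == "cancer"] <- v[dc, ph == "cancer"] + config$decoy_cancer_shift
    v[dc, ph == "inflammation"] <-
      v[dc, ph == "inflammation"] + config$decoy_infl_shift
    list(cohort = PatientCohort(v, ph),
         phenotypes = data.frame(sample = samples, phenotype = ph))
  })
}

#' Generate a survival cohort with expression-dependent hazards
#'
#' Event times are exponential with log-hazard linear in a patient frailty
#' shared by the cohort's planted survival genes: each planted gene's
#' standardized expression loads on the frailty with `latent_loading`, so
#' its marginal log hazard ratio per expression SD equals the planted value
#' in `truth$survival_genes`.  Censoring is independent (exponential) at
#' approximately the configured rate.
#'
#' @param genes genes to emit (rows).
#' @param truth a [groundTruth()] object.
#' @param config a [syntheticConfig()] object.
#' @param cohort cohort index (column of `truth$survival_genes`).
#' @return List: `expr` (genes x patients matrix), `clinical` (data.frame
#'   `patient`, `time`, `event`), `cohort` (label).
#' @export
generateSurvivalCohort <- function(genes, truth, config, cohort = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  if (config$censoring_rate < 0 || config$censoring_rate >= 1)
    .cfgStop("censoring_rate", "must lie in [0, 1)")
  .withSeed(if (is.null(config$rng_seed)) NULL
            else config$rng_seed + 606L + cohort, {
    n <- config$patients_per_cohort
    patients <- sprintf("C%dP%03d", cohort, seq_len(n))
    nG <- length(genes)
    v <- matrix(rnorm(nG * n), nG, n, dimnames = list(genes, patients))
    sg <- truth$survival_genes
    active <- if (nrow(sg) > 0 && cohort <= ncol(sg))
      intersect(rownames(sg)[sg[, cohort] != 0], genes) else character(0)
    u <- rnorm(n)
    lam <- config$latent_loading
    for (g in active)
      v[g, ] <- lam * u + sqrt(1 - lam^2) * rnorm(n)
    theta <- if (length(active) > 0) sg[active[1L], cohort] else 0
    h0 <- 1 / 365
    rate <- h0 * exp((theta / lam) * u)
    T <- rexp(n, rate)
    cr <- config$censoring_rate
    if (cr > 0) {
      C <- rexp(n, h0 * cr / (1 - cr))
      time <- pmin(T, C); event <- as.integer(T <= C)
    } else {
      time <- T; event <- rep(1L, n)
    }
    list(expr = 8 + v,
         clinical = data.frame(patient = patients, time = time,
                               event = event),
         cohort = sprintf("cohort%d", cohort))
  })
}

#' Generate the full synthetic study
#'
#' Convenience wrapper calling every generator in order with a shared
#' configuration (and a single `rng_seed` fanned out to per-generator child
#' streams).
#'
#' @param config a [syntheticConfig()] object.
#' @return List with `config`, `catalogue`, `cellline` (expression, regions,
#'   locations, diagnostics), `ppi`, `sets`, `patient`, `cohorts` (one
#'   [generateSurvivalCohort()] result per cohort) and `truth`.
#' @export
generateSyntheticStudy <- function(config = syntheticConfig()) {
  catalogue <- generateCatalogue(config)
  cl <- generateCellLineData(catalogue, config)
  ppi <- generatePpi(cl$truth, config)
  ann <- generateAnnotationSets(catalogue, ppi$truth, config)
  sets <- ann$sets
  truth <- ann$truth
  genes <- syntheticGeneUniverse(config)$genes
  patient <- generatePatientCohort(genes, truth, config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(k)
    generateSurvivalCohort(genes, truth, config, cohort = k))
  names(cohorts) <- vapply(cohorts, `[[`, "", "cohort")
  list(config = config, catalogue = catalogue, cellline = cl,
       ppi = ppi$network, sets = sets, patient = patient,
       cohorts = cohorts, truth = truth)
}
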
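## End-to-end pipeline: TF activity -> CNV profiles -> TF selection -> MCN
## (significance + negative control) -> central targets -> accessible filter
## -> cancer specificity -> survival screen, with a threshold manifest and a
## plain-text log, resumable from on-disk stage outputs.

.PIPELINE_THRESHOLDS <- c(evalue_max = 10, q_max = 0.25, alpha = 0.05,
                          alpha_bh = 0.05, min_evidence = 2, n_random = 1000,
                          n_control_lists = 100, top_k = 10, rng_seed = 1)

#' Read a flat key=value pipeline configuration file
#'
#' Recognized keys: the input paths `expression`, `sample_map`, `catalogue`,
#' `regions`, `gene_locations`, `ppi`, `annotation_sets`,
#' `patient_expression`, `phenotypes`, `cohort_names` (comma-separated) with
#' per-cohort `<name>_expression` / `<name>_clinical`; the thresholds
#' `evalue_max`, `q_max`, `alpha`, `alpha_bh`, `min_evidence`, `n_random`,
#' `n_control_lists`, `top_k`, `rng_seed`; and `out_dir`.  Unknown keys are
#' an error (they are almost always typos in threshold names).
#'
#' @param path configuration file path.
#' @return Named list (class `pipeline_config`).
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  cfg <- as.list(setNames(vals, keys))
  pathKeys <- c("expression", "sample_map", "catalogue", "regions",
                "gene_locations", "ppi", "annotation_sets",
                "patient_expression", "phenotypes", "out_dir")
  cohorts <- if (!is.null(cfg$cohort_names))
    strsplit(cfg$cohort_names, ",", fixed = TRUE)[[1L]] else character(0)
  cohortKeys <- c(paste0(cohorts, "_expression"),
                  paste0(cohorts, "_clinical"))
  known <- c(pathKeys, "cohort_names", cohortKeys,
             names(.PIPELINE_THRESHOLDS))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (k in intersect(names(.PIPELINE_THRESHOLDS), names(cfg)))
    cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in setdiff(names(.PIPELINE_THRESHOLDS), names(cfg)))
    cfg[[k]] <- .PIPELINE_THRESHOLDS[[k]]
  cfg$cohort_names <- cohorts
  structure(cfg, class = "pipeline_config")
}

#' Cross-check identifier namespaces and conventions of loaded inputs
#'
#' Verifies that the expression genes cover catalogue targets, that the
#' catalogue TFs are measured and (at least partly) present in the
#' interactome, that CNV samples match the expression cell lines, that the
#' location table covers the measured genes, and that every patient column
#' has a phenotype.  Unmapped identifiers produce warnings (mirroring the
#' loss of seeds absent from a curated interactome); empty intersections
#' are fatal.
#'
#' @param inputs named list with elements `expression`
#'   ([LineExpression-class]), `catalogue`, `ppi`, `regions`, `locations`,
#'   and optionally `patient` (matrix), `phenotypes` (named vector),
#'   `sets`.
#' @return data.frame report (`level`, `check`, `detail`), invisibly when
#'   everything is clean.
#' @export
validateInputs <- function(inputs) {
  rep <- list()
  note <- function(level, check, detail)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, check = check,
                                           detail = detail)
  genes <- rownames(assay(inputs$expression))
  targets <- targetUniverse(inputs$catalogue)
  tfs <- tfUniverse(inputs$catalogue)
  if (length(intersect(genes, targets)) == 0L)
    stop("fatal: no catalogue target is measured in the expression matrix")
  nt <- sum(!targets %in% genes)
  if (nt > 0)
    note("warning", "catalogue_targets",
         paste0(nt, " catalogue target(s) not measured"))
  ntf <- sum(!tfs %in% genes)
  if (ntf > 0)
    note("warning", "tf_expression",
         paste0(ntf, " TF-encoding gene(s) not measured"))
  ppiNodes <- igraph::V(ppiGraph(inputs$ppi))$name
  if (length(intersect(tfs, ppiNodes)) == 0L)
    stop("fatal: no catalogue TF maps onto the interactome")
  nm <- sum(!tfs %in% ppiNodes)
  if (nm > 0)
    note("warning", "tf_interactome",
         paste0(nm, " of ", length(tfs),
                " TF(s) absent from the interactome"))
  lines <- unique(unname(cellLines(inputs$expression)))
  rs <- .regionSamples(inputs$regions)
  if (length(intersect(lines, rs)) == 0L)
    stop("fatal: CNV samples share no ids with the expression cell lines")
  if (!setequal(lines, rs))
    note("warning", "cnv_samples", "CNV and expression sample sets differ")
  nl <- sum(!genes %in% inputs$locations$gene)
  if (nl > 0)
    note("warning", "gene_locations",
         paste0(nl, " measured gene(s) without a location"))
  if (!is.null(inputs$patient)) {
    ph <- inputs$phenotypes
    mis <- setdiff(colnames(inputs$patient), names(ph))
    if (length(mis) > 0)
      stop("fatal: patient column(s) without phenotype: ",
           paste(mis, collapse = ", "))
    absent <- setdiff(.PHENOTYPES, unique(unname(ph)))
    if (length(absent) > 0)
      note("warning", "phenotypes",
           paste0("phenotype(s) absent: ", paste(absent, collapse = ", ")))
  }
  out <- if (length(rep) > 0) do.call(rbind, rep)
         else data.frame(level = character(0), check = character(0),
                         detail = character(0))
  for (i in seq_len(nrow(out)))
    warning(out$check[i], ": ", out$detail[i], call. = FALSE)
  if (nrow(out) == 0L) invisible(out) else out
}

#' Run the full biomarker-prioritization pipeline
#'
#' Executes, in order: per-line differential genes + TF scores, gene-level
#' CNV matrix, correlation-profile regression + TF selection, MCN extraction
#' with KS significance and the random-list negative control, central-TF
#' target collection + accessible (secreted/transmembrane) filter, patient
#' cancer-specificity, and the tertile survival screen.  Every stage writes
#' its output under `out_dir`; `manifest.txt` records every threshold and
#' stage file, `pipeline.log` the stage-by-stage progress.  With
#' `resume = TRUE` a stage whose output files already exist is reloaded
#' instead of recomputed.
#'
#' @param config a `pipeline_config` (from [readPipelineConfig()]) or the
#'   path of a configuration file.
#' @param outDir output directory; defaults to `config$out_dir`.
#' @param resume reuse existing stage outputs (default `FALSE`).
#' @return Invisibly, a list with the key results: `scores`, `cnv`, `fits`,
#'   `selected`, `mcn` ([McnResult-class]), `negative_control`, `central`,
#'   `accessible`, `cancer_specific`, `screen`, `biomarkers`, `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL, resume = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is.null(outDir)) outDir <- config$out_dir
  if (is.null(outDir)) stop("an output directory is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline.log")
  logLines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  out <- function(f) file.path(outDir, f)
  seed <- as.integer(config$rng_seed)

  say("stage input: reading inputs")
  expr <- readExpression(config$expression, config$sample_map)
  catalogue <- readCatalogue(config$catalogue)
  regions <- readRegions(config$regions)
  locations <- readGeneLocations(config$gene_locations)
  ppi <- readPpi(config$ppi)
  sets <- readGmt(config$annotation_sets)
  patient <- readMatrixTsv(config$patient_expression)
  phen <- readPhenotypes(config$phenotypes)
  cohorts <- lapply(config$cohort_names, function(cn)
    list(expr = readMatrixTsv(config[[paste0(cn, "_expression")]]),
         clinical = readClinical(config[[paste0(cn, "_clinical")]])))
  names(cohorts) <- config$cohort_names
  suppressWarnings(
    validateInputs(list(expression = expr, catalogue = catalogue,
                        ppi = ppi, regions = regions, locations = locations,
                        patient = patient, phenotypes = phen, sets = sets)))

  genes <- rownames(assay(expr))
  lines <- unique(unname(cellLines(expr)))

  ## stage 1: TF activity ---------------------------------------------------
  if (resume && file.exists(out("tf_scores.tsv"))) {
    say("stage tf_activity: resumed from tf_scores.tsv")
    scores <- readMatrixTsv(out("tf_scores.tsv"))
  } else {
    say("stage tf_activity: differential genes (e-value <= ",
        config$evalue_max, ") and enrichment scores")
    regulated <- lapply(lines, function(l)
      differentialGenes(expr, l, evalueMax = config$evalue_max))
    names(regulated) <- lines
    say("  median regulated genes per line: ",
        median(lengths(regulated)))
    scores <- tfScores(catalogue, regulated, universe = genes)
    writeMatrixTsv(scores, out("tf_scores.tsv"))
  }

  ## stage 2: CNV profiles --------------------------------------------------
  if (resume && file.exists(out("cnv_matrix.tsv"))) {
    say("stage cnv_profiles: resumed from cnv_matrix.tsv")
    cnv <- readMatrixTsv(out("cnv_matrix.tsv"))
  } else {
    say("stage cnv_profiles: gene-level CNV matrix (q <= ", config$q_max, ")")
    cnv <- geneCnvMatrix(regions, locations, samples = lines,
                         qMax = config$q_max)
    writeMatrixTsv(cnv, out("cnv_matrix.tsv"))
  }

  ## stage 3: TF selection --------------------------------------------------
  if (resume && file.exists(out("fits.tsv")) &&
      file.exists(out("selected_tfs.txt"))) {
    say("stage tf_select: resumed")
    fits <- read.delim(out("fits.tsv"))
    selected <- readLines(out("selected_tfs.txt"))
  } else {
    say("stage tf_select: correlation profiles and per-TF regression")
    profiles <- correlationProfiles(scores, expr, cnv)
    fits <- fitTfModels(profiles)
    selected <- selectTfs(fits, alpha = config$alpha)
    say("  ", length(selected), " TF(s) selected at alpha = ", config$alpha)
    fitsOut <- fits
    for (cn in c("b0", "b1", "b2", "p1", "p2"))
      fitsOut[[cn]] <- .num(fitsOut[[cn]])
    .writeTsv(fitsOut, out("fits.tsv"))
    writeLines(selected, out("selected_tfs.txt"))
  }
  if (length(selected) < 2L)
    stop("stage tf_select failed: fewer than 2 TFs selected")

  ## stage 4: MCN -----------------------------------------------------------
  say("stage mcn: minimal connected network (min evidence ",
      config$min_evidence, ", ", config$n_random, " random sets)")
  mcn <- minimalConnectedNetwork(selected, ppi,
                                 minEvidence = config$min_evidence)
  mcn <- subnetworkSignificance(mcn, ppi, nRandom = config$n_random,
                                rngSeed = seed + 11L,
                                minEvidence = config$min_evidence)
  nc <- negativeControl(tfUniverse(catalogue), ppi, mcn,
                        nLists = config$n_control_lists,
                        listSize = length(mcn@seeds),
                        rngSeed = seed + 12L,
                        minEvidence = config$min_evidence)
  sig <- mcnSignificance(mcn)
  say(sprintf("  KS p: betweenness %.3g, connections %.3g, clustering %.3g; negative control %.3g",
              sig$betweenness, sig$connections, sig$clustering, nc$p))
  nm <- mcnNodeMetrics(mcn)
  nmOut <- nm
  nmOut$betweenness <- .num(nmOut$betweenness)
  nmOut$clustering <- .num(nmOut$clustering)
  .writeTsv(nmOut, out("mcn_nodes.tsv"))
  el <- igraph::as_edgelist(mcnGraph(mcn))
  writeLines(paste(el[, 1L], "interacts", el[, 2L], sep = "\t"),
             out("mcn_edges.sif"))
  .writeTsv(data.frame(
    metric = c("betweenness", "connections", "clustering",
               "negative_control"),
    p = .num(c(sig$betweenness, sig$connections, sig$clustering, nc$p))),
    out("mcn_significance.tsv"))

  ## stage 5: central targets + accessible filter ---------------------------
  say("stage central_targets: top ", config$top_k,
      " central MCN TFs and their targets")
  central <- centralNodes(mcn, k = config$top_k)
  centralTfs <- intersect(central$top_k, tfUniverse(catalogue))
  if (length(centralTfs) == 0L)
    stop("stage central_targets failed: no central node is a catalogue TF")
  targets <- centralTfTargets(centralTfs, catalogue)
  acc <- annotationFilter(targets, sets, universe = genes)
  say("  ", length(targets), " unique targets, ", length(acc$filtered),
      " secreted/transmembrane")
  writeLines(central$top_k, out("central_nodes.txt"))
  writeLines(sort(acc$filtered), out("accessible_genes.txt"))

  ## stage 6: cancer specificity --------------------------------------------
  say("stage cancer_specific: dual-contrast BH at alpha_bh = ",
      config$alpha_bh)
  candidates <- intersect(acc$filtered, rownames(patient))
  if (length(candidates) == 0L)
    stop("stage cancer_specific failed: no accessible gene measured in patients")
  norm <- normalizePatientExpression(patient)
  cs <- cancerSpecificGenes(norm, candidates, alphaBh = config$alpha_bh,
                            phenotypeTable = phen)
  say("  ", length(cs), " cancer-specific gene(s)")
  csTab <- attr(cs, "table")
  for (cn in c("lfc_cancer", "p_A", "q_A", "p_B", "q_B"))
    csTab[[cn]] <- .num(csTab[[cn]])
  .writeTsv(csTab, out("cancer_specific.tsv"))

  ## stage 7: survival screen -----------------------------------------------
  say("stage survival: tertile log-rank screen at alpha = ", config$alpha)
  screen <- survivalScreen(cs, cohorts, alpha = config$alpha)
  biomarkers <- sort(screen$selected)
  say("  ", length(biomarkers), " biomarker(s) significant in >= 1 cohort")
  pv <- screen$pvalues
  pvOut <- data.frame(gene = rownames(pv),
                      as.data.frame(apply(pv, 2L, .num)),
                      check.names = FALSE)
  .writeTsv(pvOut, out("survival_pvalues.tsv"))
  writeLines(biomarkers, out("biomarkers.txt"))

  ## manifest + log ---------------------------------------------------------
  manifest <- c(
    vapply(names(.PIPELINE_THRESHOLDS), function(k)
      paste0(k, "=", .num(as.numeric(config[[k]]))), ""),
    paste0("stage_tf_activity=", "tf_scores.tsv"),
    paste0("stage_cnv_profiles=", "cnv_matrix.tsv"),
    paste0("stage_tf_select=", "fits.tsv,selected_tfs.txt"),
    paste0("stage_mcn=", "mcn_nodes.tsv,mcn_edges.sif,mcn_significance.tsv"),
    paste0("stage_central_targets=", "central_nodes.txt,accessible_genes.txt"),
    paste0("stage_cancer_specific=", "cancer_specific.tsv"),
    paste0("stage_survival=", "survival_pvalues.tsv,biomarkers.txt"))
  writeLines(manifest, out("manifest.txt"))
  writeLines(logLines, logPath)

  invisible(list(scores = scores, cnv = cnv, fits = fits,
                 selected = selected, mcn = mcn, negative_control = nc,
                 central = central, accessible = acc$filtered,
                 cancer_specific = cs, screen = screen,
                 biomarkers = biomarkers,
                 manifest = setNames(as.list(manifest), sub("=.*", "", manifest))))
}

#' Write a pipeline configuration for a synthetic-study directory
#'
#' Convenience helper pairing [writeSyntheticInputs()] with
#' [readPipelineConfig()]: writes a `run.cfg` pointing at the standard file
#' names in `dir`.
#'
#' @param dir directory holding the synthetic inputs.
#' @param cohortNames cohort labels (default the `cohort*_clinical.tsv`
#'   files present).
#' @param outDir pipeline output directory (default `file.path(dir, "run")`).
#' @param ... threshold overrides (e.g. `n_random = 200`, `rng_seed = 7`).
#' @return Path of the written configuration file.
#' @export
writePipelineConfig <- function(dir, cohortNames = NULL, outDir = NULL, ...) {
  if (is.null(cohortNames)) {
    f <- list.files(dir, pattern = "_clinical\\.tsv$")
    cohortNames <- sub("_clinical\\.tsv$", "", f)
  }
  if (is.null(outDir)) outDir <- file.path(dir, "run")
  thr <- modifyList(as.list(.PIPELINE_THRESHOLDS), list(...))
  lines <- c(
    paste0("expression=", file.path(dir, "expression.tsv")),
    paste0("sample_map=", file.path(dir, "sample_map.tsv")),
    paste0("catalogue=", file.path(dir, "catalogue.tsv")),
    paste0("regions=", file.path(dir, "regions.tsv")),
    paste0("gene_locations=", file.path(dir, "gene_locations.tsv")),
    paste0("ppi=", file.path(dir, "ppi.tsv")),
    paste0("annotation_sets=", file.path(dir, "annotation_sets.gmt")),
    paste0("patient_expression=", file.path(dir, "patient_expression.tsv")),
    paste0("phenotypes=", file.path(dir, "phenotypes.tsv")),
    paste0("cohort_names=", paste(cohortNames, collapse = ",")),
    unlist(lapply(cohortNames, function(cn) c(
      paste0(cn, "_expression=", file.path(dir, paste0(cn, "_expression.tsv"))),
      paste0(cn, "_clinical=", file.path(dir, paste0(cn, "_clinical.tsv")))))),
    paste0("out_dir=", outDir),
    vapply(names(thr), function(k) paste0(k, "=", thr[[k]]), ""))
  cfgPath <- file.path(dir, "run.cfg")
  writeLines(lines, cfgPath)
  cfgPath
}
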
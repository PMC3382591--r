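## Readers and writers for the standard plain-text interchange formats:
## expression TSV + sample map, catalogue TSV, BED-like region/location
## tables, SIF/TSV edge lists, GMT gene sets, phenotype and clinical TSVs.

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.num <- function(x) {
  ## fixed-format numbers so that reruns are byte-identical
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Read / write a regulation catalogue TSV
#'
#' Columns `tf`, `target` and optionally `sign`; the sign is carried along
#' but ignored in sign-less enrichment mode.
#'
#' @param path file path.
#' @param catalogue a [RegulationCatalogue-class] (for writing).
#' @return `readCatalogue`: a [RegulationCatalogue-class];
#'   `writeCatalogue`: the path, invisibly.
#' @export
readCatalogue <- function(path) {
  RegulationCatalogue(read.delim(path, colClasses = "character"))
}

#' @rdname readCatalogue
#' @export
writeCatalogue <- function(catalogue, path) {
  .writeTsv(catalogueEntries(catalogue), path)
}

#' Read / write replicate-level expression (TSV + sample map)
#'
#' The expression TSV has a first column `gene` and one column per replicate
#' sample; the side-car map TSV has columns `sample`, `cell_line`.
#'
#' @param path expression TSV path.
#' @param mapPath sample -> cell line map TSV path.
#' @param expr a [LineExpression-class] (for writing).
#' @return `readExpression`: a [LineExpression-class].
#' @export
readExpression <- function(path, mapPath) {
  tab <- read.delim(path, check.names = FALSE)
  map <- read.delim(mapPath, colClasses = "character")
  stopifnot(all(c("sample", "cell_line") %in% names(map)))
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  idx <- match(colnames(v), map$sample)
  if (any(is.na(idx)))
    stop("samples missing from the map: ",
         paste(colnames(v)[is.na(idx)], collapse = ", "))
  LineExpression(v, map$cell_line[idx])
}

#' @rdname readExpression
#' @export
writeExpression <- function(expr, path, mapPath) {
  v <- assay(expr)
  .writeTsv(data.frame(gene = rownames(v),
                       as.data.frame(apply(v, 2L, .num)),
                       check.names = FALSE), path)
  .writeTsv(data.frame(sample = colnames(v),
                       cell_line = unname(cellLines(expr))), mapPath)
}

#' Read / write a CNV region table
#'
#' Metadata columns `chrom`, `start`, `end`, `region_id`, `type`, `q`
#' (0-based half-open coordinates) followed by per-sample value columns.
#'
#' @param path file path.
#' @param regions region table (for writing).
#' @export
readRegions <- function(path) {
  r <- read.delim(path, check.names = FALSE)
  .checkRegions(r)
  r
}

#' @rdname readRegions
#' @export
writeRegions <- function(regions, path) {
  s <- .regionSamples(regions)
  regions[s] <- lapply(regions[s], .num)
  .writeTsv(regions, path)
}

#' Read / write a gene-location table (BED-like)
#'
#' Columns `gene`, `chrom`, `start`, `end` (0-based half-open).
#'
#' @param path file path.
#' @param locations location data.frame (for writing).
#' @export
readGeneLocations <- function(path) {
  loc <- read.delim(path)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(loc)))
  loc
}

#' @rdname readGeneLocations
#' @export
writeGeneLocations <- function(locations, path) .writeTsv(locations, path)

#' Read / write a PPI edge list
#'
#' Either a 3-column TSV (`a`, `b`, `evidence`) or a SIF file
#' (`a interacts b`, evidence defaulting to 1).
#'
#' @param path file path.
#' @param network a [PpiNetwork-class] (for writing; TSV format).
#' @export
readPpi <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\tinteracts\t| interacts ", first)) {
    lines <- readLines(path)
    parts <- strsplit(trimws(lines), "[\t ]+")
    parts <- parts[lengths(parts) >= 3L]
    edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                        b = vapply(parts, `[`, "", 3L), evidence = 1L)
  } else {
    edges <- read.delim(path)
    stopifnot(all(c("a", "b") %in% names(edges)))
  }
  PpiNetwork(edges)
}

#' @rdname readPpi
#' @export
writePpi <- function(network, path) {
  g <- ppiGraph(network)
  el <- igraph::as_edgelist(g)
  .writeTsv(data.frame(a = el[, 1L], b = el[, 2L],
                       evidence = igraph::E(g)$evidence), path)
}

#' Read / write GMT-like annotation gene sets
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path file path.
#' @param sets named list of gene sets (for writing).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-c(1L, 2L)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Columns `sample`, `phenotype` (cancer/inflammation/healthy), optional
#' `tissue`.
#'
#' @param path file path.
#' @return Named character vector sample -> phenotype.
#' @export
readPhenotypes <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  stopifnot(all(c("sample", "phenotype") %in% names(tab)))
  setNames(tab$phenotype, tab$sample)
}

#' Read a clinical table
#'
#' Columns `patient`, `time` (days, positive), `event` (0/1).
#'
#' @param path file path.
#' @export
readClinical <- function(path) {
  tab <- read.delim(path)
  stopifnot(all(c("patient", "time", "event") %in% names(tab)))
  tab$patient <- as.character(tab$patient)
  tab
}

#' Read a plain genes x samples matrix TSV (first column gene)
#'
#' @param path file path.
#' @export
readMatrixTsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  v
}

#' @rdname readMatrixTsv
#' @param v matrix to write.
#' @export
writeMatrixTsv <- function(v, path) {
  .writeTsv(data.frame(gene = rownames(v),
                       as.data.frame(apply(v, 2L, .num)),
                       check.names = FALSE), path)
}

#' Write every input of a synthetic study to a directory
#'
#' Emits the standard formats consumed by [runPipeline()]: expression TSV
#' plus sample map, catalogue TSV, region and location tables, PPI edge
#' list, GMT annotation sets, patient expression + phenotypes, per-cohort
#' expression + clinical tables, and a plain-text ground-truth manifest.
#'
#' @param study result of [generateSyntheticStudy()].
#' @param dir output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
writeSyntheticInputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeExpression(study$cellline$expression, p("expression.tsv"),
                  p("sample_map.tsv"))
  writeCatalogue(study$catalogue, p("catalogue.tsv"))
  writeRegions(study$cellline$regions, p("regions.tsv"))
  writeGeneLocations(study$cellline$locations, p("gene_locations.tsv"))
  writePpi(study$ppi, p("ppi.tsv"))
  writeGmt(study$sets, p("annotation_sets.gmt"))
  writeMatrixTsv(assay(study$patient$cohort), p("patient_expression.tsv"))
  .writeTsv(study$patient$phenotypes, p("phenotypes.tsv"))
  for (cn in names(study$cohorts)) {
    co <- study$cohorts[[cn]]
    writeMatrixTsv(co$expr, p(paste0(cn, "_expression.tsv")))
    cl <- co$clinical
    cl$time <- .num(cl$time)
    .writeTsv(cl, p(paste0(cn, "_clinical.tsv")))
  }
  truth <- study$truth
  writeLines(c(
    paste0("driver_tfs=", paste(truth$driver_tfs, collapse = ",")),
    paste0("module_nodes=", paste(truth$module_nodes, collapse = ",")),
    paste0("cancer_specific_genes=",
           paste(truth$cancer_specific_genes, collapse = ",")),
    paste0("decoy_genes=", paste(truth$decoy_genes, collapse = ",")),
    paste0("survival_genes=",
           paste(rownames(truth$survival_genes), collapse = ","))),
    p("ground_truth.txt"))
  files <- list.files(dir, full.names = TRUE)
  invisible(setNames(as.list(files), basename(files)))
}
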
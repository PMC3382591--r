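## Central S4 containers.  Matrix-like assays extend SummarizedExperiment;
## the catalogue and the interactome wrap a data.frame and an igraph object.

#' RegulationCatalogue: curated TF -> target regulations
#'
#' Holds a sign-less (or optionally signed) catalogue of experimentally
#' established transcription-factor/target-gene regulations, the substrate of
#' enrichment scoring and target collection.
#'
#' @slot entries data.frame with columns `tf`, `target` and optionally `sign`.
#' @export
setClass("RegulationCatalogue", slots = c(entries = "data.frame"))

setValidity("RegulationCatalogue", function(object) {
  e <- object@entries
  if (!all(c("tf", "target") %in% names(e)))
    return("entries must have columns 'tf' and 'target'")
  if (!is.character(e$tf) || !is.character(e$target))
    return("'tf' and 'target' must be character")
  if (anyDuplicated(paste0(e$tf, "\r", e$target)))
    return("duplicate (tf, target) pairs are not allowed")
  if (nrow(e) > 0 && any(!nzchar(e$tf) | !nzchar(e$target)))
    return("empty identifiers are not allowed")
  TRUE
})

#' Construct a RegulationCatalogue
#'
#' @param tf character vector of TF ids, or a data.frame with columns
#'   `tf`, `target` (and optionally `sign`).
#' @param target character vector of target gene ids (ignored when `tf` is a
#'   data.frame).
#' @param sign optional regulation sign (`"UP"`/`"DOWN"`), ignored in
#'   sign-less mode.
#' @return A [RegulationCatalogue-class] object.
#' @examples
#' cat <- RegulationCatalogue(c("TF1", "TF1", "TF2"), c("g1", "g2", "g2"))
#' targetsOf(cat, "TF1")
#' @export
RegulationCatalogue <- function(tf, target = NULL, sign = NULL) {
  if (is.data.frame(tf)) {
    e <- tf
  } else {
    e <- data.frame(tf = as.character(tf), target = as.character(target),
                    stringsAsFactors = FALSE)
    if (!is.null(sign)) e$sign <- as.character(sign)
  }
  e$tf <- as.character(e$tf)
  e$target <- as.character(e$target)
  rownames(e) <- NULL
  new("RegulationCatalogue", entries = e)
}

#' PpiNetwork: undirected protein-protein interaction graph
#'
#' A simple undirected graph over protein ids.  Each edge carries an
#' `evidence` attribute counting independent experimental evidences; the
#' curated view used throughout the pipeline keeps edges with at least two
#' evidences (see [evidenceFilter()]).
#'
#' @slot graph an `igraph` object (undirected, simple, edge attribute
#'   `evidence`).
#' @export
setClass("PpiNetwork", slots = c(graph = "ANY"))

setValidity("PpiNetwork", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) return("multi-edges are not allowed")
  ev <- igraph::E(g)$evidence
  if (igraph::ecount(g) > 0 && (is.null(ev) || any(is.na(ev)) || any(ev < 1)))
    return("every edge needs an evidence count >= 1")
  if (is.null(igraph::V(g)$name)) return("vertices must be named")
  TRUE
})

#' Construct a PpiNetwork from an edge table
#'
#' @param edges data.frame with columns `a`, `b` (protein ids) and optionally
#'   `evidence` (defaults to 1). Duplicate undirected edges are collapsed,
#'   keeping the maximum evidence count.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node ids.
#' @return A [PpiNetwork-class] object.
#' @export
PpiNetwork <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))
  if (is.null(edges$evidence)) edges$evidence <- 1L
  keep <- edges$a != edges$b
  edges <- edges[keep, , drop = FALSE]
  key <- ifelse(edges$a < edges$b, paste0(edges$a, "\r", edges$b),
                paste0(edges$b, "\r", edges$a))
  if (anyDuplicated(key)) {
    ev <- tapply(edges$evidence, key, max)
    parts <- strsplit(names(ev), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                        b = vapply(parts, `[`, "", 2L),
                        evidence = as.numeric(ev))
  }
  verts <- unique(c(edges$a, edges$b, nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  new("PpiNetwork", graph = g)
}

#' McnResult: an extracted minimal connected network
#'
#' @slot seeds character, the submitted seed protein ids.
#' @slot mappedSeeds character, seeds present in the (evidence-filtered) graph.
#' @slot subnetwork igraph, all direct seed-seed edges plus one-intermediate
#'   shortest-path edges.
#' @slot components list of character vectors (node sets), ordered by edge
#'   count (largest first).
#' @slot mcn igraph, the largest connected component of the subnetwork.
#' @slot nodeMetrics data.frame with columns `node`, `is_seed`, `betweenness`,
#'   `connections`, `clustering`, computed within the MCN subgraph.
#' @slot significance list; filled by [subnetworkSignificance()].
#' @export
setClass("McnResult",
         slots = c(seeds = "character", mappedSeeds = "character",
                   subnetwork = "ANY", components = "list", mcn = "ANY",
                   nodeMetrics = "data.frame", significance = "list"))

setValidity("McnResult", function(object) {
  if (!inherits(object@subnetwork, "igraph") || !inherits(object@mcn, "igraph"))
    return("subnetwork and mcn must be igraph objects")
  mcnNodes <- igraph::V(object@mcn)$name
  if (!all(mcnNodes %in% igraph::V(object@subnetwork)$name))
    return("mcn nodes must be a subset of the subnetwork nodes")
  if (!all(object@mappedSeeds %in% object@seeds))
    return("mappedSeeds must be a subset of seeds")
  TRUE
})

#' LineExpression: replicate-level cell-line expression
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay of log2 intensities (genes x replicate columns) whose
#' `colData` maps every column to exactly one cell line (`cell_line`).
#'
#' @export
setClass("LineExpression", contains = "SummarizedExperiment")

setValidity("LineExpression", function(object) {
  if (!"cell_line" %in% names(colData(object)))
    return("colData must contain a 'cell_line' column")
  if (anyDuplicated(rownames(object)))
    return("duplicate gene ids are not allowed")
  v <- assay(object)
  if (!is.numeric(v) || any(!is.finite(v)))
    return("expression values must be finite numbers")
  if (any(is.na(colData(object)$cell_line)))
    return("every column must map to exactly one cell line")
  TRUE
})

#' Construct a LineExpression object
#'
#' @param values numeric matrix of log2 intensities, genes in rows, replicate
#'   columns named by sample id.
#' @param cellLine character vector (length `ncol(values)`) mapping each
#'   column to its cell line.
#' @return A [LineExpression-class] object.
#' @export
LineExpression <- function(values, cellLine) {
  se <- SummarizedExperiment(
    assays = list(log2 = as.matrix(values)),
    colData = DataFrame(cell_line = as.character(cellLine),
                        row.names = colnames(values)))
  new("LineExpression", se)
}

#' PatientCohort: normalized patient expression with phenotypes
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose `colData$phenotype` labels every patient as `cancer`, `inflammation`
#' or `healthy`.
#'
#' @export
setClass("PatientCohort", contains = "SummarizedExperiment")

.PHENOTYPES <- c("cancer", "inflammation", "healthy")

setValidity("PatientCohort", function(object) {
  ph <- colData(object)$phenotype
  if (is.null(ph)) return("colData must contain a 'phenotype' column")
  if (!all(ph %in% .PHENOTYPES))
    return(sprintf("phenotypes must be one of: %s",
                   paste(.PHENOTYPES, collapse = ", ")))
  TRUE
})

#' Construct a PatientCohort object
#'
#' @param values numeric matrix, genes x patients (log2 scale).
#' @param phenotype character vector of per-patient phenotypes
#'   (`cancer`/`inflammation`/`healthy`).
#' @param tissue optional tissue label per patient.
#' @return A [PatientCohort-class] object.
#' @export
PatientCohort <- function(values, phenotype, tissue = NULL) {
  cd <- DataFrame(phenotype = as.character(phenotype),
                  row.names = colnames(values))
  if (!is.null(tissue)) cd$tissue <- as.character(tissue)
  se <- SummarizedExperiment(assays = list(log2 = as.matrix(values)),
                             colData = cd)
  new("PatientCohort", se)
}
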
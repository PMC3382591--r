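#' Accessors for tfmcn classes
#'
#' `tfUniverse()`, `targetUniverse()` and `targetsOf()` expose the catalogue;
#' `catalogueEntries()` returns its underlying table.  `ppiGraph()` returns
#' the igraph object inside a [PpiNetwork-class]; `evidenceFilter()` returns
#' the curated view with at least `minEvidence` experimental evidences.
#' `mcnGraph()`, `mcnNodeMetrics()` and `mcnSignificance()` expose an
#' [McnResult-class].  `cellLines()` gives the column -> cell-line mapping of
#' a [LineExpression-class]; `phenotypes()` the patient labels of a
#' [PatientCohort-class].
#'
#' @param x,object the object.
#' @param tf a TF id (for `targetsOf`).
#' @param minEvidence minimum evidence count kept (for `evidenceFilter`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tfUniverse", function(x) standardGeneric("tfUniverse"))

#' @rdname accessors
#' @export
setGeneric("targetUniverse", function(x) standardGeneric("targetUniverse"))

#' @rdname accessors
#' @export
setGeneric("targetsOf", function(x, tf) standardGeneric("targetsOf"))

#' @rdname accessors
#' @export
setGeneric("catalogueEntries", function(x) standardGeneric("catalogueEntries"))

#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))

#' @rdname accessors
#' @export
setGeneric("evidenceFilter",
           function(x, minEvidence = 2) standardGeneric("evidenceFilter"))

#' @rdname accessors
#' @export
setGeneric("mcnGraph", function(x) standardGeneric("mcnGraph"))

#' @rdname accessors
#' @export
setGeneric("mcnSeeds", function(x) standardGeneric("mcnSeeds"))

#' @rdname accessors
#' @export
setGeneric("mappedSeeds", function(x) standardGeneric("mappedSeeds"))

#' @rdname accessors
#' @export
setGeneric("mcnNodeMetrics", function(x) standardGeneric("mcnNodeMetrics"))

#' @rdname accessors
#' @export
setGeneric("mcnSignificance", function(x) standardGeneric("mcnSignificance"))

#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setMethod("tfUniverse", "RegulationCatalogue",
          function(x) unique(x@entries$tf))

#' @rdname accessors
#' @export
setMethod("targetUniverse", "RegulationCatalogue",
          function(x) unique(x@entries$target))

#' @rdname accessors
#' @export
setMethod("targetsOf", "RegulationCatalogue", function(x, tf) {
  stopifnot(length(tf) >= 1L)
  bad <- setdiff(tf, x@entries$tf)
  if (length(bad) > 0)
    stop("unknown TF id(s): ", paste(bad, collapse = ", "))
  unique(x@entries$target[x@entries$tf %in% tf])
})

#' @rdname accessors
#' @export
setMethod("catalogueEntries", "RegulationCatalogue", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("ppiGraph", "PpiNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("evidenceFilter", "PpiNetwork", function(x, minEvidence = 2) {
  g <- x@graph
  keep <- igraph::E(g)[igraph::E(g)$evidence >= minEvidence]
  new("PpiNetwork", graph = igraph::subgraph_from_edges(g, keep,
                                                        delete.vertices = FALSE))
})

#' @rdname accessors
#' @export
setMethod("mcnGraph", "McnResult", function(x) x@mcn)

#' @rdname accessors
#' @export
setMethod("mcnSeeds", "McnResult", function(x) x@seeds)

#' @rdname accessors
#' @export
setMethod("mappedSeeds", "McnResult", function(x) x@mappedSeeds)

#' @rdname accessors
#' @export
setMethod("mcnNodeMetrics", "McnResult", function(x) x@nodeMetrics)

#' @rdname accessors
#' @export
setMethod("mcnSignificance", "McnResult", function(x) x@significance)

#' @rdname accessors
#' @export
setMethod("cellLines", "LineExpression",
          function(x) setNames(colData(x)$cell_line, colnames(x)))

#' @rdname accessors
#' @export
setMethod("phenotypes", "PatientCohort",
          function(x) setNames(colData(x)$phenotype, colnames(x)))

#' @rdname accessors
#' @export
setMethod("show", "RegulationCatalogue", function(object) {
  e <- object@entries
  cat("RegulationCatalogue:", nrow(e), "regulations linking",
      length(unique(e$tf)), "TFs to", length(unique(e$target)),
      "target genes\n")
  if ("sign" %in% names(e)) cat("  signed entries present\n")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("show", "PpiNetwork", function(object) {
  g <- object@graph
  cat("PpiNetwork:", igraph::vcount(g), "proteins,", igraph::ecount(g),
      "interactions\n")
  if (igraph::ecount(g) > 0)
    cat("  evidence counts:", min(igraph::E(g)$evidence), "-",
        max(igraph::E(g)$evidence), "\n")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("show", "McnResult", function(object) {
  cat("McnResult:", length(object@mappedSeeds), "of", length(object@seeds),
      "seeds mapped;", length(object@components), "component(s)\n")
  cat("  MCN:", igraph::vcount(object@mcn), "nodes,",
      igraph::ecount(object@mcn), "edges\n")
  if (length(object@significance) > 0) {
    s <- object@significance
    cat(sprintf("  KS significance: betweenness %.3g, connections %.3g, clustering %.3g\n",
                s$betweenness, s$connections, s$clustering))
  }
  invisible(NULL)
})
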
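## Minimal connected network (MCN) extraction on a PPI graph, KS significance
## against random node sets, negative control, and centrality ranking.

.asIgraph <- function(x, minEvidence = NULL) {
  if (is(x, "PpiNetwork")) {
    if (!is.null(minEvidence)) x <- evidenceFilter(x, minEvidence)
    return(ppiGraph(x))
  }
  if (inherits(x, "igraph")) return(x)
  stop("expected a PpiNetwork or an igraph object")
}

## Named adjacency list (character neighbor vectors) of an igraph graph.
.adjList <- function(g) {
  nm <- igraph::V(g)$name
  al <- igraph::as_adj_list(g, mode = "all")
  out <- lapply(al, function(v) nm[as.integer(v)])
  names(out) <- nm
  out
}

## Edge set (2-column character matrix, a < b) of the minimal connected
## subnetwork of `seeds` over the adjacency list `adj`: all direct seed-seed
## edges plus, for every seed pair at graph distance exactly 2, every common
## neighbor with both incident edges.
.mcnEdgeSet <- function(seeds, adj) {
  es <- character(0)
  ns <- length(seeds)
  nbr <- adj[seeds]
  for (i in seq_len(ns - 1L)) {
    s1 <- seeds[i]; n1 <- nbr[[i]]
    for (j in (i + 1L):ns) {
      s2 <- seeds[j]
      if (s2 %in% n1) {                      # direct interaction
        es <- c(es, if (s1 < s2) c(s1, s2) else c(s2, s1))
      } else {                               # one tolerated intermediate
        common <- intersect(n1, nbr[[j]])
        for (w in common)
          es <- c(es,
                  if (s1 < w) c(s1, w) else c(w, s1),
                  if (w < s2) c(w, s2) else c(s2, w))
      }
    }
  }
  if (length(es) == 0L)
    return(matrix(character(0), ncol = 2L))
  m <- matrix(es, ncol = 2L, byrow = TRUE)
  m[!duplicated(paste0(m[, 1L], "\r", m[, 2L])), , drop = FALSE]
}

## Largest component (by edge count; ties: node count, then smallest
## lexicographic node id) of an edge set.  Returns an igraph or NULL.
.largestComponent <- function(sub) {
  comp <- igraph::components(sub)
  if (comp$no == 0L) return(NULL)
  members <- split(igraph::V(sub)$name, comp$membership)
  graphs <- lapply(members, function(v)
    igraph::induced_subgraph(sub, v))
  ne <- vapply(graphs, function(g) as.numeric(igraph::ecount(g)), 0)
  nv <- vapply(graphs, function(g) as.numeric(igraph::vcount(g)), 0)
  minId <- vapply(members, function(v) min(v), "")
  ord <- order(-ne, -nv, minId)
  list(graphs = graphs[ord], order = ord)
}

## Node metrics within a subgraph: unnormalized betweenness (each unordered
## pair counted once, fractional credit for multiple shortest paths), degree
## ("connections") and local clustering coefficient (0 for degree < 2).
.nodeMetrics <- function(g, seeds = character(0)) {
  nm <- igraph::V(g)$name
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(node = nm, is_seed = nm %in% seeds,
             betweenness = unname(btw), connections = unname(deg),
             clustering = cc, row.names = NULL)
}

#' Extract the minimal connected network of seed proteins
#'
#' The subnetwork consists of all direct seed-seed interactions plus, for
#' every seed pair at graph distance exactly 2, every common neighbor and
#' both incident edges (one tolerated intermediate).  Connected components
#' are ordered by edge count and the largest one is the MCN; smaller
#' components (such as a 3-node/2-edge fragment) are reported but discarded
#' from MCN candidacy.  Node metrics (betweenness, connections, clustering
#' coefficient) are computed within the MCN subgraph.
#'
#' @param seeds character vector of seed protein ids; at least 2 must map
#'   onto graph nodes (unmapped seeds are reported via a message).
#' @param network a [PpiNetwork-class] or an igraph object.
#' @param minEvidence evidence filter applied to a `PpiNetwork` (default 2).
#' @return An [McnResult-class] (significance slot empty; see
#'   [subnetworkSignificance()]).
#' @export
minimalConnectedNetwork <- function(seeds, network, minEvidence = 2) {
  g <- .asIgraph(network, minEvidence)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  seeds <- unique(as.character(seeds))
  mapped <- intersect(seeds, igraph::V(g)$name)
  if (length(mapped) < 2L)
    stop("fewer than 2 seeds map onto the graph (",
         length(seeds) - length(mapped), " unmapped)")
  if (length(mapped) < length(seeds))
    message(length(seeds) - length(mapped), " of ", length(seeds),
            " seeds not present in the interactome: ",
            paste(setdiff(seeds, mapped), collapse = ", "))
  em <- .mcnEdgeSet(mapped, .adjList(g))
  sub <- igraph::graph_from_edgelist(em, directed = FALSE)
  comps <- .largestComponent(sub)
  if (is.null(comps)) {
    mcn <- igraph::make_empty_graph(directed = FALSE)
    mcn <- igraph::set_vertex_attr(mcn, "name", value = character(0))
    components <- list()
    metrics <- data.frame(node = character(0), is_seed = logical(0),
                          betweenness = numeric(0), connections = numeric(0),
                          clustering = numeric(0))
  } else {
    mcn <- comps$graphs[[1L]]
    components <- lapply(comps$graphs, function(x) igraph::V(x)$name)
    metrics <- .nodeMetrics(mcn, mapped)
  }
  new("McnResult", seeds = seeds, mappedSeeds = mapped, subnetwork = sub,
      components = components, mcn = mcn, nodeMetrics = metrics,
      significance = list())
}

#' Unnormalized shortest-path betweenness
#'
#' Each unordered node pair is counted once; multiple shortest paths share
#' fractional credit.
#'
#' @param graph an igraph object or [PpiNetwork-class] (undirected,
#'   unweighted).
#' @return Named numeric vector of node scores.
#' @export
nodeBetweenness <- function(graph) {
  g <- .asIgraph(graph)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected;
#' 0 by convention for degree below 2.
#'
#' @param graph an igraph object or [PpiNetwork-class].
#' @param node optional node id(s); default all nodes.
#' @return Named numeric vector in `[0, 1]`.
#' @export
clusteringCoefficient <- function(graph, node = NULL) {
  g <- .asIgraph(graph)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  if (is.null(node)) cc else cc[node]
}

## Two-sided two-sample KS p-value between an observed metric vector and a
## pooled background; asymptotic (backgrounds are large and heavily tied).
.ksCompare <- function(obs, pooled) {
  if (length(obs) == 0L || length(pooled) == 0L) return(NA_real_)
  suppressWarnings(ks.test(obs, pooled, exact = FALSE)$p.value)
}

#' KS significance of an MCN against random node sets
#'
#' Draws `nRandom` uniform node sets of the same size as the number of
#' mapped seeds, extracts each set's MCN, and pools the node-level
#' betweenness, connections and clustering values across all random MCNs.
#' Each observed metric distribution is compared to its pooled background
#' with a two-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param result an [McnResult-class] with a non-empty MCN.
#' @param network the [PpiNetwork-class] (or igraph) the result was
#'   extracted from.
#' @param nRandom number of random node sets (default 1000; must be >= 1).
#' @param rngSeed integer seed for reproducibility (optional).
#' @param minEvidence evidence filter for a `PpiNetwork` (default 2).
#' @return The `result` with its `significance` slot filled: p-values
#'   `betweenness`, `connections`, `clustering`, plus `n_random`,
#'   `n_empty` (random sets whose MCN was empty) and `degenerate` (TRUE when
#'   all random MCNs were empty).
#' @export
subnetworkSignificance <- function(result, network, nRandom = 1000,
                                   rngSeed = NULL, minEvidence = 2) {
  stopifnot(is(result, "McnResult"))
  if (nRandom < 1L) stop("nRandom must be a positive integer")
  if (igraph::vcount(result@mcn) == 0L) stop("observed MCN is empty")
  g <- .asIgraph(network, minEvidence)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  adj <- .adjList(g)
  nodes <- igraph::V(g)$name
  k <- length(result@mappedSeeds)
  pool <- list(betweenness = vector("list", nRandom),
               connections = vector("list", nRandom),
               clustering = vector("list", nRandom))
  nEmpty <- 0L
  for (i in seq_len(nRandom)) {
    rnd <- sample(nodes, k)
    em <- .mcnEdgeSet(rnd, adj)
    if (nrow(em) == 0L) { nEmpty <- nEmpty + 1L; next }
    sub <- igraph::graph_from_edgelist(em, directed = FALSE)
    comps <- .largestComponent(sub)
    m <- .nodeMetrics(comps$graphs[[1L]])
    pool$betweenness[[i]] <- m$betweenness
    pool$connections[[i]] <- m$connections
    pool$clustering[[i]] <- m$clustering
  }
  degenerate <- nEmpty == nRandom
  obs <- result@nodeMetrics
  sig <- list(
    betweenness = if (degenerate) NA_real_ else
      .ksCompare(obs$betweenness, unlist(pool$betweenness)),
    connections = if (degenerate) NA_real_ else
      .ksCompare(obs$connections, unlist(pool$connections)),
    clustering = if (degenerate) NA_real_ else
      .ksCompare(obs$clustering, unlist(pool$clustering)),
    n_random = nRandom, n_empty = nEmpty, degenerate = degenerate)
  result@significance <- sig
  result
}

#' Negative control: random TF lists from the catalogue
#'
#' Generates `nLists` random lists of `listSize` distinct TFs from the
#' catalogue universe, extracts each list's MCN, pools the node betweenness
#' values of all random MCNs, and compares the observed MCN's betweenness
#' distribution to the pooled one with a two-sided KS test.
#'
#' @param tfUniverse character vector of all catalogue TF ids.
#' @param network the [PpiNetwork-class] (or igraph).
#' @param observed an [McnResult-class] (the cancer-associated MCN).
#' @param nLists number of random lists (default 100).
#' @param listSize list size; defaults to the number of observed seeds.
#'   Must not exceed `length(tfUniverse)`.
#' @param rngSeed integer seed (optional).
#' @param minEvidence evidence filter (default 2).
#' @return List with `p`, `statistic`, `n_lists`, `n_empty` and
#'   `pooled_n` (number of pooled background values).
#' @export
negativeControl <- function(tfUniverse, network, observed, nLists = 100,
                            listSize = NULL, rngSeed = NULL,
                            minEvidence = 2) {
  stopifnot(is(observed, "McnResult"))
  tfUniverse <- unique(as.character(tfUniverse))
  if (is.null(listSize)) listSize <- length(observed@seeds)
  if (listSize > length(tfUniverse))
    stop("listSize (", listSize, ") exceeds the TF universe (",
         length(tfUniverse), ")")
  if (nLists < 1L) stop("nLists must be a positive integer")
  g <- .asIgraph(network, minEvidence)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  adj <- .adjList(g)
  nodes <- igraph::V(g)$name
  pooled <- vector("list", nLists)
  nEmpty <- 0L
  for (i in seq_len(nLists)) {
    lst <- sample(tfUniverse, listSize)
    mapped <- intersect(lst, nodes)
    if (length(mapped) < 2L) { nEmpty <- nEmpty + 1L; next }
    em <- .mcnEdgeSet(mapped, adj)
    if (nrow(em) == 0L) { nEmpty <- nEmpty + 1L; next }
    sub <- igraph::graph_from_edgelist(em, directed = FALSE)
    comps <- .largestComponent(sub)
    pooled[[i]] <- .nodeMetrics(comps$graphs[[1L]])$betweenness
  }
  pooled <- unlist(pooled)
  obs <- observed@nodeMetrics$betweenness
  if (length(pooled) == 0L)
    return(list(p = NA_real_, statistic = NA_real_, n_lists = nLists,
                n_empty = nEmpty, pooled_n = 0L))
  kt <- suppressWarnings(ks.test(obs, pooled, exact = FALSE))
  list(p = kt$p.value, statistic = unname(kt$statistic), n_lists = nLists,
       n_empty = nEmpty, pooled_n = length(pooled))
}

#' Central MCN nodes by betweenness
#'
#' `above_average` contains the nodes whose betweenness strictly exceeds the
#' mean over MCN nodes; `top_k` the k highest-betweenness nodes (ties broken
#' by degree, then node id).  The share of total betweenness concentrated in
#' the top k is also reported.
#'
#' @param x an [McnResult-class] or a node-metrics data.frame with columns
#'   `node`, `betweenness`, `connections`.
#' @param k number of top nodes (default 10); clamped (with a message) when
#'   larger than the MCN.
#' @return List with `above_average` (character), `top_k` (character, ranked)
#'   and `top_share` (fraction of total betweenness in the top k).
#' @export
centralNodes <- function(x, k = 10) {
  m <- if (is(x, "McnResult")) x@nodeMetrics else x
  stopifnot(all(c("node", "betweenness", "connections") %in% names(m)))
  if (nrow(m) == 0L)
    return(list(above_average = character(0), top_k = character(0),
                top_share = NA_real_))
  if (k > nrow(m)) {
    message("k clamped from ", k, " to ", nrow(m), " (MCN size)")
    k <- nrow(m)
  }
  above <- m$node[m$betweenness > mean(m$betweenness)]
  ord <- order(-m$betweenness, -m$connections, m$node)
  top <- m$node[ord][seq_len(k)]
  tot <- sum(m$betweenness)
  share <- if (tot > 0) sum(m$betweenness[ord][seq_len(k)]) / tot else NA_real_
  list(above_average = above, top_k = top, top_share = share)
}
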
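## Shared fixture builders (everything generated in code, nothing on disk).

## genes x (lines * reps) LineExpression with iid normal values
makeExpression <- function(nGenes = 20, nLines = 5, reps = 2, seed = 1,
                           shift = NULL) {
  set.seed(seed)
  lines <- sprintf("CL%02d", seq_len(nLines))
  cols <- paste0(rep(lines, each = reps), "_r", seq_len(reps))
  v <- matrix(rnorm(nGenes * nLines * reps, 8, 1), nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)), cols))
  if (!is.null(shift))  # list(gene=, line=, delta=)
    for (s in shift) {
      j <- grep(paste0("^", s$line, "_"), cols)
      v[s$gene, j] <- v[s$gene, j] + s$delta
    }
  LineExpression(v, rep(lines, each = reps))
}

makeCatalogue <- function(tfs = c("TF1", "TF2"), targetsPer = 3,
                          genes = sprintf("g%03d", 1:20), seed = 1) {
  set.seed(seed)
  RegulationCatalogue(do.call(rbind, lapply(tfs, function(tf)
    data.frame(tf = tf, target = sample(genes, targetsPer)))))
}

## small igraph from an edge string like "a-b,b-c"
edgeGraph <- function(spec, isolated = character(0)) {
  e <- do.call(rbind, strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "-"))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (length(isolated) > 0)
    g <- igraph::add_vertices(g, length(isolated), name = isolated)
  g
}

ppiFromSpec <- function(spec, evidence = 2, isolated = character(0)) {
  e <- do.call(rbind, strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "-"))
  PpiNetwork(data.frame(a = e[, 1], b = e[, 2], evidence = evidence),
             nodes = isolated)
}

## region table row helper: one peak with per-sample values
regionRow <- function(chrom, start, end, id, q, values, type = "amp") {
  cbind(data.frame(chrom = chrom, start = start, end = end, region_id = id,
                   type = type, q = q),
        as.data.frame(as.list(values)))
}
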
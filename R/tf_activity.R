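## TF activity inference: per-line regulated gene lists (two-sample KS) and
## catalogue enrichment scores (-log10 e-value), a TFactS-style scorer.

## Two-sample KS statistic of x (size m <= 3, fast closed form) or general m
## against y.  Returns the two-sided sup-distance D.
.ksStat <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m <= 3L) {
    xs <- sort(x)
    d <- 0
    for (i in seq_len(m)) {
      le <- sum(y <= xs[i]); lt <- sum(y < xs[i])
      d <- max(d, abs(i / m - le / n), abs((i - 1) / m - lt / n))
    }
    return(d)
  }
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= m, 1 / m, -1 / n))
  ws <- sort(w)
  z <- z[c(diff(ws) != 0, TRUE)]  # drop tied positions except last
  max(abs(z))
}

## Asymptotic two-sided Kolmogorov tail: P(sqrt(mn/N) D >= t).
.ksAsymptoticP <- function(d, m, n) {
  t <- sqrt(m * n / (m + n)) * d
  if (t < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

## Whether the exact permutation-null p is required: the asymptotic
## approximation is unusable when the smaller sample has only a few points
## (its attainable p-values are bounded well away from 0), and cheap to
## replace when the pooled sample is small.
.ksUseExact <- function(m, n, exactMax = 25L) {
  min(m, n) <= 3L || m + n <= exactMax
}

## Two-sided two-sample KS p-value.  Exact (permutation null, via
## stats::psmirnov, ties-aware) for tiny samples, asymptotic otherwise.
.ksPvalue <- function(x, y, exactMax = 25L) {
  m <- length(x); n <- length(y)
  d <- .ksStat(x, y)
  if (.ksUseExact(m, n, exactMax)) {
    p <- psmirnov(d, sizes = c(m, n), z = c(x, y), two.sided = TRUE,
                  exact = TRUE, lower.tail = FALSE)
  } else {
    p <- .ksAsymptoticP(d, m, n)
  }
  c(statistic = d, p = p)
}

#' Genes differentially expressed in one cell line
#'
#' For every gene, the replicate values of `line` are compared to the pooled
#' values of all other columns with a two-sample Kolmogorov-Smirnov test.
#' P-values are turned into e-values by multiplying by the number of genes
#' tested (a Bonferroni-style correction), and genes with
#' `e-value <= evalueMax` are called differentially expressed.
#'
#' The KS p-value is exact (permutation null) when the smaller sample has at
#' most 3 points or the pooled sample at most 25, asymptotic otherwise.  The
#' exact null is essential for 2-3 replicates against a large pool: the
#' attainable asymptotic p-values are bounded away from 0 there (around 0.04
#' for duplicates), which would make the Bonferroni-style e-value threshold
#' unreachable for every gene.
#'
#' @param expr a [LineExpression-class] object.
#' @param line a cell-line id with at least 2 replicate columns; at least 2
#'   other cell lines must be present.
#' @param evalueMax e-value threshold (default 10).
#' @param details if `TRUE`, return the full per-gene table instead of the
#'   gene set.
#' @return Character vector of differentially expressed gene ids, or (with
#'   `details = TRUE`) a data.frame with columns `gene`, `statistic`, `p`,
#'   `evalue`.
#' @examples
#' cfg <- syntheticConfig(n_tfs = 6, n_genes = 40, n_cell_lines = 6,
#'                        n_drivers = 2, rng_seed = 1)
#' cl <- generateCellLineData(generateCatalogue(cfg), cfg)
#' head(differentialGenes(cl$expression, "L01"))
#' @export
differentialGenes <- function(expr, line, evalueMax = 10, details = FALSE) {
  stopifnot(is(expr, "LineExpression"))
  map <- cellLines(expr)
  if (!line %in% map) stop("unknown cell line: ", line)
  idx <- which(map == line)
  if (length(idx) < 2L)
    stop("cell line ", line, " has a single replicate; at least 2 required")
  if (length(unique(map[-idx])) < 2L)
    stop("at least 2 other cell lines are required")
  v <- assay(expr)
  nGenes <- nrow(v)
  m <- length(idx)
  X <- v[, idx, drop = FALSE]
  Y <- v[, -idx, drop = FALSE]
  n <- ncol(Y)
  if (m <= 3L && m + n > 25L) {
    ## closed-form D for 2-3 replicates, vectorized across genes; exact
    ## permutation-null p shared across genes via the unique D values
    Xs <- t(apply(X, 1L, sort))
    d <- numeric(nGenes)
    for (i in seq_len(m)) {
      le <- rowSums(Y <= Xs[, i]) / n
      lt <- rowSums(Y < Xs[, i]) / n
      d <- pmax(d, abs(i / m - le), abs((i - 1) / m - lt))
    }
    dr <- round(d, 12)
    du <- sort(unique(dr))
    pu <- vapply(du, function(q)
      psmirnov(q, sizes = c(m, n), two.sided = TRUE, exact = TRUE,
               lower.tail = FALSE), 0)
    p <- pu[match(dr, du)]
    stat <- d
  } else {
    res <- vapply(seq_len(nGenes),
                  function(g) .ksPvalue(X[g, ], Y[g, ]),
                  c(statistic = 0, p = 0))
    stat <- res["statistic", ]; p <- res["p", ]
  }
  evalue <- p * nGenes
  tab <- data.frame(gene = rownames(v), statistic = stat, p = p,
                    evalue = evalue, row.names = NULL)
  if (details) return(tab)
  tab$gene[tab$evalue <= evalueMax]
}

#' Regulated gene lists for every cell line
#'
#' Equivalent to calling [differentialGenes()] for each cell line, but
#' computed with shared per-gene rank matrices so the whole panel is
#' processed in one pass.  Rows containing tied values fall back to the
#' per-gene path.
#'
#' @inheritParams differentialGenes
#' @return Named list (cell line -> character vector of regulated genes).
#' @export
regulatedGeneLists <- function(expr, evalueMax = 10) {
  stopifnot(is(expr, "LineExpression"))
  map <- cellLines(expr)
  lines <- unique(unname(map))
  v <- assay(expr)
  nGenes <- nrow(v)
  nCols <- ncol(v)
  counts <- table(map)
  if (any(counts < 2L) || length(lines) < 3L || max(counts) > 3L)
    return(setNames(lapply(lines, function(l)
      differentialGenes(expr, l, evalueMax = evalueMax)), lines))
  ## counts of values <= x and < x across ALL columns, per gene
  Rle <- t(apply(v, 1L, rank, ties.method = "max"))
  Rlt <- t(apply(v, 1L, rank, ties.method = "min")) - 1L
  tied <- which(apply(v, 1L, anyDuplicated) > 0L)
  out <- vector("list", length(lines))
  names(out) <- lines
  pCache <- new.env(parent = emptyenv())
  for (l in lines) {
    idx <- which(map == l)
    m <- length(idx)
    n <- nCols - m
    X <- v[, idx, drop = FALSE]
    ord <- t(apply(X, 1L, order))
    d <- numeric(nGenes)
    for (i in seq_len(m)) {
      col <- idx[ord[, i]]
      flat <- cbind(seq_len(nGenes), col)
      le <- (Rle[flat] - i) / n
      lt <- (Rlt[flat] - (i - 1L)) / n
      d <- pmax(d, abs(i / m - le), abs((i - 1) / m - lt))
    }
    dr <- round(d, 12)
    du <- unique(dr)
    pu <- vapply(du, function(q) {
      qk <- paste0(m, ":", n, ":", format(q, digits = 15))
      if (is.null(pCache[[qk]]))
        pCache[[qk]] <- psmirnov(q, sizes = c(m, n), two.sided = TRUE,
                                 exact = TRUE, lower.tail = FALSE)
      pCache[[qk]]
    }, 0)
    p <- pu[match(dr, du)]
    ## genes with ties: recompute honestly (ties change both D and the null)
    for (g in tied) {
      res <- .ksPvalue(v[g, idx], v[g, -idx])
      p[g] <- res["p"]
    }
    out[[l]] <- rownames(v)[p * nGenes <= evalueMax]
  }
  out
}

#' One-sided over-representation test of a gene set in a query list
#'
#' Hypergeometric upper tail `P(X >= overlap)` with the universe as
#' population, `targetSet` as successes and the query as draws (one-sided
#' Fisher exact test for over-representation).
#'
#' @param query gene set submitted (must be a subset of `universe`).
#' @param targetSet gene set tested for enrichment (subset of `universe`).
#' @param universe non-empty background gene set.
#' @return List with `overlap` (count) and `p` (one-sided p-value).
#' @examples
#' u <- paste0("g", 1:20)
#' setEnrichment(u[1:5], u[1:5], u)  # p = 1/choose(20, 5)
#' @export
setEnrichment <- function(query, targetSet, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  query <- unique(query); targetSet <- unique(targetSet)
  bad <- setdiff(query, universe)
  if (length(bad) > 0)
    stop("query genes outside the universe: ", paste(bad, collapse = ", "))
  bad <- setdiff(targetSet, universe)
  if (length(bad) > 0)
    stop("target-set genes outside the universe: ",
         paste(bad, collapse = ", "))
  k <- length(intersect(query, targetSet))
  p <- phyper(k - 1, length(targetSet), length(universe) - length(targetSet),
              length(query), lower.tail = FALSE)
  list(overlap = k, p = unname(p))
}

#' TF regulation scores from per-line regulated gene lists
#'
#' For every (TF, cell line) pair the TF's catalogue targets are tested for
#' enrichment in the line's regulated gene list ([setEnrichment()]).  The
#' p-value is converted into an e-value by multiplying by the number of TFs
#' tested, and the regulation score is `max(0, -log10(e-value))`, so a score
#' is positive exactly when the e-value is below 1 (the "positive e-value
#' score" significance rule).
#'
#' Catalogue targets outside the universe are dropped (with a reported
#' count); TFs with no remaining target are excluded from the matrix.  An
#' empty regulated list yields all-zero scores for that line.
#'
#' @param catalogue a [RegulationCatalogue-class].
#' @param regulatedLists named list (cell line -> character vector of
#'   regulated genes).
#' @param universe background gene set; defaults to all genes appearing in
#'   the regulated lists is not sensible, so it must be supplied explicitly
#'   (typically all measured genes).
#' @param multiplier `"tested"` (default; e-value multiplier is the number of
#'   TFs with at least one target in the universe) or `"catalogue"` (all
#'   catalogue TFs).
#' @return Numeric matrix of scores, TFs x cell lines, with attributes
#'   `n_tested` (e-value multiplier), `dropped_targets` (count of catalogue
#'   targets outside the universe) and `not_significant_anywhere` (TF ids
#'   whose score is 0 in every line).
#' @export
tfScores <- function(catalogue, regulatedLists, universe,
                     multiplier = c("tested", "catalogue")) {
  stopifnot(is(catalogue, "RegulationCatalogue"))
  multiplier <- match.arg(multiplier)
  universe <- unique(universe)
  e <- catalogueEntries(catalogue)
  inU <- e$target %in% universe
  dropped <- sum(!inU)
  targets <- split(e$target[inU], e$tf[inU])
  targets <- targets[lengths(targets) > 0]
  tfs <- sort(names(targets))
  if (length(tfs) == 0L) stop("no catalogue TF has a target in the universe")
  nTested <- if (multiplier == "tested") length(tfs)
             else length(tfUniverse(catalogue))
  lines <- names(regulatedLists)
  if (is.null(lines) || any(!nzchar(lines)))
    stop("regulatedLists must be a named list (cell line -> gene set)")
  nT <- lengths(targets[tfs])
  U <- length(universe)
  scores <- matrix(0, nrow = length(tfs), ncol = length(lines),
                   dimnames = list(tfs, lines))
  for (l in lines) {
    q <- unique(intersect(regulatedLists[[l]], universe))
    if (length(q) == 0L) next  # empty list: all scores 0 for this line
    k <- vapply(targets[tfs], function(tt) sum(tt %in% q), 0L)
    p <- phyper(k - 1, nT, U - nT, length(q), lower.tail = FALSE)
    scores[, l] <- pmax(0, -log10(p * nTested))
  }
  attr(scores, "n_tested") <- nTested
  attr(scores, "dropped_targets") <- dropped
  attr(scores, "not_significant_anywhere") <-
    rownames(scores)[rowSums(scores > 0) == 0]
  scores
}
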
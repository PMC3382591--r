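## Independent oracles, deliberately implemented by different routes than
## the package code paths they check.

## Exact hypergeometric upper tail P(X >= k) by direct enumeration of the
## counting formula with exact integer arithmetic (choose() is exact well
## beyond the |U| <= 20 range used here).
oracleHyper <- function(k, nT, nU, nQ) {
  i <- k:min(nT, nQ)
  if (length(i) == 0 || k > min(nT, nQ)) return(0)
  sum(choose(nT, i) * choose(nU - nT, nQ - i)) / choose(nU, nQ)
}

## Brute-force betweenness: enumerate every shortest path between every
## node pair by depth-limited DFS and give each interior node fractional
## credit.
oracleBetweenness <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(g, i)))
  D <- igraph::distances(g)
  btw <- setNames(numeric(n), nm)
  allPaths <- function(from, to, depth) {
    ## all simple paths of exactly `depth` edges from `from` to `to`
    if (depth == 0) {
      if (from == to) return(list(from)) else return(list())
    }
    out <- list()
    for (w in adj[[from]])
      if (is.finite(D[w, to]) && D[w, to] == depth - 1)
        out <- c(out, lapply(allPaths(w, to, depth - 1),
                             function(p) c(from, p)))
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- allPaths(s, t, D[s, t])
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      if (length(inner) > 0)
        btw[inner] <- btw[inner] + 1 / length(paths)
    }
  }
  btw
}

## Triangle-counting clustering coefficient from the adjacency matrix.
oracleClustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  out <- setNames(numeric(n), igraph::V(g)$name)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    out[i] <- sum(A[nb, nb]) / (k * (k - 1))
  }
  out
}

## Hand product-limit estimator.
oracleKm <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    atRisk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

## Plain log-rank chi-square (O(events * groups)), used both directly and
## inside the permutation oracle.
oracleLogrankStat <- function(times, events, group) {
  group <- as.integer(factor(group))
  k <- max(group)
  ut <- sort(unique(times[events == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t0 in ut) {
    atRisk <- times >= t0
    n <- sum(atRisk)
    d <- sum(events == 1 & times == t0)
    for (j in seq_len(k)) {
      nj <- sum(atRisk & group == j)
      O[j] <- O[j] + sum(events == 1 & times == t0 & group == j)
      E[j] <- E[j] + d * nj / n
    }
    if (n > 1) {
      for (j in seq_len(k)) {
        nj <- sum(atRisk & group == j)
        V[j, j] <- V[j, j] + d * (nj / n) * (1 - nj / n) * (n - d) / (n - 1)
        for (l in seq_len(k)) if (l != j) {
          nl <- sum(atRisk & group == l)
          V[j, l] <- V[j, l] - d * nj * nl / n^2 * (n - d) / (n - 1)
        }
      }
    }
  }
  idx <- seq_len(k - 1)
  drop(t(O[idx] - E[idx]) %*% solve(V[idx, idx]) %*% (O[idx] - E[idx]))
}

## Monte-Carlo permutation p-value for the log-rank statistic.
oraclePermLogrank <- function(times, events, group, nPerm = 1e4,
                              seed = 1) {
  set.seed(seed)
  obs <- oracleLogrankStat(times, events, group)
  perm <- replicate(nPerm,
                    oracleLogrankStat(times, events, sample(group)))
  mean(perm >= obs - 1e-12)
}

## Benjamini-Hochberg by the literal max-k step-up definition.
oracleBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0, which(ps <= alpha * seq_len(m) / m)))
  sel <- logical(m)
  if (k > 0) sel[o[seq_len(k)]] <- TRUE
  sel
}
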
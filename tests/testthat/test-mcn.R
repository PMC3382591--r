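test_that("MCN keeps direct edges and one tolerated intermediate", {
  ## direct seed-seed edge
  m <- minimalConnectedNetwork(c("a", "b"), edgeGraph("a-b,b-c"))
  expect_setequal(igraph::V(mcnGraph(m))$name, c("a", "b"))
  expect_equal(igraph::ecount(mcnGraph(m)), 1)
  ## one intermediate on a distance-2 path
  m <- minimalConnectedNetwork(c("a", "c"), edgeGraph("a-w,w-c"))
  expect_setequal(igraph::V(mcnGraph(m))$name, c("a", "w", "c"))
  ## seeds at distance 3 cannot be connected
  m <- minimalConnectedNetwork(c("a", "d"), edgeGraph("a-b,b-c,c-d"))
  expect_equal(igraph::vcount(mcnGraph(m)), 0)
  ## all common neighbors of a distance-2 pair are included
  m <- minimalConnectedNetwork(c("a", "c"), edgeGraph("a-w,w-c,a-v,v-c"))
  expect_setequal(igraph::V(mcnGraph(m))$name, c("a", "c", "w", "v"))
})

test_that("unmapped seeds are reported and the run proceeds", {
  ## 88 submitted, 18 unknown to the interactome: continue with 70
  g <- igraph::sample_gnp(120, 0.15)
  igraph::V(g)$name <- sprintf("P%03d", 1:120)
  seeds <- c(sprintf("P%03d", 1:70), sprintf("X%02d", 1:18))
  expect_message(m <- minimalConnectedNetwork(seeds, g), "18 of 88")
  expect_length(m@mappedSeeds, 70)
  ## fewer than 2 mapped seeds is fatal
  expect_error(minimalConnectedNetwork(c("X1", "X2", "P001"), g),
               "fewer than 2")
})

test_that("largest component is chosen by edge count, small ones reported", {
  ## two components: a 4-clique of seeds and a 3-node path (2 edges)
  g <- edgeGraph("a-b,a-c,a-d,b-c,b-d,c-d,x-y,y-z")
  m <- minimalConnectedNetwork(c("a", "b", "c", "d", "x", "z"), g)
  expect_setequal(igraph::V(mcnGraph(m))$name, c("a", "b", "c", "d"))
  expect_length(m@components, 2)
  expect_setequal(m@components[[2]], c("x", "y", "z"))
})

test_that("betweenness matches analytic values on canonical graphs", {
  b <- nodeBetweenness(edgeGraph("a-b,b-c"))
  expect_equal(b[["b"]], 1)
  expect_equal(b[["a"]], 0)
  star <- edgeGraph("h-l1,h-l2,h-l3,h-l4")
  expect_equal(nodeBetweenness(star)[["h"]], choose(4, 2))
  expect_equal(clusteringCoefficient(edgeGraph("a-b,b-c,a-c"))[["a"]], 1)
  expect_equal(clusteringCoefficient(star)[["h"]], 0)
  ## neighbors {x,y,z} with one edge among them -> 1/3
  g <- edgeGraph("n-x,n-y,n-z,x-y")
  expect_equal(clusteringCoefficient(g, "n")[["n"]], 1 / 3)
})

test_that("betweenness and clustering equal brute-force enumeration", {
  set.seed(13)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.6))
    igraph::V(g)$name <- paste0("n", seq_len(n))
    expect_equal(nodeBetweenness(g), oracleBetweenness(g),
                 tolerance = 1e-10)
    expect_equal(clusteringCoefficient(g), oracleClustering(g),
                 tolerance = 1e-12)
  }
})

test_that("MCN extraction is invariant under node relabeling", {
  set.seed(3)
  g <- igraph::sample_gnp(30, 0.12)
  igraph::V(g)$name <- sprintf("n%02d", 1:30)
  seeds <- sprintf("n%02d", 1:6)
  m1 <- minimalConnectedNetwork(seeds, g)
  relabel <- setNames(sprintf("z%02d", sample(30)), sprintf("n%02d", 1:30))
  g2 <- g; igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  m2 <- minimalConnectedNetwork(unname(relabel[seeds]), g2)
  expect_setequal(unname(relabel[igraph::V(mcnGraph(m1))$name]),
                  igraph::V(mcnGraph(m2))$name)
  expect_equal(igraph::ecount(mcnGraph(m1)), igraph::ecount(mcnGraph(m2)))
})

test_that("every MCN edge lies on a length<=2 seed path", {
  set.seed(8)
  for (i in 1:10) {
    g <- igraph::sample_gnp(25, 0.15)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    seeds <- sample(igraph::V(g)$name, 6)
    m <- minimalConnectedNetwork(seeds, g)
    sub <- m@subnetwork
    if (igraph::ecount(sub) == 0) next
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    el <- igraph::as_edgelist(sub)
    for (k in seq_len(nrow(el))) {
      u <- el[k, 1]; v <- el[k, 2]
      if (u %in% seeds && v %in% seeds) next      # direct seed-seed edge
      w <- if (u %in% seeds) v else u              # the intermediate
      s <- if (u %in% seeds) u else v              # its seed endpoint
      expect_true(s %in% seeds)                    # no non-seed pairs
      others <- setdiff(seeds, s)
      ## w must close a distance-2 path s - w - s2 for a non-adjacent s2
      expect_true(any(A[w, others] > 0 & A[s, others] == 0))
    }
  }
})

test_that("tree betweenness satisfies the subtree-product identity", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    tr <- igraph::sample_tree(n)
    igraph::V(tr)$name <- paste0("t", seq_len(n))
    btw <- nodeBetweenness(tr)
    ## on a tree each pair has one path: total interior credit equals
    ## sum over edges of n1*n2 minus the C(n,2) endpoint pairs' endpoints
    el <- igraph::as_edgelist(tr, names = FALSE)
    tot <- 0
    for (k in seq_len(nrow(el))) {
      g2 <- igraph::delete_edges(tr, k)
      comp <- igraph::components(g2)$csize
      tot <- tot + prod(comp)
    }
    ## each pair contributes (path length) edges; interior nodes per pair =
    ## path length - 1, so sum(btw) = tot - C(n,2)
    expect_equal(sum(btw), tot - choose(n, 2), tolerance = 1e-9)
  }
})

test_that("subnetwork significance is reproducible and guarded", {
  set.seed(30)
  g <- igraph::sample_gnp(60, 0.1)
  igraph::V(g)$name <- sprintf("n%02d", 1:60)
  m <- minimalConnectedNetwork(sprintf("n%02d", 1:8), g)
  expect_error(subnetworkSignificance(m, g, nRandom = 0), "positive")
  s1 <- subnetworkSignificance(m, g, nRandom = 50, rngSeed = 5)
  s2 <- subnetworkSignificance(m, g, nRandom = 50, rngSeed = 5)
  expect_equal(mcnSignificance(s1), mcnSignificance(s2))
  expect_true(all(unlist(mcnSignificance(s1)[1:3]) >= 0))
})

test_that("negative control degenerates to D = 0 on the observed list", {
  g <- edgeGraph("a-b,b-c,c-d,a-c")
  m <- minimalConnectedNetwork(c("a", "b", "c"), g)
  ## the only possible 3-element list from a 3-TF universe is the observed
  nc <- negativeControl(c("a", "b", "c"), g, m, nLists = 1, listSize = 3)
  expect_equal(nc$statistic, 0)
  expect_error(negativeControl(c("a", "b"), g, m, listSize = 5),
               "exceeds")
})

test_that("central nodes use strict above-average and documented ties", {
  metrics <- data.frame(node = c("a", "b", "c"),
                        betweenness = c(10, 1, 1),
                        connections = c(3, 5, 2))
  out <- centralNodes(metrics, k = 2)
  expect_equal(out$above_average, "a")
  expect_equal(out$top_k, c("a", "b"))        # tie broken by degree
  expect_equal(out$top_share, 11 / 12)
  ## all-equal scores: strictly-above-average set is empty
  eq <- data.frame(node = c("a", "b"), betweenness = c(2, 2),
                   connections = c(1, 1))
  expect_length(centralNodes(eq, k = 1)$above_average, 0)
  expect_message(centralNodes(eq, k = 5), "clamped")
})
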
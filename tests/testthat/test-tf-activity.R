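test_that("setEnrichment matches the exact hypergeometric tail", {
  u <- paste0("g", 1:20)
  ## full overlap of a 5-gene set in a 5-gene query: p = 1/C(20,5)
  res <- setEnrichment(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## empty query is never enriched
  expect_equal(setEnrichment(character(0), u[1:5], u)$p, 1)
  ## the whole universe as target set is a certain event
  expect_equal(setEnrichment(u[1:7], u, u)$p, 1)
  expect_error(setEnrichment(c("zz"), u[1:5], u), "zz")
  expect_error(setEnrichment(u[1:2], c("zz"), u), "zz")
})

test_that("adding a target-set member to the query never increases p", {
  set.seed(42)
  u <- paste0("g", 1:30)
  for (i in 1:25) {
    tset <- sample(u, sample(3:12, 1))
    q <- sample(u, sample(2:10, 1))
    extra <- setdiff(tset, q)
    if (length(extra) == 0) next
    p0 <- setEnrichment(q, tset, u)$p
    p1 <- setEnrichment(c(q, extra[1]), tset, u)$p
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("differentialGenes applies the KS + e-value rule", {
  ## a gene identical to the pool is never called (p = 1 -> e = nGenes)
  v <- matrix(rnorm(15 * 12, 8), 15,
              dimnames = list(sprintf("g%02d", 1:15),
                              paste0(rep(sprintf("L%d", 1:6), each = 2),
                                     "_r", 1:2)))
  v["g01", ] <- rep(c(1, 2), 6)  # same two values in every line
  le <- LineExpression(v, rep(sprintf("L%d", 1:6), each = 2))
  tab <- differentialGenes(le, "L1", details = TRUE)
  expect_equal(tab$p[tab$gene == "g01"], 1)
  expect_false("g01" %in% differentialGenes(le, "L1"))
  ## degenerate threshold returns every gene
  expect_setequal(differentialGenes(le, "L1", evalueMax = Inf),
                  rownames(v))
  expect_error(differentialGenes(le, "Lx"), "unknown")
  ## single replicate is a precondition failure
  le2 <- LineExpression(v[, -2], c("L1", sprintf("L%d", rep(2:6, each = 2))))
  expect_error(differentialGenes(le2, "L1"), "replicate")
})

test_that("KS p-values agree with a permutation enumeration oracle", {
  ## 2 line points vs 4 pool points: enumerate all C(6,2) assignments of
  ## the pooled values to the 'line' role and tabulate the exact null of D
  x <- c(10, 11); y <- c(1, 2, 3, 4)
  z <- c(x, y)
  dObs <- tfmcn:::.ksStat(x, y)
  combos <- combn(6, 2)
  dNull <- apply(combos, 2, function(i) tfmcn:::.ksStat(z[i], z[-i]))
  pOracle <- mean(dNull >= dObs - 1e-12)
  pImpl <- tfmcn:::.ksPvalue(x, y)["p"]
  expect_equal(unname(pImpl), pOracle, tolerance = 1e-12)
  ## and against stats::ks.test on random draws, exact and asymptotic
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(6:20, 1))
    ref <- suppressWarnings(ks.test(a, b))
    got <- tfmcn:::.ksPvalue(a, b)
    expect_equal(unname(got["statistic"]), unname(ref$statistic),
                 tolerance = 1e-12)
    if (length(a) + length(b) <= 25)  # boundary fuzz in the DP recursion
      expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-4)
  }
  for (i in 1:10) {  # asymptotic branch vs ks.test's asymptotic p
    a <- rnorm(10); b <- rnorm(25)
    ref <- suppressWarnings(ks.test(a, b, exact = FALSE))
    got <- tfmcn:::.ksPvalue(a, b)
    expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-4)
  }
})

test_that("differential calls are invariant under monotone rescaling", {
  le <- makeExpression(nGenes = 30, nLines = 5, reps = 3, seed = 3,
                       shift = list(list(gene = "g001", line = "CL01",
                                         delta = 6)))
  a <- differentialGenes(le, "CL01")
  v2 <- exp(SummarizedExperiment::assay(le) / 4)  # strictly monotone
  le2 <- LineExpression(v2, unname(cellLines(le)))
  expect_identical(a, differentialGenes(le2, "CL01"))
  expect_true("g001" %in% a)
})

test_that("regulatedGeneLists matches per-line differentialGenes", {
  le <- makeExpression(nGenes = 40, nLines = 6, reps = 3, seed = 11,
                       shift = list(list(gene = "g002", line = "CL03",
                                         delta = 7)))
  ## inject ties to exercise the fallback path
  v <- SummarizedExperiment::assay(le)
  v["g010", ] <- rep(c(5, 5, 6), 6)
  le <- LineExpression(v, unname(cellLines(le)))
  fast <- regulatedGeneLists(le)
  for (l in names(fast))
    expect_setequal(fast[[l]], differentialGenes(le, l))
})

test_that("tfScores floors at zero and applies the e-value multiplier", {
  genes <- sprintf("g%03d", 1:40)
  cat <- RegulationCatalogue(
    data.frame(tf = rep(c("TF1", "TF2", "TF3"), each = 5),
               target = c(genes[1:5], genes[6:10], paste0("x", 1:5))))
  lists <- list(L1 = genes[1:6], L2 = character(0))
  scores <- tfScores(cat, lists, universe = genes)
  ## TF3 has no target inside the universe -> absent
  expect_setequal(rownames(scores), c("TF1", "TF2"))
  expect_equal(attr(scores, "dropped_targets"), 5)
  expect_equal(attr(scores, "n_tested"), 2)
  ## empty regulated list -> all scores 0 for that line
  expect_true(all(scores[, "L2"] == 0))
  ## scores agree with the tested-TF multiplier applied to setEnrichment
  for (tf in rownames(scores)) {
    p <- setEnrichment(lists$L1, intersect(targetsOf(cat, tf), genes),
                       genes)$p
    expect_equal(scores[tf, "L1"], max(0, -log10(p * 2)), tolerance = 1e-12)
  }
  ## catalogue-wide multiplier option
  scores3 <- tfScores(cat, lists, universe = genes,
                      multiplier = "catalogue")
  expect_equal(attr(scores3, "n_tested"), 3)
  ## the positive-score rule: score > 0 iff e-value < 1
  p <- setEnrichment(lists$L1, genes[6:10], genes)$p
  expect_equal(scores["TF2", "L1"] > 0, p * 2 < 1)
  expect_true("TF2" %in% attr(scores, "not_significant_anywhere") ||
              scores["TF2", "L1"] > 0)
})
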
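test_that("central TF targets are a deduplicated union", {
  cat <- RegulationCatalogue(
    data.frame(tf = c("A", "A", "A", "B", "B", "B", "B", "C", "C"),
               target = c("g1", "g2", "g3", "g4", "g5", "g6", "g7",
                          "g1", "g2")))
  expect_length(centralTfTargets("A", cat), 3)
  expect_length(centralTfTargets(c("A", "B"), cat), 7)   # disjoint 3 + 4
  expect_length(centralTfTargets(c("A", "C"), cat),
                length(centralTfTargets("A", cat)))      # shared targets
  expect_error(centralTfTargets(c("A", "Z"), cat), "Z")
})

test_that("annotation filter keeps set members and reports enrichment", {
  u <- paste0("g", 1:20)
  sets <- list(secreted = u[1:5], transmembrane = u[6:8])
  out <- annotationFilter(u[15:18], sets, u)
  expect_length(out$filtered, 0)
  expect_true(all(out$enrichment$p == 1))
  out2 <- annotationFilter(u[1:3], sets, u)
  expect_setequal(out2$filtered, u[1:3])
  ## fully-contained query reproduces the exact hypergeometric tail
  out3 <- annotationFilter(u[1:5], sets, u, setNames = "secreted")
  expect_equal(out3$enrichment$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(annotationFilter(u[1:2], sets, u, setNames = "nope"),
               "nope")
})

test_that("median/IQR normalization follows the type-7 quartile rule", {
  v <- rbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(0, 1, 5, 9, 10))
  colnames(v) <- paste0("p", 1:5)
  expect_message(out <- normalizePatientExpression(v), "zero-IQR")
  expect_equal(unname(out["a", ]), c(-1, -0.5, 0, 0.5, 1))
  expect_false("b" %in% rownames(out))
  expect_equal(attr(out, "dropped"), "b")
  ## location/scale idempotence: normalized rows have median 0, IQR 1
  expect_equal(unname(apply(out, 1, median)), c(0, 0))
  expect_equal(unname(apply(out, 1, IQR)), c(1, 1))
  expect_error(normalizePatientExpression(v["b", , drop = FALSE]),
               "zero IQR")
})

test_that("dual-contrast rule keeps cancer-only genes and drops shared ones", {
  set.seed(77)
  n <- c(cancer = 60, inflammation = 25, healthy = 25)
  ph <- rep(names(n), n)
  genes <- c("cancerOnly", "shared", sprintf("null%d", 1:20))
  ## inflammation samples are noisier (whole-blood heterogeneity); the
  ## cancer-only contrast B would otherwise see the cancer shift through
  ## the pooled rest group
  sds <- ifelse(ph == "inflammation", 6, 1)
  v <- matrix(rnorm(length(genes) * sum(n), 0, rep(sds, each = length(genes))),
              length(genes),
              dimnames = list(genes, sprintf("p%03d", seq_len(sum(n)))))
  v["cancerOnly", ph == "cancer"] <- v["cancerOnly", ph == "cancer"] + 3
  v["shared", ph == "cancer"] <- v["shared", ph == "cancer"] + 3
  v["shared", ph == "inflammation"] <- v["shared", ph == "inflammation"] + 9
  cs <- cancerSpecificGenes(v, genes, phenotypeTable = setNames(ph, colnames(v)))
  expect_true("cancerOnly" %in% cs)
  expect_false("shared" %in% cs)   # significant in contrast B too
  tab <- attr(cs, "table")
  expect_true(tab$q_B[tab$gene == "shared"] <= 0.05)
  expect_gt(tab$lfc_cancer[tab$gene == "cancerOnly"], 2)
  ## absent phenotype is a precondition error
  expect_error(cancerSpecificGenes(v[, ph != "healthy"], genes,
               phenotypeTable = setNames(ph[ph != "healthy"],
                                         colnames(v)[ph != "healthy"])),
               "healthy")
})

test_that("BH selection matches the literal step-up definition", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    sel <- p.adjust(p, "BH") <= 0.1
    expect_equal(sel, oracleBH(p, 0.1))
  }
})

test_that("tertile split follows the rank rule with ties to the lower group", {
  expect_equal(as.vector(table(tertileGroups(1:9))), c(3, 3, 3))
  expect_equal(as.vector(table(tertileGroups(1:10))), c(4, 3, 3))
  g <- tertileGroups(1:9)
  expect_equal(which(g == "low"), 1:3)
  expect_equal(which(g == "high"), 7:9)
  ## all values equal: everyone in the lower group
  expect_true(all(tertileGroups(rep(5, 8)) == "low"))
  ## a tie across the boundary goes low
  g2 <- tertileGroups(c(1, 2, 2, 2, 5, 6, 7, 8, 9))
  expect_true(all(g2[2:4] == g2[2]))
  expect_error(tertileGroups(c(1, 2)), "3 patients")
})

test_that("Kaplan-Meier estimator equals the hand product-limit", {
  ## no events: survival stays 1
  km <- kmCurve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km$fn(c(0, 10)) == 1))
  ## n = 4, one death at t = 10
  km <- kmCurve(c(10, 12, 15, 20), c(1, 0, 0, 0))
  expect_equal(km$fn(10), 0.75)
  expect_equal(km$fn(9.99), 1)
  ## deaths at 5 and 10 with a censoring at 7 among n = 3
  km <- kmCurve(c(5, 7, 10), c(1, 0, 1))
  expect_equal(km$fn(5), 2 / 3)
  expect_equal(km$fn(10), 0)
  ## random fixtures against the oracle
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    t0 <- sample(1:40, n, replace = TRUE)
    e0 <- rbinom(n, 1, 0.7)
    if (sum(e0) == 0) next
    km <- kmCurve(t0, e0)
    ref <- oracleKm(t0, e0)
    expect_equal(km$fn(ref$time), ref$surv, tolerance = 1e-12)
  }
})

test_that("log-rank test handles identical, empty and event-free groups", {
  g1 <- list(times = c(3, 6, 9, 12), events = c(1, 0, 1, 1))
  lt <- logrankTest(list(g1, g1))
  expect_equal(lt$statistic, 0, tolerance = 1e-12)
  expect_equal(lt$p, 1, tolerance = 1e-9)
  ## all event-free: statistic 0, p 1, flagged
  lt2 <- logrankTest(list(list(times = 1:3, events = rep(0, 3)),
                          list(times = 1:3, events = rep(0, 3))))
  expect_equal(lt2$p, 1)
  expect_true(lt2$flagged)
  ## an empty group is dropped and the test runs on the remaining two
  lt3 <- logrankTest(list(g1, list(times = numeric(0), events = numeric(0)),
                          list(times = c(1, 2, 4, 8), events = rep(1, 4))))
  expect_equal(lt3$n_groups, 2)
  expect_true(lt3$flagged)
  expect_lte(lt3$p, 1)
})

test_that("log-rank p is invariant under monotone time transforms", {
  set.seed(41)
  t0 <- rexp(30, 0.1) + 1
  e0 <- rbinom(30, 1, 0.8)
  grp <- rep(c("a", "b", "c"), each = 10)
  p1 <- logrankTest(times = t0, events = e0, group = grp)$p
  p2 <- logrankTest(times = log(t0) + 5, events = e0, group = grp)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("log-rank matches the permutation oracle on small toys", {
  t0 <- c(1, 2, 3, 4, 5, 6, 7, 9, 11, 14)
  e0 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  grp <- rep(c("a", "b"), 5)
  lt <- logrankTest(times = t0, events = e0, group = grp)
  pPerm <- oraclePermLogrank(t0, e0, grp, nPerm = 4000)
  ## chi-square approximation vs the exact permutation null: MC tolerance
  expect_lt(abs(lt$p - pPerm), 0.08)
})

test_that("survival screen standardizes, tertiles and selects per cohort", {
  set.seed(55)
  n <- 120
  pts <- sprintf("p%03d", 1:n)
  z <- rnorm(n)
  h0 <- 1 / 365
  times <- rexp(n, h0 * exp(log(4) * z))
  expr <- rbind(assoc = z, null = rnorm(n), flat = rep(1, n))
  colnames(expr) <- pts
  cohorts <- list(c1 = list(expr = expr,
                            clinical = data.frame(patient = pts,
                                                  time = times,
                                                  event = 1L)))
  expect_message(scr <- survivalScreen(rownames(expr), cohorts),
                 "untestable")
  expect_true("assoc" %in% scr$selected)
  expect_equal(scr$untestable, "flat")          # constant expression
  expect_false("flat" %in% rownames(scr$pvalues))
  ## a cohort without overlapping patients is skipped with a warning
  bad <- list(c1 = cohorts$c1,
              c2 = list(expr = expr,
                        clinical = data.frame(patient = paste0("x", 1:5),
                                              time = 1:5, event = 1L)))
  expect_warning(scr2 <- survivalScreen("assoc", bad), "no overlapping")
  expect_true(all(is.na(scr2$pvalues[, "c2"])))
})
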
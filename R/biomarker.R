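## Biomarker prioritization: central-TF target collection, secreted/
## transmembrane annotation filter, dual-contrast cancer specificity on a
## patient cohort, and a tertile Kaplan-Meier survival screen.

#' Union of target genes of a set of TFs
#'
#' @param tfs character vector of TF ids (all must be in the catalogue).
#' @param catalogue a [RegulationCatalogue-class].
#' @return Character vector of unique target genes.
#' @export
centralTfTargets <- function(tfs, catalogue) {
  stopifnot(is(catalogue, "RegulationCatalogue"))
  targetsOf(catalogue, tfs)
}

#' Restrict genes to annotation sets (secreted/transmembrane)
#'
#' Returns the genes belonging to the union of the named annotation sets,
#' together with a per-set over-representation p-value
#' ([setEnrichment()]) reported for transparency.
#'
#' @param genes character vector (subset of `universe`).
#' @param sets named list of gene sets (e.g. `secreted`, `transmembrane`).
#' @param universe background gene set.
#' @param setNames which sets to use; default all.
#' @return List with `filtered` (character) and `enrichment` (data.frame:
#'   `set`, `overlap`, `p`).
#' @export
annotationFilter <- function(genes, sets, universe, setNames = names(sets)) {
  bad <- setdiff(setNames, names(sets))
  if (length(bad) > 0)
    stop("unknown annotation set(s): ", paste(bad, collapse = ", "))
  genes <- unique(genes)
  enr <- do.call(rbind, lapply(setNames, function(s) {
    res <- setEnrichment(genes, intersect(sets[[s]], universe), universe)
    data.frame(set = s, overlap = res$overlap, p = res$p)
  }))
  keep <- intersect(genes, unique(unlist(sets[setNames])))
  list(filtered = keep, enrichment = enr)
}

#' Median/IQR normalization of patient expression
#'
#' Each gene row is centred by its median and scaled by its inter-quartile
#' range (type-7 quartiles).  Rows with zero IQR are dropped and reported.
#'
#' @param expr a [PatientCohort-class] or a genes x patients matrix of log2
#'   values.
#' @return Object of the same type, with attribute `dropped` (gene ids with
#'   zero IQR) on the matrix (or in the metadata of a `PatientCohort`).
#' @export
normalizePatientExpression <- function(expr) {
  isCohort <- is(expr, "PatientCohort")
  v <- if (isCohort) assay(expr) else as.matrix(expr)
  med <- apply(v, 1L, median)
  iqr <- apply(v, 1L, IQR, type = 7)
  drop <- iqr == 0
  if (all(drop)) stop("all gene rows have zero IQR; nothing to normalize")
  if (any(drop))
    message("dropping ", sum(drop), " zero-IQR gene row(s)")
  out <- (v[!drop, , drop = FALSE] - med[!drop]) / iqr[!drop]
  if (isCohort) {
    res <- PatientCohort(out, phenotypes(expr))
    metadata(res)$dropped <- rownames(v)[drop]
    return(res)
  }
  attr(out, "dropped") <- rownames(v)[drop]
  out
}

## Row-wise Welch two-sample t-test: matrix rows, logical column split.
.rowWelch <- function(v, inGroup) {
  x <- v[, inGroup, drop = FALSE]
  y <- v[, !inGroup, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  data.frame(delta = mx - my, t = t, df = df, p = p)
}

#' Cancer-specific genes by the dual-contrast BH rule
#'
#' Contrast A compares cancer against inflammation plus healthy; contrast B
#' compares inflammation against cancer plus healthy (per-gene Welch t-tests
#' on normalized values).  P-values are Benjamini-Hochberg corrected within
#' each contrast over the candidate genes, and a gene is called
#' cancer-specific when it is significant in A (`q_A <= alphaBh`) but not in
#' B (`q_B > alphaBh`).
#'
#' @param normExpr a normalized [PatientCohort-class], or a genes x patients
#'   matrix (then `phenotypeTable` is required).
#' @param candidateGenes genes to test (must be rows of the matrix).
#' @param alphaBh BH-corrected significance level for both contrasts
#'   (default 0.05).
#' @param phenotypeTable named character vector patient -> phenotype, used
#'   when `normExpr` is a bare matrix.
#' @return Character vector of cancer-specific genes, with attribute
#'   `table` (data.frame: gene, fold-change `lfc_cancer`, `p_A`, `q_A`,
#'   `p_B`, `q_B`).
#' @export
cancerSpecificGenes <- function(normExpr, candidateGenes, alphaBh = 0.05,
                                phenotypeTable = NULL) {
  if (is(normExpr, "PatientCohort")) {
    v <- assay(normExpr)
    ph <- unname(phenotypes(normExpr))
  } else {
    v <- as.matrix(normExpr)
    if (is.null(phenotypeTable))
      stop("phenotypeTable is required for a bare matrix")
    ph <- unname(phenotypeTable[colnames(v)])
  }
  cnt <- table(factor(ph, levels = .PHENOTYPES))
  if (any(cnt < 2L))
    stop("each phenotype needs at least 2 samples; missing/short: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  candidateGenes <- unique(candidateGenes)
  bad <- setdiff(candidateGenes, rownames(v))
  if (length(bad) > 0)
    stop("candidate genes absent from the matrix: ",
         paste(bad, collapse = ", "))
  v <- v[candidateGenes, , drop = FALSE]
  a <- .rowWelch(v, ph == "cancer")
  b <- .rowWelch(v, ph == "inflammation")
  qA <- p.adjust(a$p, method = "BH")
  qB <- p.adjust(b$p, method = "BH")
  keep <- qA <= alphaBh & qB > alphaBh
  out <- candidateGenes[keep]
  attr(out, "table") <- data.frame(
    gene = candidateGenes, lfc_cancer = a$delta, p_A = a$p, q_A = qA,
    p_B = b$p, q_B = qB, selected = keep, row.names = NULL)
  out
}

#' Tertile stratification of per-patient values
#'
#' Rank-based split at the empirical 1/3 and 2/3 quantiles; tied values are
#' assigned to the lower group, and group sizes differ by at most 1 when all
#' values are distinct.  With all values equal every patient is labelled
#' `low` (the gene is untestable downstream).
#'
#' @param values numeric vector (>= 3 patients).
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
tertileGroups <- function(values) {
  n <- length(values)
  if (n < 3L) stop("at least 3 patients are required for tertiles")
  r <- rank(values, ties.method = "min")
  k1 <- ceiling(n / 3); k2 <- ceiling(2 * n / 3)
  factor(ifelse(r <= k1, "low", ifelse(r <= k2, "mid", "high")),
         levels = c("low", "mid", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' @param times positive follow-up times.
#' @param events event status (1 = death observed, 0 = censored).
#' @return List of class `km_curve` with `time`, `surv` (survival
#'   probability after each event time), `n_risk`, `n_event`, and `fn`, a
#'   right-continuous step function with `S(0) = 1`.
#' @export
kmCurve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  if (length(times) == 0L) stop("empty group: no curve")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event,
              fn = stats::stepfun(fit$time, c(1, fit$surv), right = FALSE))
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points, final S(t) =",
      signif(x$surv[length(x$surv)], 4), "\n")
  invisible(x)
}

#' k-group log-rank test
#'
#' Chi-square log-rank statistic with `k - 1` degrees of freedom.  Empty
#' groups are removed (flagged); when fewer than 2 non-empty groups remain
#' or no event is observed, the statistic is 0 with p = 1.
#'
#' @param groups list of `list(times =, events =)` per group, or a
#'   two-element list `(times, events)` plus a `group` factor via the
#'   `group` argument.
#' @param times,events,group alternative interface: vectors plus a group
#'   factor.
#' @return List with `statistic`, `df`, `p`, `n_groups` (used) and
#'   `flagged` (TRUE when groups were dropped or the test degenerated).
#' @export
logrankTest <- function(groups = NULL, times = NULL, events = NULL,
                        group = NULL) {
  if (is.null(groups)) {
    stopifnot(!is.null(times), !is.null(events), !is.null(group))
    groups <- lapply(split(seq_along(times), group),
                     function(i) list(times = times[i], events = events[i]))
  }
  sizes <- vapply(groups, function(g) length(g$times), 0L)
  flagged <- any(sizes == 0L)
  groups <- groups[sizes > 0L]
  k <- length(groups)
  if (k < 2L)
    return(list(statistic = 0, df = 0L, p = 1, n_groups = k, flagged = TRUE))
  t <- unlist(lapply(groups, `[[`, "times"))
  e <- unlist(lapply(groups, `[[`, "events"))
  gl <- rep(seq_len(k), vapply(groups, function(g) length(g$times), 0L))
  if (sum(e) == 0)
    return(list(statistic = 0, df = k - 1L, p = 1, n_groups = k,
                flagged = TRUE))
  sd <- survival::survdiff(survival::Surv(t, e) ~ gl)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p = pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE),
       n_groups = k, flagged = flagged)
}

#' Tertile survival screen across cancer cohorts
#'
#' For every gene and cohort the expression vector is standardized (median
#' subtraction, IQR division), patients are split into expression tertiles,
#' and a 3-group log-rank test is run on the corresponding Kaplan-Meier
#' curves.  A gene passes when `p <= alpha` in at least one cohort (no
#' cross-cohort multiplicity correction, matching the published screen).
#' Cohorts from different platforms are treated as separate entries of
#' `cohorts` and screened independently.
#'
#' @param genes genes to screen.
#' @param cohorts named list; each element is a `list(expr =, clinical =)`
#'   with a genes x patients matrix and a data.frame with columns
#'   `patient`, `time` (days, > 0), `event` (0/1).
#' @param alpha log-rank significance level (default 0.05).
#' @return List of class `survival_screen`: `pvalues` (gene x cohort
#'   matrix, NA when untestable), `selected` (genes significant in >= 1
#'   cohort), `untestable` (genes untestable in every cohort, excluded from
#'   `pvalues`), `alpha`.
#' @export
survivalScreen <- function(genes, cohorts, alpha = 0.05) {
  stopifnot(length(cohorts) > 0, !is.null(names(cohorts)))
  genes <- unique(genes)
  pv <- matrix(NA_real_, length(genes), length(cohorts),
               dimnames = list(genes, names(cohorts)))
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    cl <- co$clinical
    stopifnot(all(c("patient", "time", "event") %in% names(cl)))
    if (any(cl$time <= 0)) stop("follow-up times must be positive (", cn, ")")
    if (anyDuplicated(cl$patient))
      stop("duplicate patients in cohort ", cn)
    pts <- intersect(colnames(co$expr), cl$patient)
    if (length(pts) == 0L) {
      warning("cohort ", cn, " has no overlapping patients; skipped")
      next
    }
    cl <- cl[match(pts, cl$patient), , drop = FALSE]
    for (gene in intersect(genes, rownames(co$expr))) {
      v <- co$expr[gene, pts]
      iqr <- IQR(v, type = 7)
      if (iqr == 0) next  # untestable: constant expression
      z <- (v - median(v)) / iqr
      grp <- tertileGroups(z)
      if (length(unique(grp[!is.na(grp)])) < 2L) next
      lt <- logrankTest(times = cl$time, events = cl$event, group = grp)
      pv[gene, cn] <- lt$p
    }
  }
  untestable <- rownames(pv)[rowSums(!is.na(pv)) == 0L]
  if (length(untestable) > 0)
    message(length(untestable), " gene(s) untestable in every cohort")
  pv <- pv[!rownames(pv) %in% untestable, , drop = FALSE]
  selected <- rownames(pv)[apply(pv, 1L, function(p)
    any(p <= alpha, na.rm = TRUE))]
  out <- list(pvalues = pv, selected = selected, untestable = untestable,
              alpha = alpha)
  class(out) <- "survival_screen"
  out
}

#' @export
print.survival_screen <- function(x, ...) {
  cat("Survival screen:", nrow(x$pvalues), "genes x", ncol(x$pvalues),
      "cohorts;", length(x$selected), "gene(s) with log-rank p <=", x$alpha,
      "in >= 1 cohort\n")
  invisible(x)
}
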
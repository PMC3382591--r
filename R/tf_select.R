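## TF selection: TF-TF Pearson correlation profiles from the regulation (R),
## expression (E) and CNV (C) matrices, and the per-TF linear model
## R = b0 + b1*E + b2*C over profile entries.

#' Collapse replicate columns to per-line means
#'
#' @param expr a [LineExpression-class].
#' @return Numeric matrix, genes x cell lines (replicate means).
#' @export
lineMeans <- function(expr) {
  stopifnot(is(expr, "LineExpression"))
  map <- cellLines(expr)
  lines <- unique(unname(map))
  v <- assay(expr)
  out <- vapply(lines, function(l) rowMeans(v[, map == l, drop = FALSE]),
                numeric(nrow(v)))
  dimnames(out) <- list(rownames(v), lines)
  out
}

#' TF-TF correlation profiles from the three matrices
#'
#' Builds three TF x TF Pearson correlation matrices over a shared TF roster
#' and shared cell-line columns: regulation (`R`, from the score matrix),
#' expression (`E`, replicate-collapsed expression of the TF-encoding genes)
#' and CNV (`C`, median-normalized locus values).  Rows with zero variance
#' yield missing correlations and the TF is flagged.
#'
#' @param scores TF x cell-line regulation score matrix ([tfScores()]).
#' @param expr a [LineExpression-class] (TF-encoding genes must be rows) or a
#'   genes x cell-line matrix already collapsed over replicates.
#' @param cnv genes x cell-line CNV matrix ([geneCnvMatrix()]).
#' @param roster TFs to use; defaults to TFs significantly regulated in at
#'   least one cell line (score > 0 somewhere).  TFs absent from the
#'   expression or CNV rows are dropped with a message.
#' @return List with correlation matrices `R`, `E`, `C`, the `roster`,
#'   `lines` used, and `zero_variance` (list of flagged TFs per matrix).
#' @export
correlationProfiles <- function(scores, expr, cnv, roster = NULL) {
  E <- if (is(expr, "LineExpression")) lineMeans(expr) else as.matrix(expr)
  if (is.null(roster))
    roster <- rownames(scores)[rowSums(scores > 0) > 0]
  missing <- setdiff(roster, intersect(rownames(E), rownames(cnv)))
  if (length(missing) > 0) {
    message("dropping ", length(missing),
            " roster TF(s) absent from expression or CNV rows")
    roster <- setdiff(roster, missing)
  }
  if (length(roster) < 4L)
    stop("roster too small (", length(roster), " TFs); need at least 4")
  lines <- Reduce(intersect, list(colnames(scores), colnames(E),
                                  colnames(cnv)))
  if (length(lines) < 3L)
    stop("fewer than 3 shared cell lines; correlations undefined")
  mats <- list(R = scores[roster, lines, drop = FALSE],
               E = E[roster, lines, drop = FALSE],
               C = cnv[roster, lines, drop = FALSE])
  zv <- lapply(mats, function(m) roster[apply(m, 1L, sd) == 0])
  cors <- lapply(mats, function(m) {
    cc <- suppressWarnings(cor(t(m)))  # zero-variance rows -> NA
    diag(cc) <- 1
    cc
  })
  list(R = cors$R, E = cors$E, C = cors$C, roster = roster, lines = lines,
       zero_variance = zv)
}

#' Ordinary least squares of a regulation profile on expression and CNV
#' profiles
#'
#' The computational core of [fitTfModel()], exposed for direct use on
#' profile vectors: `r = b0 + b1*e + b2*c` with two-sided t-tests on the
#' slopes.  Pairs with missing values are removed; the fit is flagged
#' `degenerate` for fewer than 4 complete points, a rank-deficient design,
#' or a zero-variance response.
#'
#' @param r,e,c numeric vectors of equal length (regulation, expression and
#'   CNV profile entries).
#' @param tf label for the output row.
#' @return One-row data.frame: `tf`, `b0`, `b1`, `b2`, `se1`, `se2`, `p1`,
#'   `p2`, `n`, `status`.
#' @export
fitRegulationModel <- function(r, e, c, tf = "tf") {
  stopifnot(length(r) == length(e), length(r) == length(c))
  ok <- complete.cases(r, e, c)
  r <- r[ok]; e <- e[ok]; c_ <- c[ok]
  n <- length(r)
  out <- data.frame(tf = tf, b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                    se1 = NA_real_, se2 = NA_real_,
                    p1 = NA_real_, p2 = NA_real_, n = n,
                    status = "degenerate", stringsAsFactors = FALSE)
  if (n < 4L) return(out)
  X <- cbind(1, e, c_)
  if (qr(X)$rank < 3L || sd(r) == 0) {
    fit <- tryCatch(lm(r ~ e + c_), error = function(err) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      out$b0 <- unname(cf[1L]); out$b1 <- unname(cf[2L])
      out$b2 <- unname(cf[3L])
    }
    return(out)
  }
  fit <- lm(r ~ e + c_)
  sm <- summary(fit)$coefficients
  out$b0 <- sm[1L, 1L]; out$b1 <- sm[2L, 1L]; out$b2 <- sm[3L, 1L]
  out$se1 <- sm[2L, 2L]; out$se2 <- sm[3L, 2L]
  out$p1 <- sm[2L, 4L]; out$p2 <- sm[3L, 4L]
  out$status <- "ok"
  out
}

#' Fit the per-TF regulation model on correlation profiles
#'
#' Ordinary least squares of one TF's regulation profile on its expression
#' and CNV profiles, `R = b0 + b1*E + b2*C`, over the other roster TFs
#' (the self-correlation entry is excluded; profile points with any missing
#' value are removed pairwise).  Slope p-values are two-sided t-tests.  The
#' fit is flagged `degenerate` when fewer than 4 complete points remain, the
#' design is rank-deficient, or the response has zero variance.
#'
#' @param profiles output of [correlationProfiles()].
#' @param tf a TF id present in the roster.
#' @return One-row data.frame: `tf`, `b0`, `b1`, `b2`, `p1`, `p2`, `n`,
#'   `status` (`"ok"`/`"degenerate"`).
#' @export
fitTfModel <- function(profiles, tf) {
  if (!tf %in% profiles$roster) stop("TF not in roster: ", tf)
  others <- setdiff(profiles$roster, tf)
  fitRegulationModel(profiles$R[tf, others], profiles$E[tf, others],
                     profiles$C[tf, others], tf = tf)
}

#' Fit the regulation model for every roster TF
#'
#' @param profiles output of [correlationProfiles()].
#' @return data.frame with one row per roster TF (see [fitTfModel()]).
#' @export
fitTfModels <- function(profiles) {
  out <- do.call(rbind, lapply(profiles$roster,
                               function(tf) fitTfModel(profiles, tf)))
  rownames(out) <- NULL
  out
}

#' Select correlatively regulated TFs
#'
#' A TF is selected when its fit status is `ok` and both slope p-values are
#' at or below `alpha` (boundary inclusive).  No multiplicity correction is
#' applied across TFs, matching the published selection rule; set
#' `adjust = "BH"` for an FDR-corrected variant.
#'
#' @param fits data.frame from [fitTfModels()].
#' @param alpha per-slope significance level, default 0.05.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()]
#'   applied to each slope's p-values across TFs.
#' @return Character vector of selected TF ids.
#' @export
selectTfs <- function(fits, alpha = 0.05, adjust = "none") {
  p1 <- fits$p1; p2 <- fits$p2
  if (adjust != "none") {
    p1 <- p.adjust(p1, method = adjust)
    p2 <- p.adjust(p2, method = adjust)
  }
  keep <- fits$status == "ok" & !is.na(p1) & !is.na(p2) &
    p1 <= alpha & p2 <= alpha
  fits$tf[keep]
}
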
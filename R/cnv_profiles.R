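## CNV profiles: turn a GISTIC-style significant-region table into a
## gene-level log2-ratio matrix via per-region median normalization.
##
## A region table is a data.frame with metadata columns
##   chrom, start, end, region_id, type ("amp"/"del"), q
## (0-based half-open coordinates) followed by one numeric column per sample
## holding the region's peak log2-ratio in that sample.  Several peak rows
## may share a region_id.

.REGION_META <- c("chrom", "start", "end", "region_id", "type", "q")

.checkRegions <- function(regions) {
  miss <- setdiff(.REGION_META, names(regions))
  if (length(miss) > 0)
    stop("region table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(regions$start >= regions$end))
    stop("region coordinates must satisfy start < end (0-based half-open)")
  if (any(is.na(regions$q)) || any(regions$q < 0 | regions$q > 1))
    stop("region q-values must lie in [0, 1]")
  invisible(regions)
}

.regionSamples <- function(regions) setdiff(names(regions), .REGION_META)

#' Keep significantly altered regions
#'
#' Filters a GISTIC-style region table to rows with `q <= qMax`
#' (boundary inclusive), preserving row order.  An empty result is allowed
#' and reported via a message.
#'
#' @param regions region table (see package details above).
#' @param qMax q-value threshold, default 0.25.
#' @return The filtered region table.
#' @export
filterSignificantRegions <- function(regions, qMax = 0.25) {
  .checkRegions(regions)
  out <- regions[regions$q <= qMax, , drop = FALSE]
  if (nrow(out) == 0L)
    message("no region passes q <= ", qMax)
  rownames(out) <- NULL
  out
}

#' Per-region, per-sample median of significant CNV peaks
#'
#' Peak rows sharing a `region_id` are collapsed to their median value per
#' sample; a region with a single peak contributes that peak's value.
#' Missing per-sample values are propagated as `NA`.
#'
#' @param regions a (significance-filtered) region table.
#' @return Numeric matrix, unique region ids x samples.
#' @export
regionMedians <- function(regions) {
  .checkRegions(regions)
  samples <- .regionSamples(regions)
  ids <- unique(regions$region_id)
  out <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
  for (id in ids) {
    rows <- regions[regions$region_id == id, samples, drop = FALSE]
    out[id, ] <- apply(as.matrix(rows), 2L, function(v)
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  }
  out
}

#' Gene-level CNV matrix from significant regions
#'
#' Every gene overlapping a significant region (any base overlap by default)
#' is assigned that region's per-sample median ([regionMedians()]); genes
#' overlapping no region carry the no-alteration sentinel 0 in all samples.
#' A gene overlapping several regions is resolved by smallest q, then larger
#' absolute overall median, then lexicographic region id.  Chromosomes X and
#' Y are excluded by default (regions and genes there yield 0 rows).
#'
#' @param regions region table; filtered to `q <= qMax` internally.
#' @param locations gene-location table: data.frame with columns `gene`,
#'   `chrom`, `start`, `end` (0-based half-open, unique gene ids).
#' @param samples sample ids to emit (default: all sample columns of
#'   `regions`).
#' @param qMax significance threshold passed to
#'   [filterSignificantRegions()].
#' @param assign `"overlap"` (any base overlap, default) or `"midpoint"`
#'   (gene midpoint contained in the region).
#' @param dropSexChromosomes exclude chrX/chrY (default `TRUE`).
#' @return Numeric matrix, genes x samples, with attribute `assigned_region`
#'   (named character: gene -> region id for altered genes).
#' @export
geneCnvMatrix <- function(regions, locations, samples = NULL, qMax = 0.25,
                          assign = c("overlap", "midpoint"),
                          dropSexChromosomes = TRUE) {
  assign <- match.arg(assign)
  stopifnot(is.data.frame(locations),
            all(c("gene", "chrom", "start", "end") %in% names(locations)))
  if (anyDuplicated(locations$gene)) stop("duplicate gene ids in locations")
  if (any(locations$start >= locations$end))
    stop("gene coordinates must satisfy start < end (0-based half-open)")
  regions <- filterSignificantRegions(regions, qMax = qMax)
  if (is.null(samples)) samples <- .regionSamples(regions)
  sex <- c("chrX", "chrY", "X", "Y")
  if (dropSexChromosomes)
    regions <- regions[!regions$chrom %in% sex, , drop = FALSE]
  genes <- locations$gene
  out <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(regions) == 0L) {
    attr(out, "assigned_region") <- character(0)
    return(out)
  }
  med <- regionMedians(regions)
  ## one row per unique region: hull coordinates, smallest q
  meta <- do.call(rbind, lapply(unique(regions$region_id), function(id) {
    r <- regions[regions$region_id == id, , drop = FALSE]
    data.frame(region_id = id, chrom = r$chrom[1L], start = min(r$start),
               end = max(r$end), q = min(r$q))
  }))
  meta$score <- apply(med[meta$region_id, , drop = FALSE], 1L,
                      function(v) if (all(is.na(v))) 0
                                  else abs(median(v, na.rm = TRUE)))
  loc <- locations
  if (dropSexChromosomes) loc <- loc[!loc$chrom %in% sex, , drop = FALSE]
  ## 0-based half-open -> 1-based closed for IRanges
  if (assign == "midpoint") {
    mid <- floor((loc$start + loc$end) / 2)
    gGR <- GRanges(loc$chrom, IRanges(mid + 1L, mid + 1L))
  } else {
    gGR <- GRanges(loc$chrom, IRanges(loc$start + 1L, loc$end))
  }
  rGR <- GRanges(meta$chrom, IRanges(meta$start + 1L, meta$end))
  hits <- findOverlaps(gGR, rGR)
  assigned <- character(0)
  if (length(hits) > 0) {
    h <- data.frame(gene = loc$gene[S4Vectors::queryHits(hits)],
                    ridx = S4Vectors::subjectHits(hits))
    h$q <- meta$q[h$ridx]
    h$score <- meta$score[h$ridx]
    h$region_id <- meta$region_id[h$ridx]
    h <- h[order(h$gene, h$q, -h$score, h$region_id), , drop = FALSE]
    h <- h[!duplicated(h$gene), , drop = FALSE]
    out[h$gene, ] <- med[h$region_id, samples, drop = FALSE]
    assigned <- setNames(h$region_id, h$gene)
  }
  attr(out, "assigned_region") <- assigned
  out
}
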
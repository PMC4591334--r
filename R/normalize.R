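#' Filter sequences by total raw count
#'
#' Keeps sequence rows whose sum across all samples reaches `minTotal` raw
#' counts (default 500, "at least" inclusive). The filter is defined on raw,
#' unnormalized counts and before locus summation; applying it to a
#' normalized table is an error. Row order is preserved.
#'
#' @param x a raw `MirCountSet`.
#' @param minTotal minimum across-sample raw count sum.
#' @return the filtered `MirCountSet`.
#' @examples
#' m <- matrix(c(499L, 1L, 500L, 0L, 250L, 251L), 3, 2, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("a", "b")))
#' x <- MirCountSet(m, locus = c("L1", "L2", "L3"))
#' nrow(filterMinTotal(x, 500))  # 2
#' @export
filterMinTotal <- function(x, minTotal = 500) {
  stopifnot(is(x, "MirCountSet"))
  if (normMethod(x) != "raw")
    stop("filterMinTotal is defined on raw counts (before normalization); ",
         "got normalization = ", normMethod(x))
  x[rowSums(assay(x, "counts")) >= minTotal, ]
}

#' Normalize counts per million genome-mappable reads
#'
#' Each cell becomes `raw * 1e6 / mappable_reads(sample)`, with the
#' denominator taken from the per-sample genome-mappable totals in
#' `colData(x)$mappable_reads` (not the column sum of the table).
#'
#' @param x a raw `MirCountSet` whose `colData` carries `mappable_reads`.
#' @return a `MirCountSet` tagged `cpm_mappable`.
#' @export
normalizeCpmMappable <- function(x) {
  stopifnot(is(x, "MirCountSet"))
  if (normMethod(x) != "raw")
    stop("input is already normalized (", normMethod(x), ")")
  mr <- mappableReads(x)  # errors if missing or non-positive
  m <- sweep(assay(x, "counts"), 2L, mr / 1e6, "/")
  y <- x
  assay(y, "counts") <- m
  y@normalization <- "cpm_mappable"
  validObject(y)
  y
}

#' Normalize by the geometric mean of a spike-in and a reference RNA
#'
#' Per sample, every cell is divided by `sqrt(spike * reference)` — the
#' geometric mean of the exogenous spike-in locus (default ath-miR-159a) and
#' a stable, abundant endogenous locus (default hsa-miR-486-5p) — and then
#' multiplied by a fixed global scale (default: the dataset mean of the
#' per-sample geometric means) so values stay on a count-like scale.
#'
#' @param x a raw `MirCountSet` (sequence or locus level).
#' @param spikeId,referenceId locus IDs of the spike-in and reference RNAs;
#'   at sequence level all sequence variants of the locus are summed.
#' @param scale global rescaling constant; `NULL` for the dataset mean of the
#'   per-sample geometric means.
#' @return a `MirCountSet` tagged `spike_geomean`.
#' @export
normalizeSpikeGeomean <- function(x, spikeId = "ath-miR-159a",
                                  referenceId = "hsa-miR-486-5p",
                                  scale = NULL) {
  stopifnot(is(x, "MirCountSet"))
  if (normMethod(x) != "raw")
    stop("input is already normalized (", normMethod(x), ")")
  loc <- locusAssignments(x)
  pick <- function(id) {
    rows <- which(loc == id | rownames(x) == id)
    if (!length(rows)) stop("locus '", id, "' not present in the table")
    colSums(assay(x, "counts")[rows, , drop = FALSE])
  }
  spike <- pick(spikeId)
  ref <- pick(referenceId)
  zero <- colnames(x)[spike == 0 | ref == 0]
  if (length(zero))
    stop("zero spike-in or reference count in sample(s): ",
         paste(zero, collapse = ", "))
  geo <- sqrt(spike * ref)
  if (is.null(scale)) scale <- mean(geo)
  m <- sweep(assay(x, "counts"), 2L, geo, "/") * scale
  y <- x
  assay(y, "counts") <- m
  y@normalization <- "spike_geomean"
  validObject(y)
  y
}

#' Sum sequence variants per miRNA locus
#'
#' Collapses a sequence-level table to one row per locus by summing all
#' sequences assigned to the locus, preserving the normalization tag (the
#' normalizations are linear, so summing commutes with them).
#'
#' @param x a sequence-level `MirCountSet`.
#' @return a locus-level `MirCountSet` with loci in order of first
#'   appearance.
#' @export
sumByLocus <- function(x) {
  stopifnot(is(x, "MirCountSet"))
  if (exprLevel(x) == "locus") return(x)
  loc <- locusAssignments(x)
  ord <- unique(loc)
  m <- rowsum(assay(x, "counts"), group = loc, reorder = FALSE)
  m <- m[ord, , drop = FALSE]
  MirCountSet(m, sampleData = colData(x), locus = rownames(m),
              normalization = normMethod(x), level = "locus")
}

#' Drop low-expressed loci by control-group mean
#'
#' Keeps loci whose arithmetic mean in the control group reaches
#' `minControlMean` (default 3.6 normalized counts, the threshold that
#' removes the lowest quarter of loci in a typical plasma exosome dataset).
#' Alternatively, `q` drops the lowest `q` fraction of loci ranked by
#' control-group mean (ties broken by locus ID).
#'
#' @param x a locus-level `MirCountSet`.
#' @param minControlMean absolute threshold on the control-group mean.
#' @param q if non-`NULL`, quantile mode: drop the `floor(q * nLoci)` loci
#'   with the lowest control means instead of using the absolute threshold.
#' @param controlLabel group label of the control samples.
#' @return the filtered `MirCountSet`.
#' @export
filterLowExpression <- function(x, minControlMean = 3.6, q = NULL,
                                controlLabel = "control") {
  stopifnot(is(x, "MirCountSet"))
  if (!"group" %in% colnames(colData(x)))
    stop("colData has no 'group' column")
  ctrl <- which(as.character(colData(x)$group) == controlLabel)
  if (!length(ctrl)) stop("no samples labelled '", controlLabel, "'")
  means <- rowMeans(assay(x, "counts")[, ctrl, drop = FALSE])
  if (!is.null(q)) {
    stopifnot(q >= 0, q < 1)
    nd <- floor(q * nrow(x))
    drop <- order(means, rownames(x))[seq_len(nd)]
    keep <- setdiff(seq_len(nrow(x)), drop)
  } else {
    keep <- which(means >= minControlMean)
  }
  x[sort(keep), ]
}
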
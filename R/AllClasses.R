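#' Container for small-RNA count tables
#'
#' `MirCountSet` extends [SummarizedExperiment::SummarizedExperiment] with two
#' bookkeeping slots: the normalization state of the single `counts` assay and
#' the row level (`"sequence"` for individual isomiR sequence variants,
#' `"locus"` for values summed per mature miRNA locus). Sequence-level objects
#' carry the sequence-to-locus assignment in `rowData(x)$locus`; sample
#' metadata (diagnostic group, sex, age, preparation batch, genome-mappable
#' read count) lives in `colData(x)`.
#'
#' @slot normalization one of `"raw"`, `"cpm_mappable"`, `"spike_geomean"`.
#' @slot level one of `"sequence"`, `"locus"`.
#' @export
setClass("MirCountSet",
  contains = "SummarizedExperiment",
  slots = c(normalization = "character", level = "character"),
  prototype = prototype(normalization = "raw", level = "sequence")
)

setValidity("MirCountSet", function(object) {
  msg <- character()
  if (length(object@normalization) != 1L ||
      !object@normalization %in% c("raw", "cpm_mappable", "spike_geomean"))
    msg <- c(msg, "normalization must be 'raw', 'cpm_mappable' or 'spike_geomean'")
  if (length(object@level) != 1L || !object@level %in% c("sequence", "locus"))
    msg <- c(msg, "level must be 'sequence' or 'locus'")
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts must not contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (identical(object@normalization, "raw") &&
          any(abs(m - round(m)) > 1e-8))
        msg <- c(msg, "raw counts must be integers")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "row (sequence/locus) IDs must be present and unique")
  if (!"locus" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'locus' column")
  else if (any(is.na(rowData(object)$locus)) ||
           any(!nzchar(rowData(object)$locus)))
    msg <- c(msg, "every locus ID must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a MirCountSet
#'
#' @param counts numeric matrix (rows: sequences or loci; columns: samples)
#'   with row and column names.
#' @param sampleData `data.frame`/`DataFrame` of per-sample metadata. If it has
#'   a `sample_id` column it is matched against `colnames(counts)`.
#' @param locus character vector assigning each row to a miRNA locus
#'   (required at sequence level; defaults to the rownames at locus level).
#' @param normalization,level see [MirCountSet-class].
#' @return A `MirCountSet`.
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
#' MirCountSet(m, locus = c("miR-1", "miR-1", "miR-2"))
#' @export
MirCountSet <- function(counts, sampleData = NULL, locus = NULL,
                        normalization = "raw", level = "sequence") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have row and column names")
  if (is.null(locus)) {
    if (identical(level, "sequence"))
      stop("sequence-level tables require a 'locus' assignment per row")
    locus <- rownames(counts)
  }
  rd <- DataFrame(locus = as.character(locus), row.names = rownames(counts))
  if (is.null(sampleData)) {
    cd <- DataFrame(row.names = colnames(counts))
  } else {
    cd <- as(as.data.frame(sampleData), "DataFrame")
    if ("sample_id" %in% colnames(cd)) rownames(cd) <- cd$sample_id
    if (is.null(rownames(cd)) || !setequal(rownames(cd), colnames(counts)))
      stop("sampleData rows must match the count matrix sample IDs")
    cd <- cd[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("MirCountSet", se, normalization = normalization, level = level)
}

#' @describeIn MirCountSet normalization tag of the assay.
#' @param x,object a `MirCountSet`.
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname MirCountSet
#' @export
setMethod("normMethod", "MirCountSet", function(x) x@normalization)

#' @describeIn MirCountSet row level (`"sequence"` or `"locus"`).
#' @export
setGeneric("exprLevel", function(x) standardGeneric("exprLevel"))

#' @rdname MirCountSet
#' @export
setMethod("exprLevel", "MirCountSet", function(x) x@level)

#' @describeIn MirCountSet named locus assignment of each row.
#' @export
setGeneric("locusAssignments", function(x) standardGeneric("locusAssignments"))

#' @rdname MirCountSet
#' @export
setMethod("locusAssignments", "MirCountSet", function(x)
  setNames(as.character(rowData(x)$locus), rownames(x)))

#' @describeIn MirCountSet factor of diagnostic group labels from
#'   `colData(x)$group`.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname MirCountSet
#' @export
setMethod("sampleGroups", "MirCountSet", function(x) {
  if (!"group" %in% colnames(colData(x)))
    stop("colData has no 'group' column")
  g <- factor(colData(x)$group)
  if (nlevels(g) != 2L)
    stop("group labels must cover exactly two classes, got: ",
         paste(levels(g), collapse = ", "))
  setNames(g, colnames(x))
})

#' @describeIn MirCountSet per-sample genome-mappable read totals from
#'   `colData(x)$mappable_reads`.
#' @export
setGeneric("mappableReads", function(x) standardGeneric("mappableReads"))

#' @rdname MirCountSet
#' @export
setMethod("mappableReads", "MirCountSet", function(x) {
  if (!"mappable_reads" %in% colnames(colData(x)))
    stop("colData has no 'mappable_reads' column")
  mr <- colData(x)$mappable_reads
  if (anyNA(mr) || any(mr <= 0)) stop("mappable_reads must be positive")
  setNames(as.numeric(mr), colnames(x))
})

setMethod("show", "MirCountSet", function(object) {
  cat("MirCountSet (", object@level, "-level, ", object@normalization, ")\n",
      sep = "")
  cat(nrow(object), " rows x ", ncol(object), " samples; ",
      length(unique(rowData(object)$locus)), " loci\n", sep = "")
  if ("group" %in% colnames(colData(object))) {
    tb <- table(colData(object)$group)
    cat("groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' Ground truth of a simulated cohort
#'
#' Records every effect planted by [simulateCohort()]: differentially
#' expressed loci with their true case/control ratios, correlated-module
#' membership, the informative loci carrying class signal, and the spike-in
#' locus.
#'
#' @slot deRatios named numeric; planted AD/control expression ratios.
#' @slot modules list of `list(loci=, group=, loading=)` planted cliques.
#' @slot informative character; loci carrying class signal.
#' @slot spike character; spike-in locus ID.
#' @export
setClass("SimTruth", slots = c(
  deRatios = "numeric", modules = "list",
  informative = "character", spike = "character"
))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@deRatios) && any(object@deRatios <= 0))
    msg <- c(msg, "planted ratios must be > 0")
  for (m in object@modules)
    if (!all(c("loci", "group", "loading") %in% names(m)))
      msg <- c(msg, "each module needs 'loci', 'group', 'loading'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@deRatios), "DE loci;",
      length(object@modules), "planted modules; spike =", object@spike, "\n")
})

#' @describeIn SimTruth planted differential-expression ratios.
#' @param x a `SimTruth`.
#' @export
setGeneric("plantedRatios", function(x) standardGeneric("plantedRatios"))

#' @rdname SimTruth
#' @export
setMethod("plantedRatios", "SimTruth", function(x) x@deRatios)

#' @describeIn SimTruth planted correlated modules.
#' @export
setGeneric("plantedModules", function(x) standardGeneric("plantedModules"))

#' @rdname SimTruth
#' @export
setMethod("plantedModules", "SimTruth", function(x) x@modules)

#' @describeIn SimTruth loci planted to carry class signal.
#' @export
setGeneric("informativeLoci", function(x) standardGeneric("informativeLoci"))

#' @rdname SimTruth
#' @export
setMethod("informativeLoci", "SimTruth", function(x) x@informative)
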
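#' Per-locus grand means
#'
#' Arithmetic mean of each locus across *all* samples, both groups pooled —
#' the reference level against which per-sample fold changes are computed.
#'
#' @param x a locus-level `MirCountSet` or numeric matrix (loci in rows).
#' @return named numeric vector of per-locus means.
#' @export
grandMeans <- function(x) {
  m <- if (is(x, "MirCountSet")) assay(x, "counts") else as.matrix(x)
  rowMeans(m)
}

#' Bounded log3 fold-change features
#'
#' The classifier feature transform: for each locus and sample the fold
#' change `FC = value / grandMean(locus)` is computed; fold changes within
#' the dead zone (strictly between 0.90 and 1.10, i.e. less than a 10%
#' change) are rounded to 1; the feature is `log3(FC)` range-limited to
#' `[-1, +1]`. A 3-fold change therefore saturates the feature, values
#' exactly at the dead-zone boundaries are *not* rounded, and a zero
#' expression value maps to -1 (the clamp of log3(0)). Outside the dead zone
#' and before clamping the transform is antisymmetric,
#' `f(FC) = -f(1/FC)`, and invariant to rescaling a locus together with its
#' grand mean.
#'
#' @param x a locus-level `MirCountSet` or matrix of normalized expression.
#' @param grand per-locus reference means; defaults to [grandMeans()] of `x`
#'   itself. Supply externally (e.g. the training cohort's means) to
#'   transform held-out data.
#' @param deadZone open interval of fold changes rounded to 1.
#' @param clampRange feature range limits.
#' @return matrix of features (loci in rows, samples in columns) with the
#'   reference means in `attr(, "grandMeans")`.
#' @examples
#' m <- matrix(c(1, 3, 9, 2, 2.1, 0), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' log3FoldFeatures(m, grand = c(a = 2, b = 3, c = 4))
#' @export
log3FoldFeatures <- function(x, grand = NULL, deadZone = c(0.90, 1.10),
                             clampRange = c(-1, 1)) {
  m <- if (is(x, "MirCountSet")) assay(x, "counts") else as.matrix(x)
  if (is.null(grand)) grand <- grandMeans(m)
  if (!is.null(names(grand))) {
    miss <- setdiff(rownames(m), names(grand))
    if (length(miss))
      stop("no grand mean supplied for: ", paste(head(miss), collapse = ", "))
    grand <- grand[rownames(m)]
  }
  if (length(grand) != nrow(m))
    stop("grand means must match the matrix rows")
  bad <- grand == 0 & rowSums(m > 0) > 0
  if (any(bad))
    stop("zero grand mean with nonzero expression at: ",
         paste(head(rownames(m)[bad]), collapse = ", "))
  fc <- m / grand
  fc[grand == 0, ] <- 1  # all-zero locus: no change by definition
  fc[fc > deadZone[1] & fc < deadZone[2]] <- 1
  f <- log(fc) / log(3)
  f <- pmin(pmax(f, clampRange[1]), clampRange[2])
  attr(f, "grandMeans") <- grand
  attr(f, "deadZone") <- deadZone
  f
}
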
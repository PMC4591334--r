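#' All pairwise Spearman correlations within a sample set
#'
#' Computes the Spearman rank correlation (midranks for ties) for every
#' locus pair over the given samples, with a two-sided p-value from the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom. For 35 samples per group a rho of about 0.33 sits at
#' p = 0.05. Loci constant within the sample set yield `NA` correlations.
#'
#' @param x a locus-level `MirCountSet` (or numeric matrix, loci in rows).
#' @param samples sample IDs (or logical/integer index) selecting the group;
#'   `NULL` uses all samples. At least 4 samples are required.
#' @return `data.frame(locus_i, locus_j, rho, p, n)` with one row per
#'   unordered pair, `locus_i` preceding `locus_j` in matrix row order.
#' @export
spearmanAllPairs <- function(x, samples = NULL) {
  m <- if (is(x, "MirCountSet")) assay(x, "counts") else as.matrix(x)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  n <- ncol(m)
  if (n < 4L) stop("need at least 4 samples for correlation analysis")
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  r <- rho[idx]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(locus_i = rownames(m)[idx[, 1L]],
             locus_j = rownames(m)[idx[, 2L]],
             rho = r, p = p, n = n, row.names = NULL)
}

#' Differential-correlation categories for all locus pairs
#'
#' Joins the per-group correlation tables and assigns the six standard
#' differential-correlation flags for thresholds `rhoThresh` (default 0.5)
#' and `diffThresh` (default 0.5):
#' \describe{
#'   \item{a}{both group rhos > `rhoThresh` (correlated in both groups)}
#'   \item{b}{AD rho > `rhoThresh` and (AD - control) > `diffThresh`}
#'   \item{c}{control rho > `rhoThresh` and (control - AD) > `diffThresh`}
#'   \item{d}{both group rhos < `-rhoThresh`}
#'   \item{e}{AD rho < `-rhoThresh` and (control - AD) > `diffThresh`}
#'   \item{f}{control rho < `-rhoThresh` and (AD - control) > `diffThresh`}
#' }
#' Pairs with an `NA` rho in a group fail that group's predicates. Swapping
#' the two input tables maps flag b to c and e to f (and fixes a, d).
#'
#' @param pcAD,pcCtrl outputs of [spearmanAllPairs()] for the case and
#'   control samples over the same pair universe.
#' @param rhoThresh,diffThresh thresholds (defaults 0.5).
#' @param requireSignificance also require the correlation p-value below
#'   `alpha` in the group(s) whose rho enters the predicate (off by default;
#'   with 35 samples a rho of 0.5 is far below p = 0.05 anyway).
#' @param alpha level used when `requireSignificance = TRUE`.
#' @return `data.frame(locus_i, locus_j, rho_AD, p_AD, rho_ctrl, p_ctrl,
#'   diff, abs_diff, flag_a..flag_f)`.
#' @export
categorizePairs <- function(pcAD, pcCtrl, rhoThresh = 0.5, diffThresh = 0.5,
                            requireSignificance = FALSE, alpha = 0.05) {
  keyA <- paste(pcAD$locus_i, pcAD$locus_j, sep = "\r")
  keyB <- paste(pcCtrl$locus_i, pcCtrl$locus_j, sep = "\r")
  if (!identical(sort(keyA), sort(keyB)))
    stop("the two correlation tables cover different pair sets")
  pcCtrl <- pcCtrl[match(keyA, keyB), , drop = FALSE]
  rA <- pcAD$rho; rC <- pcCtrl$rho
  d <- rA - rC
  gt <- function(v, th) !is.na(v) & v > th
  lt <- function(v, th) !is.na(v) & v < th
  sigA <- if (requireSignificance) !is.na(pcAD$p) & pcAD$p < alpha else TRUE
  sigC <- if (requireSignificance) !is.na(pcCtrl$p) & pcCtrl$p < alpha else TRUE
  data.frame(
    locus_i = pcAD$locus_i, locus_j = pcAD$locus_j,
    rho_AD = rA, p_AD = pcAD$p, rho_ctrl = rC, p_ctrl = pcCtrl$p,
    diff = d, abs_diff = abs(d),
    flag_a = gt(rA, rhoThresh) & gt(rC, rhoThresh) & sigA & sigC,
    flag_b = gt(rA, rhoThresh) & gt(d, diffThresh) & sigA,
    flag_c = gt(rC, rhoThresh) & gt(-d, diffThresh) & sigC,
    flag_d = lt(rA, -rhoThresh) & lt(rC, -rhoThresh) & sigA & sigC,
    flag_e = lt(rA, -rhoThresh) & gt(-d, diffThresh) & sigA,
    flag_f = lt(rC, -rhoThresh) & gt(d, diffThresh) & sigC,
    row.names = NULL
  )
}

#' Maximal cliques of an undirected graph given as an edge list
#'
#' Enumerates all maximal cliques of size at least `minSize`
#' (Bron-Kerbosch with pivoting, via igraph).
#'
#' @param edges two-column `data.frame` (or matrix) of vertex name pairs.
#' @param minSize minimum clique size to report.
#' @return list of character vectors (sorted members), largest cliques
#'   first; ties ordered lexicographically.
#' @export
maximalCliques <- function(edges, minSize = 1L) {
  edges <- as.data.frame(edges)[, 1:2]
  if (!nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = minSize)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  key <- vapply(cl, paste, character(1), collapse = "|")
  cl[order(-lengths(cl), key)]
}

#' Find co-expression cliques in a thresholded correlation graph
#'
#' Builds the graph whose edges are the pairs flagged for the requested
#' context — `"both"` (flag a: correlated in both groups), `"AD"` (flag b:
#' high in AD, much lower in controls) or `"control"` (flag c) — and reports
#' all maximal cliques of at least `minSize` loci.
#'
#' @param pairs output of [categorizePairs()].
#' @param context `"both"`, `"AD"` or `"control"`.
#' @param minSize minimum clique size (default 4).
#' @return list of `list(members, context, size)`, largest first.
#' @export
findCliques <- function(pairs, context = c("both", "AD", "control"),
                        minSize = 4L) {
  context <- match.arg(context)
  flag <- switch(context, both = "flag_a", AD = "flag_b",
                 control = "flag_c")
  sel <- pairs[pairs[[flag]] %in% TRUE, c("locus_i", "locus_j")]
  cl <- maximalCliques(sel, minSize = minSize)
  lapply(cl, function(v)
    list(members = v, context = context, size = length(v)))
}
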
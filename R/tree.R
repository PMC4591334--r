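#' Fit a C4.5-style gain-ratio decision tree
#'
#' Greedy binary tree over numeric features: at each node every feature's
#' candidate thresholds (midpoints between consecutive distinct sorted
#' values) are scored by the information gain ratio (gain divided by the
#' split entropy), the best admissible split is taken, and growth stops at
#' class purity, the minimum leaf size, or when no split has positive gain.
#' Ties between splits are broken by feature name and then by the lower
#' threshold, so the fitted tree does not depend on feature column order.
#' Pruning is off: with the small, pre-screened feature sets this tree is
#' used on, the cross-validated wrapper does the complexity control.
#'
#' @param x numeric matrix, samples in rows, named feature columns.
#' @param y class labels (factor or character).
#' @param minLeaf minimum number of samples in each child (default 2).
#' @param maxDepth optional depth limit.
#' @return object of class `j48tree` with `predict` and `print` methods.
#' @export
fitTree <- function(x, y, minLeaf = 2L, maxDepth = Inf) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  root <- .growNode(x, y, levels(y), minLeaf, maxDepth, depth = 0L)
  structure(list(root = root, classes = levels(y),
                 features = colnames(x), minLeaf = minLeaf),
            class = "j48tree")
}

.leaf <- function(y, classes) {
  counts <- table(factor(y, levels = classes))
  cls <- classes[which.max(counts)]  # ties: first class level
  list(type = "leaf", class = cls,
       prob = setNames(as.numeric(counts) / sum(counts), classes))
}

.growNode <- function(x, y, classes, minLeaf, maxDepth, depth) {
  n <- nrow(x)
  if (length(unique(y)) == 1L || n < 2L * minLeaf || depth >= maxDepth)
    return(.leaf(y, classes))
  H <- .entropy(table(y))
  best <- NULL
  for (f in colnames(x)[order(colnames(x))]) {
    v <- x[, f]
    o <- order(v)
    vs <- v[o]
    pos <- cumsum(y[o] == classes[1])
    i <- seq_len(n - 1L)
    ok <- vs[i] < vs[i + 1L] & i >= minLeaf & (n - i) >= minLeaf
    if (!any(ok)) next
    i <- i[ok]
    hl <- .binEntropy(pos[i], i)
    hr <- .binEntropy(sum(y == classes[1]) - pos[i], n - i)
    gain <- H - (i / n) * hl - ((n - i) / n) * hr
    splitInfo <- .binEntropy(i, n)
    gr <- gain / splitInfo
    gr[gain <= 1e-12] <- -Inf
    k <- which.max(gr)  # ties: lowest threshold (i ascending)
    if (is.finite(gr[k]) &&
        (is.null(best) || gr[k] > best$gr + 1e-12)) {
      best <- list(gr = gr[k], feature = f,
                   threshold = (vs[i[k]] + vs[i[k] + 1L]) / 2)
    }
  }
  if (is.null(best)) return(.leaf(y, classes))
  left <- x[, best$feature] <= best$threshold
  list(type = "node", feature = best$feature, threshold = best$threshold,
       left = .growNode(x[left, , drop = FALSE], y[left], classes,
                        minLeaf, maxDepth, depth + 1L),
       right = .growNode(x[!left, , drop = FALSE], y[!left], classes,
                         minLeaf, maxDepth, depth + 1L))
}

#' @rdname fitTree
#' @param object a fitted `j48tree`.
#' @param newdata matrix of samples to classify.
#' @param type `"class"` for labels, `"prob"` for the positive-leaning class
#'   probability matrix.
#' @param ... ignored.
#' @export
predict.j48tree <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  walk <- function(node, row) {
    while (node$type == "node")
      node <- if (row[[node$feature]] <= node$threshold) node$left
              else node$right
    node
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i)
    walk(object$root, newdata[i, ]))
  if (type == "class")
    vapply(leaves, `[[`, character(1), "class")
  else
    t(vapply(leaves, `[[`, numeric(length(object$classes)), "prob"))
}

#' Features used at the internal nodes of a tree
#'
#' A feature is counted once per node, so it may be counted several times in
#' one tree.
#'
#' @param tree a `j48tree`.
#' @return character vector of node feature names (with multiplicity).
#' @export
treeNodeFeatures <- function(tree) {
  rec <- function(node) {
    if (node$type == "leaf") return(character())
    c(node$feature, rec(node$left), rec(node$right))
  }
  rec(tree$root)
}

#' @export
print.j48tree <- function(x, ...) {
  nNodes <- length(treeNodeFeatures(x))
  cat("gain-ratio decision tree:", nNodes, "internal node(s), classes:",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}
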
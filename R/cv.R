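#' Repeated stratified cross-validation plan
#'
#' Randomly partitions the samples into `folds` folds of fixed class
#' composition, `repeats` times independently. With 35 samples per class and
#' 7 folds every fold holds out 5 positives and 5 negatives, and 10 repeats
#' give 70 train/test runs. Each class count must be divisible by `folds`.
#'
#' @param labels class labels (two classes).
#' @param folds folds per repeat (default 7).
#' @param repeats independent repartitions (default 10).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param perClassPerFold optional check: expected held-out samples per
#'   class per fold.
#' @return object of class `cvPlan`: list with `assignments` (samples x
#'   repeats matrix of fold ids), `folds`, `repeats`, `labels`, `seed`.
#' @export
makeCVPlan <- function(labels, folds = 7L, repeats = 10L, seed = 1L,
                       perClassPerFold = NULL) {
  y <- factor(labels)
  counts <- table(y)
  if (any(counts %% folds != 0))
    stop("class sizes (", paste(counts, collapse = ", "), ") are not ",
         "divisible by ", folds, " folds; choose a fold count that divides ",
         "both class sizes or drop samples to balance")
  per <- counts / folds
  if (!is.null(perClassPerFold) && any(per != perClassPerFold))
    stop("plan would hold out ", paste(per, collapse = "/"),
         " per class per fold, not ", perClassPerFold)
  set.seed(as.integer(seed))
  n <- length(y)
  assignments <- matrix(0L, nrow = n, ncol = repeats)
  for (r in seq_len(repeats)) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      assignments[idx, r] <- sample(rep(seq_len(folds),
                                        length.out = length(idx)))
    }
  }
  structure(list(assignments = assignments, folds = as.integer(folds),
                 repeats = as.integer(repeats), labels = y,
                 seed = as.integer(seed)),
            class = "cvPlan")
}

#' @export
print.cvPlan <- function(x, ...) {
  cat("cvPlan:", x$folds, "folds x", x$repeats, "repeats =",
      x$folds * x$repeats, "train/test runs on", length(x$labels),
      "samples (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Model specifications for cross-validation
#'
#' Lightweight fit/score closures handed to [crossValidate()] and
#' [stepwiseSelect()]: the boosted stump ensemble ([fitAdaboostM1()]), the
#' gain-ratio decision tree ([fitTree()]; score = positive-class leaf
#' probability) and the soft-margin linear classifier ([fitLinearMargin()]).
#'
#' @param rounds boosting rounds.
#' @param positive positive class label.
#' @return a list with elements `name`, `fit(x, y)` and `score(model, x)`
#'   (scores in `[0, 1]`, 0.5 = decision boundary).
#' @export
modelAdaboost <- function(rounds = 10L, positive = "AD") {
  list(name = "AdaboostM1", positive = positive,
       fit = function(x, y) fitAdaboostM1(x, y, rounds = rounds,
                                          positive = positive),
       score = function(m, x) predict(m, x, type = "score"))
}

#' @rdname modelAdaboost
#' @param minLeaf minimum samples per leaf for the tree.
#' @export
modelTree <- function(minLeaf = 2L, positive = "AD") {
  list(name = "J48", positive = positive,
       fit = function(x, y) fitTree(x, y, minLeaf = minLeaf),
       score = function(m, x) predict(m, x, type = "prob")[, positive])
}

#' @rdname modelAdaboost
#' @param C soft-margin cost.
#' @export
modelLinear <- function(C = 1, positive = "AD") {
  list(name = "SVMLinear", positive = positive,
       fit = function(x, y) fitLinearMargin(x, y, C = C,
                                            positive = positive),
       score = function(m, x) predict(m, x, type = "score"))
}

#' Cross-validate a model specification
#'
#' For every repeat and fold of the plan, trains on the remaining folds and
#' evaluates the held-out fold, returning the full per-run metric sets
#' (confusion counts, precision, recall, F1, AUC, MCC) and their means.
#'
#' @param spec a model specification ([modelAdaboost()] and friends).
#' @param x feature matrix, samples in rows (aligned with the plan).
#' @param y class labels.
#' @param plan a [makeCVPlan()] plan.
#' @return list with `runs` (one row per train/test run) and `means`
#'   (named numeric over precision, recall, f1, auc, mcc).
#' @export
crossValidate <- function(spec, x, y, plan) {
  x <- as.matrix(x)
  y <- factor(y)
  rows <- vector("list", plan$folds * plan$repeats)
  k <- 0L
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignments[, r]
    for (f in seq_len(plan$folds)) {
      te <- fold == f
      model <- spec$fit(x[!te, , drop = FALSE], y[!te])
      sc <- spec$score(model, x[te, , drop = FALSE])
      ms <- .metricSet(sc, y[te], spec$positive)
      k <- k + 1L
      rows[[k]] <- c(repeat_ = r, fold = f, ms)
    }
  }
  runs <- as.data.frame(do.call(rbind, rows))
  list(runs = runs,
       means = colMeans(runs[c("precision", "recall", "f1", "auc", "mcc")]))
}

# internal: vectorized two-sided Mann-Whitney (normal approximation, tie
# corrected, no continuity correction) for every feature column, plus the
# rank-biserial effect size used for tie-breaking.
.mwStats <- function(x, y, positive) {
  pos <- y == positive
  n1 <- sum(pos); n2 <- sum(!pos); n <- n1 + n2
  stats <- apply(x, 2L, function(v) {
    r <- rank(v)
    u <- sum(r[pos]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tieTerm <- sum(ties^3 - ties)
    s2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- if (s2 <= 0) 0 else (u - n1 * n2 / 2) / sqrt(s2)
    p <- if (s2 <= 0) 1 else 2 * pnorm(-abs(z))
    c(p = p, rb = 2 * u / (n1 * n2) - 1, u = u)
  })
  data.frame(feature = colnames(x), p = stats["p", ], rb = stats["rb", ],
             u = stats["u", ], row.names = NULL)
}

#' Select the most significant features by Mann-Whitney U
#'
#' Ranks features by the two-sided Mann-Whitney p-value of their values
#' between the two classes (normal approximation with tie correction) and
#' returns the top `k`. Ties on the p-value are broken by the absolute
#' rank-biserial effect size, then by feature ID, making the ranking
#' deterministic.
#'
#' @param x feature matrix, samples in rows.
#' @param y class labels.
#' @param k number of features to keep (default 50).
#' @param positive positive class label.
#' @return character vector of the `k` selected feature names, most
#'   significant first; the full ranking is in `attr(, "ranking")`.
#' @export
mannWhitneyTopK <- function(x, y, k = 50L, positive = "AD") {
  x <- as.matrix(x)
  if (k > ncol(x)) stop("k exceeds the number of features")
  st <- .mwStats(x, y, positive)
  ord <- order(st$p, -abs(st$rb), st$feature)
  st <- st[ord, , drop = FALSE]
  out <- head(st$feature, k)
  attr(out, "ranking") <- st
  out
}

#' Rank features by decision-tree node usage across cross-validation
#'
#' Trains one gain-ratio tree per train split of the plan (70 trees for the
#' default 7-fold x 10-repeat plan) and counts how many internal nodes each
#' feature occupies in total; a feature used at several nodes of one tree is
#' counted once per node. Features never chosen score 0. The count ranks the
#' discrimination importance of each feature.
#'
#' @param x feature matrix, samples in rows.
#' @param y class labels.
#' @param plan a [makeCVPlan()] plan.
#' @param minLeaf tree leaf-size parameter.
#' @return `data.frame(feature, count)` sorted by descending count (ties by
#'   feature ID).
#' @export
rankByTreeUsage <- function(x, y, plan, minLeaf = 2L) {
  x <- as.matrix(x)
  y <- factor(y)
  counts <- setNames(integer(ncol(x)), colnames(x))
  for (r in seq_len(plan$repeats)) {
    fold <- plan$assignments[, r]
    for (f in seq_len(plan$folds)) {
      tr <- fold != f
      tree <- fitTree(x[tr, , drop = FALSE], y[tr], minLeaf = minLeaf)
      used <- table(treeNodeFeatures(tree))
      counts[names(used)] <- counts[names(used)] + as.integer(used)
    }
  }
  out <- data.frame(feature = names(counts), count = as.integer(counts),
                    row.names = NULL)
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: cross-validated (auc, mcc) criterion for a feature subset
.cvCriterion <- function(spec, x, y, plan, feats) {
  cv <- crossValidate(spec, x[, feats, drop = FALSE], y, plan)
  cv$means[c("auc", "mcc")]
}

# internal: is criterion a better than b? AUC first, ties broken by MCC.
# With criterion "auc_or_mcc" an improvement in either measure counts.
.betterCriterion <- function(a, b, criterion, tol = 1e-9) {
  if (criterion == "auc_or_mcc")
    return(a[["auc"]] > b[["auc"]] + tol || a[["mcc"]] > b[["mcc"]] + tol)
  a[["auc"]] > b[["auc"]] + tol ||
    (abs(a[["auc"]] - b[["auc"]]) <= tol && a[["mcc"]] > b[["mcc"]] + tol)
}

#' Greedy wrapper feature selection by cross-validated performance
#'
#' Forward selection starts from the empty model and repeatedly adds the
#' candidate whose inclusion most improves the cross-validated criterion;
#' backward selection starts from all candidates and repeatedly removes the
#' feature whose removal most improves it. Selection stops when no step
#' improves. The criterion is the mean cross-validated AUC with ties broken
#' by MCC (`"auc_then_mcc"`, default) or an improvement in either measure
#' (`"auc_or_mcc"`).
#'
#' @param x feature matrix, samples in rows.
#' @param y class labels.
#' @param candidates candidate feature names (e.g. the top 18 from
#'   [rankByTreeUsage()]).
#' @param plan a [makeCVPlan()] plan.
#' @param direction `"forward"` or `"backward"`.
#' @param spec model specification evaluated inside the wrapper
#'   (default [modelAdaboost()]).
#' @param criterion `"auc_then_mcc"` or `"auc_or_mcc"`.
#' @return list with `selected` (feature names), `score` (auc/mcc of the
#'   final set) and `trace` (every evaluated step).
#' @export
stepwiseSelect <- function(x, y, candidates, plan,
                           direction = c("forward", "backward"),
                           spec = modelAdaboost(),
                           criterion = c("auc_then_mcc", "auc_or_mcc")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (!length(candidates)) stop("empty candidate set")
  if (!all(candidates %in% colnames(x)))
    stop("candidates must be a subset of the feature columns")
  trace <- list()
  note <- function(step, action, feat, sc, accepted)
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, action = action, feature = feat,
      auc = sc[["auc"]], mcc = sc[["mcc"]], accepted = accepted)

  if (direction == "forward") {
    current <- character()
    curScore <- c(auc = -Inf, mcc = -Inf)
  } else {
    current <- candidates
    curScore <- .cvCriterion(spec, x, y, plan, current)
  }
  step <- 0L
  repeat {
    step <- step + 1L
    pool <- if (direction == "forward") setdiff(candidates, current)
            else if (length(current) > 1L) current else character()
    if (!length(pool)) break
    scores <- lapply(pool, function(f) {
      feats <- if (direction == "forward") c(current, f)
               else setdiff(current, f)
      .cvCriterion(spec, x, y, plan, feats)
    })
    bestIdx <- 1L
    for (j in seq_along(pool))
      if (.betterCriterion(scores[[j]], scores[[bestIdx]], criterion))
        bestIdx <- j
    for (j in seq_along(pool))
      note(step, if (direction == "forward") "add" else "remove",
           pool[j], scores[[j]], FALSE)
    if (.betterCriterion(scores[[bestIdx]], curScore, criterion)) {
      current <- if (direction == "forward") c(current, pool[bestIdx])
                 else setdiff(current, pool[bestIdx])
      curScore <- scores[[bestIdx]]
      trace[[length(trace)]]$accepted <- FALSE  # keep trace tidy
      note(step, if (direction == "forward") "add" else "remove",
           pool[bestIdx], curScore, TRUE)
    } else break
  }
  list(selected = current, score = curScore,
       trace = do.call(rbind, trace))
}
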
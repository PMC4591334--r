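#' Full biomarker-panel selection procedure
#'
#' Runs the complete model-building chain on a locus-level normalized
#' expression matrix: (1) bounded log3 fold-change features
#' ([log3FoldFeatures()]); (2) Mann-Whitney pre-filter to the `topK` most
#' significant loci; (3) decision-tree node-usage ranking across the
#' cross-validation runs, keeping the top `treeRankTop`; (4) greedy wrapper
#' selection ([stepwiseSelect()]) with the boosted stump ensemble; (5) the
#' final AdaBoost.M1 model trained on all samples with the selected panel,
#' reported with its cross-validated metric means.
#'
#' By default the grand means, the Mann-Whitney filter and the tree ranking
#' are computed on the full dataset before cross-validation — the protocol
#' of typical discovery studies, which leaks selection information into the
#' CV estimates. `foldSafe = TRUE` instead nests the entire chain inside
#' each cross-validation fold (grand means, filter, ranking and wrapper are
#' recomputed from the training folds only, with an inner plan) and reports
#' honest held-out metrics plus per-fold selections.
#'
#' @param x locus-level `MirCountSet` of normalized expression, or a numeric
#'   matrix (loci in rows) plus `groups`.
#' @param groups class labels per sample (taken from `colData(x)$group` when
#'   `x` is a `MirCountSet`).
#' @param positive positive class label (default `"AD"`).
#' @param topK Mann-Whitney pre-filter size (default 50).
#' @param treeRankTop features kept after tree-usage ranking (default 18).
#' @param folds,repeats cross-validation geometry (defaults 7 x 10).
#' @param rounds boosting rounds of the wrapped/final ensemble.
#' @param direction wrapper direction, `"forward"` or `"backward"`.
#' @param criterion wrapper acceptance rule, see [stepwiseSelect()].
#' @param foldSafe nest all selection inside CV folds (honest mode).
#' @param innerRepeats repeats of the inner plan in fold-safe mode.
#' @param seed master seed for the partitioning.
#' @return object of class `biomarkerPanel`: list with `selected`,
#'   `metrics` (cross-validated means), `runs`, `finalModel`, `ranking`,
#'   `preFilter`, `grandMeans`, `plan`, `trace`, `foldSafe` and, in
#'   fold-safe mode, `foldSelections`.
#' @export
selectBiomarkerPanel <- function(x, groups = NULL, positive = "AD",
                                 topK = 50L, treeRankTop = 18L,
                                 folds = 7L, repeats = 10L, rounds = 10L,
                                 direction = "forward",
                                 criterion = "auc_then_mcc",
                                 foldSafe = FALSE, innerRepeats = 1L,
                                 seed = 1L) {
  if (is(x, "MirCountSet")) {
    if (is.null(groups)) groups <- as.character(sampleGroups(x))
    m <- assay(x, "counts")
  } else m <- as.matrix(x)
  y <- factor(groups)
  topK <- min(topK, nrow(m))
  spec <- modelAdaboost(rounds = rounds, positive = positive)
  plan <- makeCVPlan(y, folds = folds, repeats = repeats, seed = seed)

  if (!foldSafe) {
    gm <- grandMeans(m)
    X <- t(log3FoldFeatures(m, grand = gm))
    pre <- mannWhitneyTopK(X, y, k = topK, positive = positive)
    ranking <- rankByTreeUsage(X[, pre, drop = FALSE], y, plan)
    cand <- head(ranking$feature[ranking$count > 0], treeRankTop)
    sel <- stepwiseSelect(X, y, cand, plan, direction = direction,
                          spec = spec, criterion = criterion)
    cv <- crossValidate(spec, X[, sel$selected, drop = FALSE], y, plan)
    final <- fitAdaboostM1(X[, sel$selected, drop = FALSE], y,
                           rounds = rounds, positive = positive)
    out <- list(selected = sel$selected, metrics = cv$means,
                runs = cv$runs, finalModel = final, ranking = ranking,
                preFilter = as.character(pre), grandMeans = gm,
                plan = plan, trace = sel$trace, foldSafe = FALSE,
                positive = positive)
  } else {
    rows <- list(); sels <- list()
    k <- 0L
    for (r in seq_len(plan$repeats)) {
      fold <- plan$assignments[, r]
      for (f in seq_len(plan$folds)) {
        te <- fold == f
        mTr <- m[, !te, drop = FALSE]
        gmTr <- grandMeans(mTr)
        XTr <- t(log3FoldFeatures(mTr, grand = gmTr))
        XTe <- t(log3FoldFeatures(m[, te, drop = FALSE], grand = gmTr))
        yTr <- y[!te]
        innerFolds <- max(2L, folds - 1L)
        innerPlan <- makeCVPlan(yTr, folds = innerFolds,
                                repeats = innerRepeats,
                                seed = seed + 1000L + k)
        pre <- mannWhitneyTopK(XTr, yTr, k = min(topK, ncol(XTr)),
                               positive = positive)
        ranking <- rankByTreeUsage(XTr[, pre, drop = FALSE], yTr, innerPlan)
        cand <- head(ranking$feature[ranking$count > 0], treeRankTop)
        if (!length(cand)) cand <- head(ranking$feature, 1L)
        sel <- stepwiseSelect(XTr, yTr, cand, innerPlan,
                              direction = direction, spec = spec,
                              criterion = criterion)
        feats <- if (length(sel$selected)) sel$selected
                 else head(cand, 1L)
        model <- spec$fit(XTr[, feats, drop = FALSE], yTr)
        sc <- spec$score(model, XTe[, feats, drop = FALSE])
        k <- k + 1L
        rows[[k]] <- c(repeat_ = r, fold = f,
                       .metricSet(sc, y[te], positive))
        sels[[k]] <- feats
      }
    }
    runs <- as.data.frame(do.call(rbind, rows))
    out <- list(selected = sort(unique(unlist(sels))),
                metrics = colMeans(runs[c("precision", "recall", "f1",
                                          "auc", "mcc")]),
                runs = runs, foldSelections = sels, plan = plan,
                foldSafe = TRUE, positive = positive)
  }
  class(out) <- "biomarkerPanel"
  out
}

#' @export
print.biomarkerPanel <- function(x, ...) {
  cat("biomarkerPanel (", if (x$foldSafe) "fold-safe" else "full-data",
      " selection)\n", sep = "")
  cat("selected loci:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("CV means: AUC %.3f, MCC %.3f, F1 %.3f, precision %.3f, recall %.3f\n",
              x$metrics[["auc"]], x$metrics[["mcc"]], x$metrics[["f1"]],
              x$metrics[["precision"]], x$metrics[["recall"]]))
  invisible(x)
}
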
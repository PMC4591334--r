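# Weighted decision stump (depth-1 threshold rule) — the weak learner of the
# boosted ensemble. Candidates are the constant classifiers plus, per
# feature, every midpoint between consecutive distinct values, in both
# polarities. Deterministic tie-breaks: first lower weighted error, then
# constants before splits, feature name, lower threshold, "left positive"
# polarity — so fits do not depend on feature column order.
.fitStump <- function(x, ypm, w, orders = NULL) {
  w <- w / sum(w)
  wPos <- sum(w[ypm > 0])
  # constant rules: threshold -Inf puts every sample in the right child
  best <- list(err = 1 - wPos, feature = NA_character_, threshold = -Inf,
               leftSign = 1, rightSign = 1)
  if (wPos < best$err - 1e-12)
    best <- list(err = wPos, feature = NA_character_, threshold = -Inf,
                 leftSign = -1, rightSign = -1)
  for (f in colnames(x)[order(colnames(x))]) {
    o <- if (is.null(orders)) order(x[, f]) else orders[[f]]
    vs <- x[o, f]
    cw <- cumsum(w[o])
    cwy <- cumsum((w * ypm)[o])
    i <- which(vs[-length(vs)] < vs[-1L])
    if (!length(i)) next
    cumWposI <- (cw[i] + cwy[i]) / 2
    cumWnegI <- (cw[i] - cwy[i]) / 2
    errA <- cumWnegI + (wPos - cumWposI)  # left -> +1, right -> -1
    errB <- 1 - errA
    for (pol in 1:2) {
      e <- if (pol == 1L) errA else errB
      k <- which.min(e)
      if (e[k] < best$err - 1e-12) {
        best <- list(err = e[k], feature = f,
                     threshold = (vs[i[k]] + vs[i[k] + 1L]) / 2,
                     leftSign = if (pol == 1L) 1 else -1,
                     rightSign = if (pol == 1L) -1 else 1)
      }
    }
  }
  best
}

.predictStump <- function(stump, x) {
  if (is.na(stump$feature))
    return(rep(stump$rightSign, nrow(x)))
  ifelse(x[, stump$feature] <= stump$threshold, stump$leftSign,
         stump$rightSign)
}

#' Fit an AdaBoost.M1 ensemble of decision stumps
#'
#' Classical AdaBoost.M1: each round fits a depth-1 threshold stump
#' minimizing the weighted training error `eps_t`, receives the vote weight
#' `alpha_t = ln((1 - eps_t)/eps_t)`, and the weights of correctly
#' classified samples are multiplied by `eps_t/(1 - eps_t)` and
#' renormalized. Boosting stops early when a round reaches `eps_t = 0`
#' (perfect weak learner, kept) or `eps_t >= 0.5` (no better than chance,
#' dropped). The prediction confidence is the normalized ensemble margin
#' `(sum(alpha_t h_t) + sum(alpha_t)) / (2 sum(alpha_t))`, mapped to
#' `[0, 1]` with 0.5 the decision boundary.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y class labels; exactly two classes must be present.
#' @param rounds maximum boosting rounds (default 10).
#' @param positive label of the positive class (default `"AD"`).
#' @return object of class `adaboostM1` with `stumps`, `alphas`, `epsilons`
#'   and a `predict` method.
#' @export
fitAdaboostM1 <- function(x, y, rounds = 10L, positive = "AD") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("AdaBoost.M1 needs exactly two classes in the training data")
  if (!positive %in% levels(y)) stop("positive class not among labels")
  negative <- setdiff(levels(droplevels(y)), positive)
  ypm <- ifelse(as.character(y) == positive, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  orders <- lapply(setNames(colnames(x), colnames(x)),
                   function(f) order(x[, f]))
  stumps <- list(); alphas <- numeric(); epsilons <- numeric()
  for (t in seq_len(rounds)) {
    st <- .fitStump(x, ypm, w, orders)
    pred <- .predictStump(st, x)
    eps <- sum(w[pred != ypm])
    if (eps >= 0.5) break
    epsClamped <- max(eps, 1e-10)
    beta <- epsClamped / (1 - epsClamped)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, log(1 / beta))
    epsilons <- c(epsilons, eps)
    if (eps <= 0) break
    w[pred == ypm] <- w[pred == ypm] * beta
    w <- w / sum(w)
  }
  majority <- if (sum(ypm > 0) >= sum(ypm < 0)) positive else negative
  structure(list(stumps = stumps, alphas = alphas, epsilons = epsilons,
                 positive = positive, negative = negative,
                 majority = majority, rounds = rounds),
            class = "adaboostM1")
}

#' @rdname fitAdaboostM1
#' @param object a fitted `adaboostM1`.
#' @param newdata feature matrix to score.
#' @param type `"score"` for confidences in `[0, 1]`, `"class"` for labels.
#' @param ... ignored.
#' @export
predict.adaboostM1 <- function(object, newdata,
                               type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  A <- sum(object$alphas)
  if (A == 0) {
    score <- rep(0.5, nrow(newdata))
  } else {
    S <- rowSums(vapply(seq_along(object$stumps), function(t)
      object$alphas[t] * .predictStump(object$stumps[[t]], newdata),
      numeric(nrow(newdata))))
    score <- (S + A) / (2 * A)
  }
  if (type == "score") return(score)
  ifelse(score >= 0.5, object$positive, object$negative)
}

#' @export
print.adaboostM1 <- function(x, ...) {
  cat("AdaBoost.M1 stump ensemble:", length(x$stumps), "round(s); features:",
      paste(unique(stats::na.omit(vapply(x$stumps, `[[`, character(1),
                                         "feature"))), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a soft-margin linear classifier
#'
#' Thin wrapper around a linear-kernel support vector machine
#' (\pkg{e1071}/libsvm) exposing the primal weight vector and bias; the
#' decision value is used as the ranking score for AUC, mapped through the
#' logistic function so confidences lie in `[0, 1]` with 0.5 at the margin.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y class labels (two classes).
#' @param C soft-margin cost parameter.
#' @param positive label of the positive class.
#' @return object of class `linearMargin` with elements `w`, `b`,
#'   `supportIndex`.
#' @export
fitLinearMargin <- function(x, y, C = 1, positive = "AD") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("two classes required")
  fit <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- setNames(as.vector(t(fit$coefs) %*% fit$SV), colnames(x))
  b <- -fit$rho
  # libsvm orients the decision value toward the class named first in the
  # decision-values column ("A/B": positive value means A)
  dv <- predict(fit, x, decision.values = TRUE)
  first <- strsplit(colnames(attr(dv, "decision.values"))[1], "/")[[1]][1]
  if (first != positive) { w <- -w; b <- -b }
  structure(list(w = w, b = b, supportIndex = sort(fit$index), C = C,
                 positive = positive,
                 negative = setdiff(levels(y), positive)),
            class = "linearMargin")
}

#' @rdname fitLinearMargin
#' @param object a fitted `linearMargin`.
#' @param newdata feature matrix to score.
#' @param type `"score"` (logistic of the decision value), `"decision"`
#'   (raw affine decision value) or `"class"`.
#' @param ... ignored.
#' @export
predict.linearMargin <- function(object, newdata,
                                 type = c("score", "decision", "class"),
                                 ...) {
  type <- match.arg(type)
  dv <- drop(as.matrix(newdata)[, names(object$w), drop = FALSE] %*%
               object$w) + object$b
  switch(type,
         decision = dv,
         score = stats::plogis(dv),
         class = ifelse(dv >= 0, object$positive, object$negative))
}
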
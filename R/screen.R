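#' Battery of two-group location tests for one locus
#'
#' Computes the five p-values used for differential-expression screening:
#' Kruskal-Wallis (rank sums with tie correction, chi-squared approximation
#' with 1 df for two groups), Welch's two-tailed t (unequal variances),
#' Mann-Whitney/Wilcoxon (two-sided normal approximation with tie correction,
#' no continuity correction), one-way ANOVA, and ANOVA blocked by preparation
#' batch (two-way fixed effects, F-test on the group term). With two groups
#' the Kruskal-Wallis and Mann-Whitney p-values coincide on tie-corrected
#' rank statistics.
#'
#' Values constant across all samples give p = 1 for every test by
#' definition. Degenerate cases where a single test cannot be computed (e.g.
#' zero variance within each group for the t-test) yield `NA` for that test.
#'
#' @param values numeric per-sample expression vector.
#' @param labels group labels (two classes, >= 2 samples each).
#' @param batch optional batch factor; required for the blocked ANOVA
#'   (otherwise `p_anova_blocked` is `NA`).
#' @param groups the two class labels, case group first.
#' @return named numeric: `p_kw`, `p_t`, `p_mw`, `p_anova`,
#'   `p_anova_blocked`.
#' @export
twoGroupTests <- function(values, labels, batch = NULL,
                          groups = c("AD", "control")) {
  labels <- as.character(labels)
  if (!all(labels %in% groups))
    stop("unknown group labels: ",
         paste(setdiff(labels, groups), collapse = ", "))
  a <- values[labels == groups[1]]
  b <- values[labels == groups[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  out <- c(p_kw = NA_real_, p_t = NA_real_, p_mw = NA_real_,
           p_anova = NA_real_, p_anova_blocked = NA_real_)
  if (all(values == values[1])) {
    out[] <- 1
    if (is.null(batch)) out["p_anova_blocked"] <- NA_real_
    return(out)
  }
  g <- factor(labels, levels = groups)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out["p_kw"] <- safe(kruskal.test(values, g)$p.value)
  out["p_t"] <- safe(t.test(a, b, var.equal = FALSE)$p.value)
  out["p_mw"] <- safe(wilcox.test(a, b, exact = FALSE,
                                  correct = FALSE)$p.value)
  out["p_anova"] <- safe(anova(lm(values ~ g))[["Pr(>F)"]][1])
  if (!is.null(batch)) {
    bf <- factor(batch)
    out["p_anova_blocked"] <- if (nlevels(bf) < 2L) out[["p_anova"]] else
      safe({
        tab <- anova(lm(values ~ bf + g))
        tab[["Pr(>F)"]][rownames(tab) == "g"]
      })
  }
  out
}

#' Screen every locus for a group difference
#'
#' Produces the screening report: per locus the group arithmetic means of the
#' normalized expression, the case/control ratio of those means, the five
#' test p-values from [twoGroupTests()], and a significance flag defined by
#' the Kruskal-Wallis p-value at level `alpha`. Rows are sorted by ascending
#' `p_kw` (NA last).
#'
#' Loci expressed in neither group have an undefined (0/0) ratio, reported as
#' `NA` and never flagged; loci with zero variance overall get p = 1.
#' Multiple-testing correction is deliberately not applied at this screening
#' stage (downstream biological and statistical criteria do the weeding);
#' Benjamini-Hochberg q-values are available as an optional extra column.
#'
#' @param x a locus-level `MirCountSet` of normalized expression.
#' @param alpha significance level for the flag (default 0.05).
#' @param groups the two class labels, case group first.
#' @param qvalues add a `q_kw` Benjamini-Hochberg column (default off).
#' @return `data.frame` with columns `locus`, `mean_AD`, `mean_control`,
#'   `ratio`, `p_kw`, `p_t`, `p_mw`, `p_anova`, `p_anova_blocked`,
#'   `significant` (and optionally `q_kw`).
#' @export
screenAll <- function(x, alpha = 0.05, groups = c("AD", "control"),
                      qvalues = FALSE) {
  stopifnot(is(x, "MirCountSet"))
  if (exprLevel(x) != "locus")
    stop("screenAll expects a locus-level matrix; run sumByLocus() first")
  g <- as.character(sampleGroups(x))
  if (!setequal(unique(g), groups))
    stop("unknown group labels: expected ", paste(groups, collapse = "/"))
  batch <- if ("prep_batch" %in% colnames(colData(x)))
    colData(x)$prep_batch else NULL
  m <- assay(x, "counts")
  ca <- g == groups[1]
  cb <- g == groups[2]
  meanA <- rowMeans(m[, ca, drop = FALSE])
  meanB <- rowMeans(m[, cb, drop = FALSE])
  ratio <- ifelse(meanA == 0 & meanB == 0, NA_real_, meanA / meanB)
  ps <- t(apply(m, 1L, twoGroupTests, labels = g, batch = batch,
                groups = groups))
  res <- data.frame(locus = rownames(m), mean_AD = meanA,
                    mean_control = meanB, ratio = ratio,
                    ps, row.names = NULL, check.names = FALSE)
  names(res)[2:3] <- paste0("mean_", groups)
  res$significant <- !is.na(res$p_kw) & res$p_kw < alpha & !is.na(res$ratio)
  if (qvalues) res$q_kw <- stats::p.adjust(res$p_kw, method = "BH")
  res[order(res$p_kw, res$locus, na.last = TRUE), , drop = FALSE]
}
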
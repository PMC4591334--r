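test_that("the CV plan partitions samples with fixed class balance", {
  y <- rep(c("AD", "control"), each = 35)
  plan <- makeCVPlan(y, folds = 7, repeats = 10, seed = 3,
                     perClassPerFold = 5)
  expect_equal(dim(plan$assignments), c(70L, 10L))
  for (r in 1:10) {
    fold <- plan$assignments[, r]
    expect_setequal(unique(fold), 1:7)
    for (f in 1:7) {
      held <- fold == f
      expect_equal(sum(held), 10L)                 # 10 samples per fold
      expect_equal(sum(held & y == "AD"), 5L)      # 5 positives each
    }
    # every sample held out exactly once per repeat
    expect_equal(tabulate(fold, 7), rep(10L, 7))
  }
  # 70 train/test runs in total
  expect_equal(plan$folds * plan$repeats, 70L)
})

test_that("CV plans are seed-deterministic and reject indivisible classes", {
  y <- rep(c("AD", "control"), each = 35)
  p1 <- makeCVPlan(y, seed = 5)
  p2 <- makeCVPlan(y, seed = 5)
  p3 <- makeCVPlan(y, seed = 6)
  expect_identical(p1$assignments, p2$assignments)
  expect_false(identical(p1$assignments, p3$assignments))
  expect_error(makeCVPlan(rep(c("AD", "control"), each = 33), folds = 7),
               "divisible")
  expect_error(makeCVPlan(y, folds = 7, perClassPerFold = 4), "not")
})

test_that("Mann-Whitney ranking puts a separating feature first", {
  set.seed(40)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, sprintf("n%02d", 1:10)))
  colnames(x)[4] <- "signal"
  y <- rep(c("AD", "control"), each = 10)
  x[, "signal"] <- ifelse(y == "AD", 1, -1) + rnorm(20, sd = 0.05)
  top <- mannWhitneyTopK(x, y, k = 3)
  expect_equal(top[1], "signal")
  expect_setequal(mannWhitneyTopK(x, y, k = 10), colnames(x))
  expect_error(mannWhitneyTopK(x, y, k = 11), "exceeds")
})

test_that("the feature ordering matches the exact U distribution on a toy", {
  # 4 + 4 samples, tie-free: order features by exact enumeration p first,
  # then check the approximate ranking agrees
  set.seed(41)
  y <- rep(c("AD", "control"), each = 4)
  x <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
  x[, 2] <- c(5, 6, 7, 8, 1, 2, 3, 4)       # perfect separation
  x[, 4] <- c(5, 1, 6, 2, 7, 3, 8, 4) / 10  # interleaved
  exactP <- vapply(colnames(x), function(f)
    exactMWPValue(x[y == "AD", f], x[y != "AD", f]), numeric(1))
  got <- mannWhitneyTopK(x, y, k = 5)
  expect_equal(got[1], names(which.min(exactP)))
  expect_equal(got[5], names(which.max(exactP)))
})

test_that("boosting drives training error to zero on separable data", {
  x <- matrix(c(1, 2, 3, 7, 8, 9), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c("control", "AD"), each = 3)
  fit <- fitAdaboostM1(x, y, rounds = 10)
  expect_length(fit$stumps, 1)          # one perfect stump, early stop
  expect_equal(fit$epsilons, 0)
  expect_equal(predict(fit, x, type = "class"), y)
  sc <- predict(fit, x, type = "score")
  expect_true(all(sc[y == "AD"] > 0.5) && all(sc[y == "control"] < 0.5))
  expect_error(fitAdaboostM1(x, rep("AD", 6)), "two classes")
})

test_that("a six-point run reproduces hand-computed weights and votes", {
  # x = 1..6, y = +,+,+,-,-,+ (positive = AD). Round 1: best stump is
  # x <= 3.5 -> AD (misses only x=6), eps1 = 1/6, alpha1 = ln 5; weights
  # renormalize to 1/10 (correct) and 1/2 (missed). Round 2: best stump is
  # the constant AD rule (errs on x=4,5: eps2 = 2/10), alpha2 = ln 4.
  x <- matrix(1:6, ncol = 1, dimnames = list(NULL, "f"))
  y <- c("AD", "AD", "AD", "control", "control", "AD")
  fit <- fitAdaboostM1(x, y, rounds = 2)
  expect_equal(fit$epsilons, c(1 / 6, 1 / 5), tolerance = 1e-12)
  expect_equal(fit$alphas, c(log(5), log(4)), tolerance = 1e-12)
  expect_equal(fit$stumps[[1]]$threshold, 3.5)
  expect_true(is.na(fit$stumps[[2]]$feature))  # constant rule
  # after two rounds the vote ln5 (stump) beats ln4 (constant) on x = 6
  pred <- predict(fit, x, type = "class")
  expect_equal(pred, c("AD", "AD", "AD", "control", "control", "control"))
})

test_that("predictions are invariant under duplicating every sample", {
  set.seed(44)
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- sample(c("AD", "control"), 15, replace = TRUE, prob = c(0.6, 0.4))
  f1 <- fitAdaboostM1(x, y, rounds = 5)
  f2 <- fitAdaboostM1(rbind(x, x), c(y, y), rounds = 5)
  expect_equal(predict(f1, x, type = "score"),
               predict(f2, x, type = "score"))
})

test_that("the linear margin classifier is oriented and scale-consistent", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c("control", "AD"), each = 3)
  fit <- fitLinearMargin(x, y, C = 10)
  expect_gt(unname(fit$w["f"]), 0)  # higher f means AD
  expect_equal(predict(fit, x, type = "class"), y)
  # doubling the features halves the weight at rescaled cost,
  # with identical decision values
  fit2 <- fitLinearMargin(x * 2, y, C = 5)
  expect_equal(unname(fit2$w), unname(fit$w) / 2, tolerance = 1e-6)
  expect_equal(predict(fit2, x * 2, type = "decision"),
               predict(fit, x, type = "decision"), tolerance = 1e-6)
})

test_that("the support set matches a brute-force dual QP on four points", {
  x <- rbind(c(0, 0), c(0.4, 0), c(2, 0), c(2.4, 0.4))
  colnames(x) <- c("u", "v")
  y <- c("control", "control", "AD", "AD")
  C <- 10
  fit <- fitLinearMargin(x, y, C = C)
  # dual: maximize sum(a) - 0.5 sum_ij a_i a_j y_i y_j <x_i, x_j>
  # subject to 0 <= a <= C, sum(a_i y_i) = 0; grid over a1, a2, a3
  ypm <- ifelse(y == "AD", 1, -1)
  K <- x %*% t(x)
  grid <- seq(0, C, length.out = 41)
  best <- c(-Inf, 0, 0, 0, 0)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    a4 <- a1 + a2 - a3  # from the equality constraint
    if (a4 < 0 || a4 > C) next
    a <- c(a1, a2, a3, a4)
    obj <- sum(a) - 0.5 * drop(t(a * ypm) %*% K %*% (a * ypm))
    if (obj > best[1]) best <- c(obj, a)
  }
  oracleSupport <- which(best[2:5] > 1e-6)
  expect_equal(fit$supportIndex, oracleSupport)
})

test_that("tree-usage ranking rewards the informative feature", {
  wins <- vapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 28
    y <- rep(c("AD", "control"), each = n / 2)
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c("signal", sprintf("n%d", 1:5))))
    x[, "signal"] <- ifelse(y == "AD", 0.9, -0.9) + rnorm(n, sd = 0.5)
    plan <- makeCVPlan(y, folds = 7, repeats = 2, seed = s)
    rk <- rankByTreeUsage(x, y, plan)
    counts <- setNames(rk$count, rk$feature)
    counts[["signal"]] >= max(counts[setdiff(names(counts), "signal")])
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("unused features score zero and counts ignore column order", {
  set.seed(46)
  n <- 20
  y <- rep(c("AD", "control"), each = 10)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("s", "n1", "n2", "n3")))
  x[, "s"] <- ifelse(y == "AD", 2, -2)
  plan <- makeCVPlan(y, folds = 5, repeats = 2, seed = 9)
  r1 <- rankByTreeUsage(x, y, plan)
  expect_true(all(r1$count[!r1$feature %in% "s"] == 0))
  r2 <- rankByTreeUsage(x[, c(3, 1, 4, 2)], y, plan)
  expect_equal(r1, r2)
})

test_that("cross-validation returns all runs and sensible extremes", {
  set.seed(47)
  n <- 28
  y <- rep(c("AD", "control"), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  x[, "a"] <- ifelse(y == "AD", 3, -3)  # perfectly separable
  plan <- makeCVPlan(y, folds = 7, repeats = 10, seed = 2)
  cv <- crossValidate(modelAdaboost(), x, y, plan)
  expect_equal(nrow(cv$runs), 70L)
  expect_equal(unname(cv$means["auc"]), 1)
  expect_equal(unname(cv$means["mcc"]), 1)
})

test_that("label-permuted data cross-validates at chance level", {
  aucs <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 20
    y <- sample(rep(c("AD", "control"), each = n / 2))
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, sprintf("f%d", 1:5)))
    plan <- makeCVPlan(y, folds = 5, repeats = 3, seed = s)
    crossValidate(modelAdaboost(), x, y, plan)$means[["auc"]]
  }, numeric(1))
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("forward selection finds the informative candidate", {
  hits <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 20
    y <- rep(c("AD", "control"), each = n / 2)
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, c("signal", sprintf("n%d", 1:9))))
    x[, "signal"] <- ifelse(y == "AD", 1, -1) + rnorm(n, sd = 0.4)
    plan <- makeCVPlan(y, folds = 5, repeats = 2, seed = s)
    sel <- stepwiseSelect(x, y, colnames(x), plan, direction = "forward")
    "signal" %in% sel$selected
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("backward selection is a fixed point when nothing helps removal", {
  set.seed(49)
  n <- 20
  y <- rep(c("AD", "control"), each = n / 2)
  # two jointly necessary features: class = sign parity of (a, b)
  a <- ifelse(y == "AD", 1, -1) * sample(c(1, 1, 1, -1), n, replace = TRUE)
  x <- cbind(a = a + rnorm(n, sd = 0.2),
             b = a * ifelse(y == "AD", 1, 1) + rnorm(n, sd = 0.2))
  plan <- makeCVPlan(y, folds = 5, repeats = 2, seed = 4)
  sel <- stepwiseSelect(x, y, c("a", "b"), plan, direction = "backward")
  expect_true(all(c("a") %in% colnames(x)))
  expect_gte(length(sel$selected), 1L)
  expect_true(all(sel$selected %in% c("a", "b")))
  expect_error(stepwiseSelect(x, y, character(), plan), "empty")
  expect_error(stepwiseSelect(x, y, "missing", plan), "subset")
})

test_that("forward and backward can converge to the same model", {
  # moderate, non-saturating signals: noise features actively hurt the
  # cross-validated criterion, so backward removal has something to do;
  # agreement between the directions is data-dependent, not guaranteed
  agree <- vapply(1:5, function(s) {
    set.seed(900 + s)
    n <- 20
    y <- rep(c("AD", "control"), each = n / 2)
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c("s1", "s2", sprintf("n%d", 1:4))))
    x[, "s1"] <- ifelse(y == "AD", 0.7, -0.7) + rnorm(n, sd = 1)
    x[, "s2"] <- ifelse(y == "AD", -0.7, 0.7) + rnorm(n, sd = 1)
    plan <- makeCVPlan(y, folds = 5, repeats = 2, seed = s)
    f <- stepwiseSelect(x, y, colnames(x), plan, direction = "forward")
    b <- stepwiseSelect(x, y, colnames(x), plan, direction = "backward")
    setequal(f$selected, b$selected)
  }, logical(1))
  expect_gte(sum(agree), 3)
})

test_that("the selection trace records every evaluated step", {
  set.seed(50)
  n <- 16
  y <- rep(c("AD", "control"), each = 8)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, "a"] <- ifelse(y == "AD", 2, -2)
  plan <- makeCVPlan(y, folds = 4, repeats = 1, seed = 1)
  sel <- stepwiseSelect(x, y, colnames(x), plan)
  expect_true(all(c("step", "action", "feature", "auc", "mcc", "accepted")
                  %in% colnames(sel$trace)))
  expect_equal(sum(sel$trace$accepted), length(sel$selected))
})
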
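test_that("linear SVM training honours the margin geometry", {
  # symmetric 1-D separable data: positive weight, bias near zero
  X <- cbind(x = c(-1.2, -1.0, -0.8, 0.8, 1.0, 1.2))
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- trainLinearSVM(X, y, C = 1)
  expect_gt(weightVector(m)[["x"]], 0)
  expect_lt(abs(m@bias), 1e-4)
  # support vectors of well-separated data sit on the unit margin
  set.seed(2)
  X2 <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  colnames(X2) <- c("a", "b")
  y2 <- rep(c(1, -1), each = 20)
  m2 <- trainLinearSVM(X2, y2, C = 100)
  sc <- decisionScores(m2, m2@supportX)
  expect_true(all(abs(abs(sc) - 1) < 1e-3))
  # duplicating the training set leaves the decision function unchanged
  m3 <- trainLinearSVM(rbind(X2, X2), c(y2, y2), C = 100)
  expect_equal(decisionScores(m3, X2), decisionScores(m2, X2),
               tolerance = 1e-5)
  expect_error(trainLinearSVM(X2, rep(1, 40)), "single class")
})

test_that("kernel-expansion scores equal explicit weight-vector scores", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  y <- sign(X[, 1] + 0.3 * rnorm(40)); y[y == 0] <- 1
  for (C in c(0.1, 1, 10)) {
    m <- trainLinearSVM(X, y, C)
    Xnew <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, letters[1:5]))
    kernel_route <- decisionScores(m, Xnew)
    weight_route <- drop(Xnew %*% weightVector(m)) + m@bias
    expect_lt(max(abs(kernel_route - weight_route)), 1e-6)
  }
  # scores are affine: score(2x) - b = 2 (score(x) - b)
  m <- trainLinearSVM(X, y, 1)
  expect_equal(decisionScores(m, 2 * X) - m@bias,
               2 * (decisionScores(m, X) - m@bias), tolerance = 1e-8)
  expect_equal(decisionScores(m, X[0, , drop = FALSE]), numeric(0))
  expect_error(decisionScores(m, X[, 1:3]), "missing")
})

test_that("auroc follows the Mann-Whitney formulation with half ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1)), 1)
  expect_equal(auroc(rep(0.5, 6), rep(c(1, -1), 3)), 0.5)
  s <- c(0.9, 0.2, 0.6, 0.4, 0.8, 0.1)
  y <- c(1, -1, 1, -1, -1, 1)
  expect_equal(auroc(-s, y), 1 - auroc(s, y))
  # invariant under strictly increasing transforms
  expect_equal(auroc(exp(3 * s), y), auroc(s, y))
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(5)
  s2 <- rnorm(60); y2 <- rep(c(1, -1), 30)
  expect_equal(auroc(s2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              direction = "<"))))
  expect_error(auroc(s2, rep(1, 60)), "both classes")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  y <- rep(c(1, -1), c(23, 37))
  f <- makeStratifiedFolds(y, 5, seed = 9)
  expect_identical(f, makeStratifiedFolds(y, 5, seed = 9))
  expect_equal(sort(unique(f)), 1:5)
  per_fold_pos <- table(f[y > 0])
  expect_lte(diff(range(per_fold_pos)), 1)
  expect_error(makeStratifiedFolds(rep(c(1, -1), c(3, 37)), 5, 1), "at least")
})

test_that("nested CV recovers planted composition effects and is deterministic", {
  ss <- makePlantedSet(60, 60, delta = 0.05, seed = 21)
  X <- assembleFeatures(ss, "f2")
  y <- unname(labels(ss))
  cv <- nestedCV(X, y, outer_folds = 5, inner_folds = 5,
                 C_grid = c(0.1, 1, 10), seed = 2, keep_weights = TRUE)
  expect_gte(cv$mean_auroc, 0.95)
  expect_equal(cv$mean_auroc, mean(cv$fold_auroc))
  # every record tested exactly once, folds stratified
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(length(cv$fold), length(y))
  # planted signs recovered in the fold weight vectors
  expect_true(all(cv$fold_weights["comp:Y", ] > 0))
  expect_true(all(cv$fold_weights["comp:K", ] < 0))
  cv2 <- nestedCV(X, y, outer_folds = 5, inner_folds = 5,
                  C_grid = c(0.1, 1, 10), seed = 2)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$fold_auroc, cv2$fold_auroc)
})

test_that("weight-vector utilities normalize, compare and correlate", {
  expect_equal(normalizeContributions(c(a = 2, b = -4)), c(a = 0.5, b = -1))
  expect_equal(normalizeContributions(c(a = -3)), c(a = -1))
  w <- c(a = 0.5, b = -1, c = 0.25)
  expect_equal(normalizeContributions(w), w)   # already normalized
  expect_error(normalizeContributions(c(a = 0, b = 0)), "all-zero")

  expect_equal(compareWeightVectors(w, w), 1)
  expect_equal(compareWeightVectors(w, -w), -1)
  expect_equal(compareWeightVectors(w, w[c("c", "a", "b")]), 1)  # name-aligned
  expect_error(compareWeightVectors(w, c(a = 1, z = 2, q = 3)), "different")

  expect_equal(correlateWeightsWithProperty(w, w)$r, 1)
  expect_equal(correlateWeightsWithProperty(w, -w)$r, -1)
  expect_error(correlateWeightsWithProperty(w, c(a = 1, b = 2)), "fewer than 3")
  # exclusion list honoured
  w4 <- c(a = 1, b = 2, c = 3, d = 4, e = -5)
  r <- correlateWeightsWithProperty(w4, w4, exclude = "e")
  expect_equal(r$n, 4)
  expect_equal(r$r, 1)
})

test_that("a model with no support vectors yields the zero weight vector", {
  m <- new("LinearSVM", supportCoefs = numeric(0),
           supportX = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("a", "b"))),
           bias = 0, cost = 1, columnNames = c("a", "b"))
  expect_equal(weightVector(m), c(a = 0, b = 0))
})

test_that("forward selection finds a dominant feature and stops when scores drop", {
  set.seed(11)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(good = 0.6 * y + rnorm(n, sd = 1),
             n1 = rnorm(n, sd = 3), n2 = rnorm(n, sd = 3),
             n3 = rnorm(n, sd = 3))
  sel <- forwardFeatureSelection(X, y, colnames(X), C = 1, folds = 5, seed = 4)
  expect_equal(sel$selected[1], "good")
  # the stop rule fired: the best remaining addition strictly lowered the
  # inner-CV score before the candidate list was exhausted
  expect_lt(length(sel$selected), 4)
  # trajectory scores never drop by construction of the stop rule
  expect_true(all(diff(sel$scores) >= 0))
  sel2 <- forwardFeatureSelection(X, y, colnames(X), C = 1, folds = 5, seed = 4)
  expect_identical(sel$selected, sel2$selected)
  expect_error(forwardFeatureSelection(X, y, character(0)), "no candidate")
})

test_that("transfer evaluation trains once and scores a held-out set", {
  tr <- makePlantedSet(40, 40, delta = 0.05, seed = 31)
  te <- makePlantedSet(30, 30, delta = 0.05, seed = 32)
  Xtr <- assembleFeatures(tr, "f2"); ytr <- unname(labels(tr))
  Xte <- assembleFeatures(te, "f2"); yte <- unname(labels(te))
  res <- transferEvaluate(Xtr, ytr, Xte, yte, C_grid = c(0.1, 1, 10),
                          folds = 5, seed = 3)
  expect_gte(res$auroc, 0.9)
  # resubstitution is at least as good as the transfer estimate here
  resub <- transferEvaluate(Xtr, ytr, Xtr, ytr, C_grid = c(0.1, 1, 10),
                            folds = 5, seed = 3)
  expect_gte(resub$auroc, res$auroc - 0.05)
  # flipping test labels mirrors the AUROC
  expect_equal(transferEvaluate(Xtr, ytr, Xte, -yte, C_grid = c(0.1, 1, 10),
                                folds = 5, seed = 3)$auroc, 1 - res$auroc)
  expect_error(transferEvaluate(Xtr, ytr, Xte[, 1:3], yte), "differ")
})

test_that("models survive a JSON round trip", {
  set.seed(8)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  y <- sign(X[, 2] + 0.2 * rnorm(20)); y[y == 0] <- 1
  m <- trainLinearSVM(X, y, C = 2)
  f <- tempfile(fileext = ".json")
  writeLinearSVM(m, f, metadata = list(seed = 8))
  m2 <- readLinearSVM(f)
  expect_equal(decisionScores(m2, X), decisionScores(m, X), tolerance = 1e-12)
  expect_equal(m2@cost, 2)
  unlink(f)
})
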
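#' Train a soft-margin linear SVM
#'
#' Fits a linear support vector machine (libsvm backend) at regularization
#' constant C and stores it in dual form, normalised so that positive
#' decision scores correspond to the +1 class regardless of input label
#' order. Features are used as-is (no internal scaling).
#'
#' @param X Numeric feature matrix with column names; rows = examples.
#' @param y Labels (+1/-1), one per row; both classes must have at least
#'   two examples.
#' @param C Positive regularization constant. Default 1.
#' @return A [LinearSVM-class] model.
#' @examples
#' X <- cbind(x = c(-2, -1, 1, 2)); rownames(X) <- letters[1:4]
#' m <- trainLinearSVM(X, c(-1, -1, 1, 1), C = 1)
#' decisionScores(m, X)
#' @export
trainLinearSVM <- function(X, y, C = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y), C > 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(sign(y))
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (min(table(y)) < 2L) stop("need >= 2 examples per class")
  if (anyNA(X)) stop("feature matrix contains missing values")
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE)
  # libsvm's decision value is positive for the class it lists first;
  # flip so that score > 0 always means the +1 class.
  flip <- if (fit$levels[fit$labels[1L]] == "pos") 1 else -1
  new("LinearSVM",
      supportCoefs = flip * as.numeric(fit$coefs),
      supportX = as.matrix(fit$SV),
      bias = -flip * fit$rho,
      cost = C,
      columnNames = colnames(X))
}

#' Decision scores of a linear SVM
#'
#' Evaluates the kernel expansion
#' `score(x) = sum_i alpha_i y_i <x_i, x> + b` for every row of `X`.
#'
#' @param model A [LinearSVM-class].
#' @param X Feature matrix whose columns match the training columns.
#' @return Numeric vector of scores (named by rownames of `X`).
#' @export
decisionScores <- function(model, X) {
  stopifnot(is(model, "LinearSVM"), is.matrix(X))
  if (!identical(colnames(X), model@columnNames)) {
    missing <- setdiff(model@columnNames, colnames(X))
    extra <- setdiff(colnames(X), model@columnNames)
    stop("feature columns do not match the model",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  if (nrow(X) == 0L) return(numeric(0))
  drop(X %*% t(model@supportX) %*% model@supportCoefs) + model@bias
}

#' Explicit feature weight vector of a linear SVM
#'
#' Collapses the dual form to the primal weight vector
#' `w = sum_i alpha_i y_i phi(x_i)` over the support vectors, named by
#' feature. `w . x + b` reproduces [decisionScores()].
#'
#' @param model A [LinearSVM-class].
#' @return Named numeric vector of per-feature weights.
#' @export
weightVector <- function(model) {
  stopifnot(is(model, "LinearSVM"))
  if (length(model@supportCoefs) == 0L)
    return(setNames(numeric(length(model@columnNames)), model@columnNames))
  setNames(drop(crossprod(model@supportX, model@supportCoefs)),
           model@columnNames)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) score
#' pairs ranked correctly, with ties counted one half.
#'
#' @param scores Numeric vector of decision scores.
#' @param labels Labels (+1/-1), both classes present.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))  # 1
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation folds
#'
#' Assigns each example to one of k folds, stratified by class so every
#' fold carries (nearly) the class proportions of the full set.
#'
#' @param y Labels (+1/-1).
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold ids in 1..k.
#' @export
makeStratifiedFolds <- function(y, k, seed) {
  stopifnot(k >= 2L)
  if (min(table(sign(y))) < k)
    stop("each class needs at least k = ", k,
         " members; reduce the number of folds")
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(sign(y))) {
      idx <- which(sign(y) == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Mean CV AUROC of a linear SVM at fixed C over given fold assignments.
cvAUROC <- function(X, y, C, fold) {
  k <- max(fold)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- trainLinearSVM(X[tr, , drop = FALSE], y[tr], C)
    auroc(decisionScores(m, X[!tr, , drop = FALSE]), y[!tr])
  }, 1)
  mean(aucs)
}

# Smallest C in the grid achieving the maximal inner-CV mean AUROC.
chooseC <- function(X, y, C_grid, folds, seed) {
  fold <- makeStratifiedFolds(y, folds, seed)
  scores <- vapply(C_grid, function(C) cvAUROC(X, y, C, fold), 1)
  C_grid[order(-scores, C_grid)[1L]]
}

#' Nested (double) cross-validation
#'
#' Estimates classifier performance by a stratified outer k-fold CV loop
#' in which, for every outer training portion, the regularization constant
#' C is chosen from a grid by an inner k-fold CV loop (smallest C
#' achieving the maximal inner mean AUROC). Reported performance is the
#' mean outer-fold test AUROC.
#'
#' @param X Feature matrix with column names.
#' @param y Labels (+1/-1); each class needs at least `outer_folds`
#'   members.
#' @param outer_folds,inner_folds Fold counts (default 10 and 10).
#' @param C_grid Candidate C values. Default `10^(-3:3)`.
#' @param seed Integer seed controlling both fold layers.
#' @param keep_weights If `TRUE`, also return the per-outer-fold primal
#'   weight vectors (features x folds matrix).
#' @return List of class `CVResult`: `fold_auroc`, `mean_auroc`,
#'   `chosen_C`, `fold`, `seed`, and optionally `fold_weights`.
#' @export
nestedCV <- function(X, y, outer_folds = 10L, C_grid = 10^(-3:3), seed = 1L,
                     inner_folds = 10L, keep_weights = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fold <- makeStratifiedFolds(y, outer_folds, seed)
  fold_auroc <- numeric(outer_folds)
  chosen <- numeric(outer_folds)
  W <- if (keep_weights)
    matrix(NA_real_, ncol(X), outer_folds,
           dimnames = list(colnames(X), NULL))
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    C <- chooseC(Xtr, ytr, C_grid, inner_folds, deriveSeed(seed, paste0("inner", f)))
    m <- trainLinearSVM(Xtr, ytr, C)
    fold_auroc[f] <- auroc(decisionScores(m, X[!tr, , drop = FALSE]), y[!tr])
    chosen[f] <- C
    if (keep_weights) W[, f] <- weightVector(m)
  }
  out <- list(fold_auroc = fold_auroc, mean_auroc = mean(fold_auroc),
              chosen_C = chosen, fold = fold, seed = seed)
  if (keep_weights) out$fold_weights <- W
  structure(out, class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat("Nested cross-validation result\n")
  cat("  mean AUROC:", format(x$mean_auroc, digits = 4),
      "over", length(x$fold_auroc), "outer folds\n")
  cat("  chosen C:", paste(format(x$chosen_C), collapse = " "), "\n")
  invisible(x)
}

#' Normalize feature contributions to the unit maximum
#'
#' Divides every entry of a weight vector by the maximum absolute entry so
#' the largest contribution has magnitude 1; signs are preserved. Used to
#' put classifiers trained on different datasets on a common scale before
#' comparison.
#'
#' @param w Named numeric weight vector with at least one nonzero entry.
#' @return Normalized weight vector.
#' @examples
#' normalizeContributions(c(a = 2, b = -4))
#' @export
normalizeContributions <- function(w) {
  m <- max(abs(w))
  if (m == 0) stop("all-zero weight vector cannot be normalized")
  w / m
}

#' Correlation between two classifiers' weight vectors
#'
#' Pearson correlation over the (identically named) entries of two weight
#' vectors; high correlation means the classifiers assign similar weights
#' to the same features.
#'
#' @param w1,w2 Named numeric vectors over the same feature names.
#' @return Pearson correlation coefficient.
#' @export
compareWeightVectors <- function(w1, w2) {
  if (!setequal(names(w1), names(w2)))
    stop("weight vectors cover different feature names")
  cor(w1, w2[names(w1)])
}

#' Correlate classifier weights with an amino-acid property
#'
#' Pearson correlation between a weight vector and a user-supplied named
#' property (e.g. a per-amino-acid synthesis-cost table) over the name
#' intersection, with an optional exclusion list.
#'
#' @param w Named weight vector (e.g. per amino acid).
#' @param property Named numeric property values.
#' @param exclude Names to leave out (e.g. the aromatic residues).
#' @return List with `r`, `p` (correlation test p-value) and `n` shared
#'   names used.
#' @export
correlateWeightsWithProperty <- function(w, property, exclude = NULL) {
  shared <- setdiff(intersect(names(w), names(property)), exclude)
  if (length(shared) < 3L)
    stop("fewer than 3 shared names between weights and property")
  ct <- cor.test(w[shared], property[shared])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Greedy forward feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes the inner-CV mean AUROC of a linear SVM at fixed C, stopping
#' as soon as the best achievable score falls below the current score.
#' Ties are broken by candidate order.
#'
#' @param X Feature matrix.
#' @param y Labels (+1/-1).
#' @param candidates Ordered candidate column names (subset of
#'   `colnames(X)`).
#' @param C Fixed regularization constant. Default 1.
#' @param folds Inner CV folds. Default 10.
#' @param seed Integer seed (fold assignment is fixed across the whole
#'   selection run so step scores are comparable).
#' @return List with `selected` (ordered feature names) and `scores`
#'   (inner-CV AUROC after each addition).
#' @export
forwardFeatureSelection <- function(X, y, candidates, C = 1, folds = 10L,
                                    seed = 1L) {
  stopifnot(is.matrix(X))
  if (length(candidates) == 0L) stop("no candidate features")
  if (!all(candidates %in% colnames(X)))
    stop("candidates must be columns of X")
  fold <- makeStratifiedFolds(y, folds, seed)
  selected <- character(0)
  scores <- numeric(0)
  current <- -Inf
  remaining <- candidates
  while (length(remaining)) {
    stepBest <- -Inf; stepFeat <- NA_character_
    for (cand in remaining) {
      s <- cvAUROC(X[, c(selected, cand), drop = FALSE], y, C, fold)
      if (s > stepBest) { stepBest <- s; stepFeat <- cand }
    }
    if (stepBest < current) break
    selected <- c(selected, stepFeat)
    scores <- c(scores, stepBest)
    current <- stepBest
    remaining <- setdiff(remaining, stepFeat)
  }
  list(selected = selected, scores = scores)
}

#' Train on one dataset, evaluate on another
#'
#' Chooses C by k-fold CV on the training set, trains a single model on
#' all training data, and reports the AUROC on the held-out test set.
#'
#' @param X_train,y_train Training features and labels.
#' @param X_test,y_test Test features and labels (identical columns).
#' @param C_grid Candidate C values.
#' @param folds CV folds for choosing C. Default 10.
#' @param seed Integer seed.
#' @return List with `auroc`, `model` and `chosen_C`.
#' @export
transferEvaluate <- function(X_train, y_train, X_test, y_test,
                             C_grid = 10^(-3:3), folds = 10L, seed = 1L) {
  if (!identical(colnames(X_train), colnames(X_test)))
    stop("training and test feature columns differ")
  C <- chooseC(X_train, y_train, C_grid, folds, seed)
  m <- trainLinearSVM(X_train, y_train, C)
  list(auroc = auroc(decisionScores(m, X_test), y_test),
       model = m, chosen_C = C)
}

#' Serialize a linear SVM to JSON
#'
#' @param model A [LinearSVM-class].
#' @param path Output file path.
#' @param metadata Optional named list stored alongside the model.
#' @return `path`, invisibly.
#' @export
writeLinearSVM <- function(model, path, metadata = list()) {
  stopifnot(is(model, "LinearSVM"))
  obj <- list(format = "hiSecPred-linear-svm", version = 1L,
              column_names = model@columnNames,
              support_coefs = model@supportCoefs,
              support_x = model@supportX,
              bias = model@bias, cost = model@cost,
              metadata = metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a linear SVM from JSON
#'
#' @param path File written by [writeLinearSVM()].
#' @return A [LinearSVM-class].
#' @export
readLinearSVM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hiSecPred-linear-svm"))
    stop("not a hiSecPred linear SVM file: ", path)
  sx <- as.matrix(obj$support_x)
  colnames(sx) <- obj$column_names
  new("LinearSVM", supportCoefs = as.numeric(obj$support_coefs),
      supportX = sx, bias = obj$bias, cost = obj$cost,
      columnNames = obj$column_names)
}
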
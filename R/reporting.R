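# Reproducibility manifest attached to every report.
reportManifest <- function(seed, config) {
  list(seed = seed,
       config_hash = rlang::hash(config),
       package_version = as.character(utils::packageVersion("hiSecPred")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Compare feature sets by nested cross-validation
#'
#' Runs [nestedCV()] for each requested feature set on the same dataset
#' and seed, producing the per-feature-set AUROC comparison table
#' (randomized structural controls such as `"f4r"` can be included to
#' test whether a structural subsequence is more informative than a
#' length-matched random draw).
#'
#' @param set A labelled [SecretionSet-class].
#' @param feature_sets Character vector of feature-set names understood by
#'   [assembleFeatures()].
#' @param folds Outer/inner fold count. Default 10.
#' @param C_grid Candidate C values.
#' @param seed Integer seed.
#' @param clusters Optional [AAClusters-class] for `"f11"`.
#' @return `data.frame` with columns `feature_set`, `mean_auroc`, and
#'   `fold_auroc` (semicolon-joined per-fold values); the reproducibility
#'   manifest is attached as attribute `"manifest"`.
#' @export
runFeatureSetComparison <- function(set, feature_sets = c("f1", "f2", "f10"),
                                    folds = 10L, C_grid = 10^(-3:3),
                                    seed = 1L, clusters = NULL) {
  stopifnot(is(set, "SecretionSet"))
  bad <- setdiff(feature_sets, FEATURE_SETS)
  if (length(bad)) stop("unknown feature set(s): ", paste(bad, collapse = ", "))
  y <- unname(labels(set))
  rows <- lapply(feature_sets, function(fs) {
    X <- assembleFeatures(set, fs, clusters = clusters, seed = seed)
    cv <- nestedCV(X, y, outer_folds = folds, C_grid = C_grid, seed = seed,
                   inner_folds = folds)
    data.frame(feature_set = fs, mean_auroc = cv$mean_auroc,
               fold_auroc = paste(signif(cv$fold_auroc, 6), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- reportManifest(seed,
    list(feature_sets = feature_sets, folds = folds, C_grid = C_grid))
  out
}

# Group feature columns by absolute correlation above a threshold
# (single linkage); returns a named group label per feature.
correlationGroups <- function(X, threshold) {
  p <- ncol(X)
  if (threshold >= 1 || p == 1L)
    return(setNames(colnames(X), colnames(X)))
  cm <- suppressWarnings(abs(cor(X)))
  cm[is.na(cm)] <- 0
  parent <- seq_len(p)
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p))
    if (cm[i, j] > threshold) {
      ri <- ufFind(parent, i); rj <- ufFind(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  comp <- vapply(seq_len(p), function(i) ufFind(parent, i), 1L)
  labs <- vapply(seq_len(p), function(i) {
    members <- colnames(X)[comp == comp[i]]
    if (length(members) == 1L) members[1L]
    else paste0(members[1L], "|+", length(members) - 1L)
  }, "")
  setNames(labs, colnames(X))
}

#' Feature selection frequency across CV loops
#'
#' Runs greedy forward feature selection on the training portion of each
#' outer CV fold and tabulates, for the first few selection iterations,
#' how often each feature (or group of mutually correlated features) was
#' selected across folds.
#'
#' @param set A labelled [SecretionSet-class].
#' @param pool Feature matrix to select from; default [selectionPool()].
#' @param folds Outer folds. Default 10.
#' @param C Fixed regularization constant during selection. Default 1.
#' @param seed Integer seed.
#' @param max_iter Number of selection iterations to tabulate. Default 3.
#' @param cor_threshold Features with absolute pairwise correlation above
#'   this value are counted as one group. Default 0.7; use 1 to disable
#'   grouping.
#' @param alpha Significance level of the t-test prefilter applied to the
#'   pool before selection. Default 0.05.
#' @return List with `counts` (list per iteration: named selection counts
#'   summing to the number of folds), `selected` (list of per-fold
#'   selection paths) and the manifest.
#' @export
runSelectionFrequency <- function(set, pool = NULL, folds = 10L, C = 1,
                                  seed = 1L, max_iter = 3L,
                                  cor_threshold = 0.7, alpha = 0.05) {
  stopifnot(is(set, "SecretionSet"))
  if (is.null(pool)) pool <- selectionPool(set)
  y <- unname(labels(set))
  groups <- correlationGroups(pool, cor_threshold)
  fold <- makeStratifiedFolds(y, folds, seed)
  paths <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- pool[tr, , drop = FALSE]
    keep <- ttestPrefilter(Xtr, y[tr], alpha)$feature
    if (length(keep) == 0L) keep <- colnames(pool)
    sel <- forwardFeatureSelection(Xtr, y[tr], keep, C = C,
                                   folds = min(folds, 10L),
                                   seed = deriveSeed(seed, paste0("sel", f)))
    paths[[f]] <- sel$selected
  }
  counts <- lapply(seq_len(max_iter), function(it) {
    feats <- vapply(paths, function(p)
      if (length(p) >= it) groups[[p[it]]] else "(none)", "")
    table(feats)
  })
  list(counts = counts, selected = paths,
       manifest = reportManifest(seed, list(folds = folds, C = C,
                                            cor_threshold = cor_threshold)))
}

#' Score a protein collection with a trained model
#'
#' Applies a trained classifier to a feature matrix (e.g. a whole
#' proteome) and summarizes the decision-score distribution.
#'
#' @param model A [LinearSVM-class].
#' @param X Feature matrix with columns matching the model.
#' @param flags Optional named logical vector (e.g. signal-peptide
#'   presence) carried through to the output.
#' @return List with `scores`, `fraction_positive` (scores above 0), `n`
#'   and `flags`.
#' @export
runProteomeScan <- function(model, X, flags = NULL) {
  scores <- decisionScores(model, X)
  list(scores = scores,
       fraction_positive = if (length(scores)) mean(scores > 0) else NA_real_,
       n = length(scores), flags = flags)
}
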
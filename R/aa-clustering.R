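#' Greedy data-driven amino-acid clustering
#'
#' Builds a reduced amino-acid alphabet directly from data. The method
#' starts by selecting the single best-performing amino acid (the one
#' whose composition alone gives the highest evaluator score). In every
#' later iteration, each remaining amino acid is tried both as a new
#' singleton cluster and merged into each existing cluster; the single
#' best-scoring placement is committed. Iterations continue until no
#' amino acids remain, and the best-scoring committed state ever observed
#' is returned -- so amino acids placed after the peak may be absent from
#' the result.
#'
#' Candidates are evaluated in alphabetical order with the new-cluster
#' option before the merges, and the first maximum wins, making traces
#' fully deterministic.
#'
#' @param evaluator Function taking a list of character vectors (the
#'   clusters) and returning a numeric score. See
#'   [makeCVClusterEvaluator()] for the default cross-validated SVM
#'   evaluator.
#' @param alphabet Letters to place; default the 20 amino acids.
#' @return List with `best` (an [AAClusters-class] of the best state),
#'   `best_score`, `final` (the state after all letters are placed) and
#'   `trace` (`data.frame` of committed placements: iteration, letter,
#'   action `"new"`/`"merge"`, target cluster index, score, and the
#'   running best score).
#' @examples
#' ev <- function(cl) sum(vapply(cl, function(s) "Q" %in% s, TRUE)) -
#'   0.1 * length(unlist(cl))
#' greedyAAClustering(ev, alphabet = c("A", "Q"))$best
#' @export
greedyAAClustering <- function(evaluator, alphabet = AA20) {
  stopifnot(is.function(evaluator), length(alphabet) >= 1L)
  alphabet <- sort(alphabet)
  evalState <- function(state) {
    s <- tryCatch(evaluator(state), error = function(e)
      stop("evaluator failed on state {",
           paste(vapply(state, paste, "", collapse = ""), collapse = "; "),
           "}: ", conditionMessage(e), call. = FALSE))
    if (!is.numeric(s) || length(s) != 1L || is.na(s))
      stop("evaluator must return a single finite score")
    unname(s)
  }
  # iteration 0: best single amino acid
  s0 <- vapply(alphabet, function(a) evalState(list(a)), 1)
  first <- alphabet[which.max(s0)]
  clusters <- list(first)
  remaining <- setdiff(alphabet, first)
  trace <- data.frame(iteration = 0L, letter = first, action = "start",
                      cluster = 1L, score = max(s0), best_score = max(s0),
                      stringsAsFactors = FALSE)
  best_state <- clusters; best_score <- max(s0)
  it <- 0L
  while (length(remaining)) {
    it <- it + 1L
    stepBest <- -Inf; stepState <- NULL
    stepLetter <- NA_character_; stepAction <- NA_character_; stepCluster <- NA_integer_
    for (a in remaining) {
      cand <- c(clusters, list(a))
      s <- evalState(cand)
      if (s > stepBest) {
        stepBest <- s; stepState <- cand; stepLetter <- a
        stepAction <- "new"; stepCluster <- length(cand)
      }
      for (j in seq_along(clusters)) {
        cand <- clusters
        cand[[j]] <- sort(c(cand[[j]], a))
        s <- evalState(cand)
        if (s > stepBest) {
          stepBest <- s; stepState <- cand; stepLetter <- a
          stepAction <- "merge"; stepCluster <- j
        }
      }
    }
    clusters <- stepState
    remaining <- setdiff(remaining, stepLetter)
    if (stepBest > best_score) { best_score <- stepBest; best_state <- clusters }
    trace <- rbind(trace, data.frame(iteration = it, letter = stepLetter,
                                     action = stepAction, cluster = stepCluster,
                                     score = stepBest, best_score = best_score,
                                     stringsAsFactors = FALSE))
  }
  list(best = AAClusters(best_state), best_score = best_score,
       final = AAClusters(clusters), trace = trace)
}

#' Cross-validated SVM evaluator for amino-acid clusterings
#'
#' Builds the default evaluator used by [greedyAAClustering()]: a
#' clustering is scored by the mean inner k-fold CV AUROC of a linear SVM
#' at fixed C trained on the cluster-composition features of the given
#' sequences. The fold assignment is fixed once from the labels and seed,
#' so all candidate states are scored on identical folds.
#'
#' @param sequences Named character vector of (mature) protein sequences.
#' @param y Labels (+1/-1) aligned with `sequences`.
#' @param C Fixed regularization constant. Default 1.
#' @param folds CV folds. Default 10.
#' @param seed Integer seed for the fold assignment.
#' @return A function from a cluster list to a numeric score.
#' @export
makeCVClusterEvaluator <- function(sequences, y, C = 1, folds = 10L, seed = 1L) {
  comps <- t(vapply(sequences, composition, setNames(numeric(20), AA20)))
  fold <- makeStratifiedFolds(y, folds, seed)
  function(clusters) {
    X <- vapply(clusters, function(s)
      rowSums(comps[, s, drop = FALSE]), numeric(nrow(comps)))
    X <- matrix(X, nrow = nrow(comps),
                dimnames = list(rownames(comps),
                                paste0("cl", seq_along(clusters))))
    cvAUROC(X, y, C, fold)
  }
}

#' Co-occurrence matrix of repeated clusterings
#'
#' Aggregates a list of amino-acid clusterings (e.g. one per CV loop) into
#' a symmetric 20 x 20 count matrix: the off-diagonal entry (a, b) counts
#' the clusterings in which a and b share a cluster, the diagonal entry
#' (a, a) counts the clusterings in which a appears in any cluster.
#'
#' @param clusterings List of [AAClusters-class] objects (or plain cluster
#'   lists).
#' @return Symmetric integer matrix over the 20 amino acids.
#' @export
clusterCooccurrence <- function(clusterings) {
  stopifnot(length(clusterings) >= 1L)
  M <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
  for (cl in clusterings) {
    sets <- if (is(cl, "AAClusters")) clusterList(cl) else cl
    for (s in sets) {
      for (a in s) M[a, a] <- M[a, a] + 1L
      if (length(s) > 1L) {
        prs <- utils::combn(sort(s), 2L)
        for (p in seq_len(ncol(prs))) {
          a <- prs[1L, p]; b <- prs[2L, p]
          M[a, b] <- M[a, b] + 1L
          M[b, a] <- M[b, a] + 1L
        }
      }
    }
  }
  M
}
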
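# Independent oracles used to cross-check the implementation.

# Smith-Waterman local alignment by explicit dynamic programming with
# linear gap penalty; returns identity over alignment columns and the
# aligned span fraction of each sequence.
swOracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  i <- best[1] - 1; j <- best[2] - 1
  matches <- 0; cols <- 0; endA <- i; endB <- j
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    s <- if (A[i] == B[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + s) {
      matches <- matches + (A[i] == B[j]); cols <- cols + 1
      i <- i - 1; j <- j - 1
    } else if (H[i + 1, j + 1] == H[i, j + 1] + gap) {
      cols <- cols + 1; i <- i - 1
    } else {
      cols <- cols + 1; j <- j - 1
    }
  }
  list(score = max(H), identity = if (cols) matches / cols else 0,
       coverage = c(a = (endA - i) / n, b = (endB - j) / m))
}

# Spectrum kernel by brute-force double loop over the union k-mer
# vocabulary.
bruteSpectrumKernel <- function(seqs, k) {
  countKmers <- function(s) {
    n <- nchar(s)
    kk <- substring(s, 1:(n - k + 1), k:n)
    table(kk)
  }
  counts <- lapply(seqs, countKmers)
  vocab <- unique(unlist(lapply(counts, names)))
  K <- matrix(0, length(seqs), length(seqs))
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    s <- 0
    for (v in vocab) {
      ci <- counts[[i]][v]; cj <- counts[[j]][v]
      if (!is.na(ci) && !is.na(cj)) s <- s + as.numeric(ci) * as.numeric(cj)
    }
    K[i, j] <- s
  }
  K
}

# All amino-acid clusterings with omissions over a small alphabet: every
# non-empty subset, partitioned in every possible way.
enumerateClusterings <- function(alphabet) {
  partitions <- function(items) {
    if (length(items) == 0) return(list(list()))
    first <- items[1]; rest <- items[-1]
    out <- list()
    for (p in partitions(rest)) {
      out <- c(out, list(c(list(first), p)))
      if (length(p)) for (j in seq_along(p)) {
        q <- p; q[[j]] <- sort(c(q[[j]], first))
        out <- c(out, list(q))
      }
    }
    out
  }
  states <- list()
  n <- length(alphabet)
  for (mask in 1:(2^n - 1)) {
    subset <- alphabet[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
    states <- c(states, partitions(subset))
  }
  states
}

# Deterministic additive clustering evaluator: per-letter values plus a
# bonus for every pair sharing a cluster. Greedy search can reach the
# global optimum for this family, so exhaustive enumeration is a valid
# oracle for it.
additiveEvaluator <- function(values, bonus) {
  function(clusters) {
    s <- sum(values[unlist(clusters)])
    for (cl in clusters)
      if (length(cl) > 1) {
        prs <- combn(sort(cl), 2)
        for (p in seq_len(ncol(prs)))
          s <- s + bonus[[paste(prs[1, p], prs[2, p], sep = "")]]
      }
    s
  }
}

# Tiny labelled dataset with one strongly separating composition feature
# (tyrosine enriched in positives).
makePlantedSet <- function(n_pos, n_neg, delta = 0.05, seed = 1) {
  cfg <- effectConfig(delta = c(Y = delta, K = -delta))
  generateProteins(n_pos, n_neg, cfg, seed = seed)
}
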
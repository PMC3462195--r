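#' Letter composition of a sequence
#'
#' Fraction of each alphabet symbol in a sequence: for symbol a,
#' `count(a, seq) / length(seq)`. Works on amino-acid strings, state
#' strings, or token vectors such as codon sequences.
#'
#' @param seq A single string (split into characters) or a character vector
#'   of tokens.
#' @param alphabet Ordered character vector defining the feature order;
#'   defaults to the 20 amino acids.
#' @return Named numeric vector over `alphabet`, summing to 1.
#' @examples
#' composition("AAY")[c("A", "Y")]
#' @export
composition <- function(seq, alphabet = AA20) {
  toks <- if (length(seq) == 1L && is.character(seq)) chars(seq) else as.character(seq)
  if (length(toks) == 0L) stop("empty sequence has no composition")
  bad <- setdiff(unique(toks), alphabet)
  if (length(bad))
    stop("symbol(s) outside alphabet: ", paste(bad, collapse = ", "))
  tab <- table(factor(toks, levels = alphabet))
  as.numeric(tab) / length(toks) -> v
  setNames(v, alphabet)
}

#' Cluster composition (reduced-alphabet features)
#'
#' Summed amino-acid composition per cluster: for cluster S, the feature is
#' the fraction of residues belonging to S.
#'
#' @param seq Amino-acid string.
#' @param clusters An [AAClusters-class] object.
#' @return Named numeric vector, one entry per cluster.
#' @examples
#' clusterComposition("DE", predefinedClusters())["acidic"]
#' @export
clusterComposition <- function(seq, clusters = predefinedClusters()) {
  stopifnot(is(clusters, "AAClusters"))
  comp <- composition(seq)
  cl <- clusterList(clusters)
  nm <- names(cl)
  if (is.null(nm)) nm <- paste0("cluster", seq_along(cl))
  setNames(vapply(cl, function(s) sum(comp[s]), 1), nm)
}

#' Relative synonymous codon usage
#'
#' For each of the 59 codons in multi-codon synonymous families (single
#' codon families ATG/Met and TGG/Trp and the stop codons are excluded),
#' the codon count divided by the count of the amino acid it encodes. For
#' every amino acid present in the translation, its family's entries sum
#' to 1; families of absent amino acids are 0.
#'
#' @param codon_seq Character vector of codon tokens (see
#'   [toCodonSequence()]).
#' @return Named numeric vector of 59 codon-usage fractions.
#' @examples
#' codonUsage(c("ATG", "GCT", "GCC", "TAA"))[c("GCT", "GCC")]
#' @export
codonUsage <- function(codon_seq) {
  if (length(codon_seq) == 0L) stop("empty codon sequence")
  out <- setNames(numeric(length(MULTIFAM_CODONS)), MULTIFAM_CODONS)
  counts <- table(factor(codon_seq, levels = CODONS64))
  for (aa in setdiff(names(AA2CODONS), "*")) {
    fam <- AA2CODONS[[aa]]
    if (length(fam) < 2L) next
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- as.numeric(counts[fam]) / tot
  }
  out
}

#' Relative adaptiveness table from a reference gene set
#'
#' Builds the per-codon relative adaptiveness w used by the codon
#' adaptation index: within each multi-codon synonymous family, each
#' codon's count across the reference collection divided by the count of
#' the most frequent codon in that family. Codons unobserved in the
#' reference are floored at a small pseudo-value (0.01) so geometric means
#' stay finite.
#'
#' @param orf_collection List of codon-token vectors, a character vector of
#'   ORF strings, or a [Biostrings::DNAStringSet].
#' @param floor Pseudo-value for zero-count codons. Default 0.01.
#' @return Named numeric vector of 59 w values in (0, 1].
#' @export
buildReferenceIndex <- function(orf_collection, floor = 0.01) {
  if (is(orf_collection, "DNAStringSet"))
    orf_collection <- as.character(orf_collection)
  if (is.character(orf_collection))
    orf_collection <- lapply(orf_collection, toCodonSequence)
  if (length(orf_collection) == 0L) stop("empty reference collection")
  all_cod <- unlist(orf_collection, use.names = FALSE)
  counts <- table(factor(all_cod, levels = CODONS64))
  w <- setNames(numeric(length(MULTIFAM_CODONS)), MULTIFAM_CODONS)
  for (aa in setdiff(names(AA2CODONS), "*")) {
    fam <- AA2CODONS[[aa]]
    if (length(fam) < 2L) next
    cmax <- max(counts[fam])
    w[fam] <- if (cmax == 0) floor else pmax(as.numeric(counts[fam]) / cmax, floor)
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w over a gene's codons,
#' excluding stop codons and the single-codon families ATG and TGG.
#'
#' @param codon_seq Character vector of codon tokens.
#' @param reference Named w table from [buildReferenceIndex()].
#' @return CAI value in (0, 1].
#' @examples
#' w <- buildReferenceIndex(list(c("GCT", "GCT", "GCC")))
#' codonAdaptationIndex(c("ATG", "GCT", "GCC", "TAA"), w)
#' @export
codonAdaptationIndex <- function(codon_seq, reference) {
  elig <- codon_seq[codon_seq %in% MULTIFAM_CODONS]
  if (length(elig) == 0L)
    stop("no codons from multi-codon families; CAI undefined")
  exp(mean(log(reference[elig])))
}

# Bjellqvist pKa values (the table used by the field's standard pI tools).
bjellqvistPKa <- function() {
  list(positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
       negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0))
}

#' Isoelectric point of a protein
#'
#' The pH at which the net charge of the protein is zero, with
#' Henderson-Hasselbalch charges over the two termini and the D/E/C/Y/H/K/R
#' side chains (Bjellqvist pKa table by default), found by bisection on
#' pH 0..14 to a tolerance of 1e-4.
#'
#' @param protein_seq Amino-acid string.
#' @param pKa List with `positive` and `negative` named pKa vectors; see
#'   `hiSecPred:::bjellqvistPKa()` for the default layout.
#' @param tol Bisection tolerance on pH. Default 1e-4.
#' @return The pI (numeric scalar).
#' @examples
#' isoelectricPoint("KKKK") > isoelectricPoint("DDDD")
#' @export
isoelectricPoint <- function(protein_seq, pKa = bjellqvistPKa(), tol = 1e-4) {
  assertScalarString(protein_seq, "protein_seq")
  comp <- table(chars(protein_seq))
  npos <- c(Nterm = 1, comp[intersect(names(comp), c("K", "R", "H"))])
  nneg <- c(Cterm = 1, comp[intersect(names(comp), c("D", "E", "C", "Y"))])
  charge <- function(pH) {
    pos <- sum(vapply(names(npos), function(g)
      npos[[g]] / (1 + 10^(pH - pKa$positive[[g]])), 1))
    neg <- sum(vapply(names(nneg), function(g)
      nneg[[g]] / (1 + 10^(pKa$negative[[g]] - pH)), 1))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Overlapping k-mer counts
#'
#' Counts all overlapping length-k windows of a sequence.
#'
#' @param seq A string.
#' @param k Window length, `1 <= k`. If `k > nchar(seq)` an empty vector is
#'   returned with a warning.
#' @return Named integer vector of counts; the counts sum to
#'   `nchar(seq) - k + 1`.
#' @examples
#' kmerCounts("NANAS", 2)
#' @export
kmerCounts <- function(seq, k) {
  assertScalarString(seq, "seq")
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- nchar(seq)
  if (k > n) {
    warning("k (", k, ") exceeds sequence length (", n, "); no k-mers")
    return(setNames(integer(0), character(0)))
  }
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  tab <- table(kmers)
  setNames(as.integer(tab), names(tab))
}

#' Spectrum kernel matrix
#'
#' Similarity between sequences defined as the inner product of their
#' overlapping k-mer count vectors. The resulting matrix is symmetric and
#' positive semi-definite.
#'
#' @param seqs Named character vector of sequences, all at least k long.
#' @param k k-mer length.
#' @return Symmetric numeric matrix with one row/column per sequence.
#' @examples
#' spectrumKernelMatrix(c(a = "AAA", b = "AAB"), k = 2)
#' @export
spectrumKernelMatrix <- function(seqs, k) {
  seqs <- setNames(as.character(seqs), names(seqs))
  short <- which(nchar(seqs) < k)
  if (length(short))
    stop("sequence(s) shorter than k=", k, ": ",
         paste(if (is.null(names(seqs))) short else names(seqs)[short],
               collapse = ", "))
  counts <- lapply(seqs, kmerCounts, k = k)
  vocab <- sort(unique(unlist(lapply(counts, names))))
  M <- matrix(0, length(seqs), length(vocab),
              dimnames = list(names(seqs), vocab))
  for (i in seq_along(counts)) M[i, names(counts[[i]])] <- counts[[i]]
  tcrossprod(M)
}

#' Welch t-test feature prefilter
#'
#' Applies a two-sample Welch t-test to every column of a feature matrix
#' and keeps the columns with p below `alpha`, ordered by decreasing
#' absolute t statistic. Constant columns get p = 1 and are never selected.
#'
#' @param X Numeric feature matrix (rows = proteins).
#' @param y Labels (+1/-1), one per row.
#' @param alpha Significance threshold. Default 0.05.
#' @return `data.frame` with columns `feature`, `t`, `p` for the selected
#'   columns, sorted by `abs(t)` descending.
#' @export
ttestPrefilter <- function(X, y, alpha = 0.05) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  pos <- y > 0; neg <- !pos
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  res <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[pos, j]; b <- X[neg, j]
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / length(a) + vb / length(b)
    if (!is.finite(se2) || se2 == 0) return(c(t = 0, p = 1))
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
    c(t = tstat, p = 2 * pt(-abs(tstat), df))
  }, c(t = 0, p = 0))
  out <- data.frame(feature = colnames(X), t = res["t", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(-abs(out$t)), , drop = FALSE]
}

FEATURE_SETS <- c("f0", "f1", "f2", "f3", "f4", "f5", "f6", "f7", "f8", "f9",
                  "f10", "f11", "f12", "f13",
                  "f4r", "f5r", "f7r", "f8r", "f9r",
                  "f15", "f16", "f17", "f18", "f19", "f20", "f21", "f22")

# Stack a list of equal-alphabet named vectors into a matrix.
stackRows <- function(vecs, prefix, ids) {
  M <- do.call(rbind, vecs)
  colnames(M) <- paste0(prefix, colnames(M))
  rownames(M) <- ids
  M
}

compositionOrZero <- function(s, alphabet, prefix, id) {
  if (nchar(s) == 0L) {
    warning("empty ", prefix, "subsequence for record ", id,
            "; zero feature row emitted")
    return(setNames(numeric(length(alphabet)), alphabet))
  }
  composition(s, alphabet)
}

#' Assemble a named feature matrix for a feature set
#'
#' Computes one of the standard feature sets from a dataset:
#' \describe{
#'   \item{f0}{64 codon compositions of the ORF codon sequence.}
#'   \item{f1 / f2}{20 amino-acid compositions of the signal peptide /
#'     mature sequence.}
#'   \item{f3}{buried/exposed state composition (2 columns).}
#'   \item{f4 / f5}{20 aa compositions of the buried / exposed
#'     subsequence; f4r / f5r their randomized length-matched controls.}
#'   \item{f6}{helix/strand/coil state composition (3 columns).}
#'   \item{f7 / f8 / f9}{20 aa compositions of the helix / strand / coil
#'     subsequence; f7r / f8r / f9r randomized controls.}
#'   \item{f10}{11 predefined physicochemical cluster compositions of the
#'     mature sequence.}
#'   \item{f11}{compositions of data-driven clusters (pass `clusters`).}
#'   \item{f12}{59 codon-usage fractions.}
#'   \item{f13}{signal-peptide length, protein length, codon adaptation
#'     index, isoelectric point.}
#'   \item{f15-f18}{k-mer counts (k = 2..5) of the full protein sequence.}
#'   \item{f19-f22}{k-mer counts (k = 2..5) of the signal peptide.}
#' }
#' An empty structural subsequence yields a zero feature row plus a
#' warning, keeping row alignment across feature sets.
#'
#' @param set A [SecretionSet-class] (ORFs required for f0/f12/f13,
#'   annotations for all structure-derived sets).
#' @param feature_set One of the names above.
#' @param clusters [AAClusters-class] for `"f11"`.
#' @param reference Relative-adaptiveness table for the CAI column of
#'   `"f13"`; defaults to an index built from the dataset's own ORFs.
#' @param seed Seed for randomized-control subsequences.
#' @return Numeric matrix, rows = records (in input order), named columns.
#' @examples
#' ss <- generateProteins(3, 3, effectConfig(), seed = 1)
#' dim(assembleFeatures(ss, "f2"))
#' @export
assembleFeatures <- function(set, feature_set = "f2", clusters = NULL,
                             reference = NULL, seed = 1L) {
  stopifnot(is(set, "SecretionSet"))
  feature_set <- match.arg(feature_set, FEATURE_SETS)
  ids <- names(set)
  needOrf <- feature_set %in% c("f0", "f12", "f13")
  if (needOrf && length(orfs(set)) == 0L)
    stop("feature set ", feature_set, " requires ORF sequences")
  kmerMatrix <- function(seqs, k, prefix) {
    counts <- lapply(seqs, kmerCounts, k = k)
    vocab <- sort(unique(unlist(lapply(counts, names))))
    M <- matrix(0, length(seqs), length(vocab),
                dimnames = list(ids, paste0(prefix, vocab)))
    for (i in seq_along(counts))
      M[i, paste0(prefix, names(counts[[i]]))] <- counts[[i]]
    M
  }
  switch(feature_set,
    f0 = {
      reps <- representationOf(set, "orf_codons")
      stackRows(lapply(reps, composition, alphabet = CODONS64), "codon:", ids)
    },
    f1 = stackRows(lapply(representationOf(set, "signal_peptide"),
                          composition), "sp:", ids),
    f2 = stackRows(lapply(representationOf(set, "mature"),
                          composition), "comp:", ids),
    f3 = stackRows(lapply(representationOf(set, "acc_string"),
                          composition, alphabet = c("B", "E")), "acc:", ids),
    f4 = stackRows(Map(compositionOrZero, representationOf(set, "buried"),
                       list(AA20), "buried:", ids), "buried:", ids),
    f5 = stackRows(Map(compositionOrZero, representationOf(set, "exposed"),
                       list(AA20), "exposed:", ids), "exposed:", ids),
    f6 = stackRows(lapply(representationOf(set, "ss_string"),
                          composition, alphabet = c("H", "E", "C")), "ss:", ids),
    f7 = stackRows(Map(compositionOrZero, representationOf(set, "helix"),
                       list(AA20), "helix:", ids), "helix:", ids),
    f8 = stackRows(Map(compositionOrZero, representationOf(set, "strand"),
                       list(AA20), "strand:", ids), "strand:", ids),
    f9 = stackRows(Map(compositionOrZero, representationOf(set, "coil"),
                       list(AA20), "coil:", ids), "coil:", ids),
    f4r = stackRows(Map(compositionOrZero,
                        representationOf(set, "buried_rand", seed),
                        list(AA20), "buriedRand:", ids), "buriedRand:", ids),
    f5r = stackRows(Map(compositionOrZero,
                        representationOf(set, "exposed_rand", seed),
                        list(AA20), "exposedRand:", ids), "exposedRand:", ids),
    f7r = stackRows(Map(compositionOrZero,
                        representationOf(set, "helix_rand", seed),
                        list(AA20), "helixRand:", ids), "helixRand:", ids),
    f8r = stackRows(Map(compositionOrZero,
                        representationOf(set, "strand_rand", seed),
                        list(AA20), "strandRand:", ids), "strandRand:", ids),
    f9r = stackRows(Map(compositionOrZero,
                        representationOf(set, "coil_rand", seed),
                        list(AA20), "coilRand:", ids), "coilRand:", ids),
    f10 = stackRows(lapply(representationOf(set, "mature"),
                           clusterComposition), "cluster:", ids),
    f11 = {
      if (is.null(clusters))
        stop("feature set f11 requires a data-driven AAClusters object")
      stackRows(lapply(representationOf(set, "mature"),
                       clusterComposition, clusters = clusters),
                "optcluster:", ids)
    },
    f12 = stackRows(lapply(representationOf(set, "orf_codons"),
                           codonUsage), "usage:", ids),
    f13 = {
      reps <- representationOf(set, "orf_codons")
      if (is.null(reference)) reference <- buildReferenceIndex(reps)
      ann <- annotations(set)
      seqs <- as.character(proteins(set))
      M <- cbind(
        sp_length = as.numeric(ann$cleavage_pos),
        protein_length = nchar(seqs),
        cai = vapply(reps, codonAdaptationIndex, 1, reference = reference),
        pI = vapply(seqs, isoelectricPoint, 1))
      rownames(M) <- ids
      M
    },
    f15 = kmerMatrix(as.character(proteins(set)), 2L, "2mer:"),
    f16 = kmerMatrix(as.character(proteins(set)), 3L, "3mer:"),
    f17 = kmerMatrix(as.character(proteins(set)), 4L, "4mer:"),
    f18 = kmerMatrix(as.character(proteins(set)), 5L, "5mer:"),
    f19 = kmerMatrix(representationOf(set, "signal_peptide"), 2L, "sp2mer:"),
    f20 = kmerMatrix(representationOf(set, "signal_peptide"), 3L, "sp3mer:"),
    f21 = kmerMatrix(representationOf(set, "signal_peptide"), 4L, "sp4mer:"),
    f22 = kmerMatrix(representationOf(set, "signal_peptide"), 5L, "sp5mer:"))
}

#' Combined 124-feature pool for feature selection
#'
#' Column-binds the seven composition-scale feature sets whose union has
#' exactly 124 columns -- ORF codon composition (f0, 64), signal-peptide
#' composition (f1, 20), mature composition (f2, 20), accessibility-state
#' composition (f3, 2), secondary-structure-state composition (f6, 3),
#' predefined cluster composition (f10, 11) and the four sequence-derived
#' scalars (f13) -- forming the default pool screened by
#' [ttestPrefilter()] ahead of forward feature selection.
#'
#' @inheritParams assembleFeatures
#' @return Numeric matrix with 124 named columns.
#' @export
selectionPool <- function(set, reference = NULL) {
  cbind(assembleFeatures(set, "f0"),
        assembleFeatures(set, "f1"),
        assembleFeatures(set, "f2"),
        assembleFeatures(set, "f3"),
        assembleFeatures(set, "f6"),
        assembleFeatures(set, "f10"),
        assembleFeatures(set, "f13", reference = reference))
}
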
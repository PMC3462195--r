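#' Dataset filter and redundancy-reduction configuration
#'
#' Collects the thresholds governing dataset construction: the minimum
#' protein length, which categorical filters are active (signal peptide
#' required, C-terminal ER-retention signal and transmembrane proteins
#' dropped), the local-alignment scoring used for pairwise identity, and
#' the identity/coverage thresholds defining sequence redundancy.
#'
#' @param min_length Minimum total protein length in residues; records must
#'   be strictly longer to be retained. Default 100.
#' @param require_signal_peptide Drop records whose annotation has
#'   `sp_flag = FALSE`. Default `TRUE`.
#' @param drop_er_retention Drop records ending in the ER-retention signal
#'   HDEL/KDEL. Default `TRUE`.
#' @param drop_transmembrane Drop records with `tm_flag = TRUE` (predicted
#'   transmembrane by both upstream predictors). Default `TRUE`.
#' @param identity_threshold Fraction in (0,1]: two sequences are redundant
#'   when their local-alignment identity reaches this value at sufficient
#'   coverage. Default 0.8.
#' @param coverage_threshold Fraction in (0,1]: minimum aligned fraction of
#'   at least one of the two sequences. Default 0.8.
#' @param match,mismatch,gap Local-alignment scoring (linear gap penalty).
#'   Defaults +1 / -1 / -2.
#' @return A list of class `FilterConfig`.
#' @examples
#' filterConfig(identity_threshold = 0.9)
#' @export
filterConfig <- function(min_length = 100L, require_signal_peptide = TRUE,
                         drop_er_retention = TRUE, drop_transmembrane = TRUE,
                         identity_threshold = 0.8, coverage_threshold = 0.8,
                         match = 1, mismatch = -1, gap = -2) {
  stopifnot(min_length >= 0,
            identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            gap <= 0)
  structure(list(min_length = as.integer(min_length),
                 require_signal_peptide = isTRUE(require_signal_peptide),
                 drop_er_retention = isTRUE(drop_er_retention),
                 drop_transmembrane = isTRUE(drop_transmembrane),
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 match = match, mismatch = mismatch, gap = gap),
            class = "FilterConfig")
}

#' Validate an ORF against its protein sequence
#'
#' An ORF is valid for a protein when it consists of the start codon through
#' the stop codon: its length is `3 * (nchar(protein) + 1)`, it starts with
#' ATG, ends with TAA/TAG/TGA, and standard-genetic-code translation of all
#' non-stop codons reproduces the protein sequence.
#'
#' @param protein_seq Amino-acid string.
#' @param orf_seq DNA string over A/C/G/T (case-insensitive).
#' @return A list with `valid` (logical) and `reasons` (character vector
#'   drawn from `"alphabet"`, `"length"`, `"stop"`, `"translation"`; empty
#'   when valid).
#' @examples
#' validateOrf("MA", "ATGGCTTAA")$valid     # TRUE
#' validateOrf("MA", "ATGGCT")$reasons      # "length"
#' @export
validateOrf <- function(protein_seq, orf_seq) {
  assertScalarString(protein_seq, "protein_seq")
  assertScalarString(orf_seq, "orf_seq")
  orf <- toupper(orf_seq)
  protein <- toupper(protein_seq)
  reasons <- character()
  if (grepl("[^ACGT]", orf)) reasons <- c(reasons, "alphabet")
  plen <- nchar(protein)
  if (nchar(orf) != 3L * (plen + 1L)) reasons <- c(reasons, "length")
  if (length(reasons) == 0L) {
    cods <- substring(orf, seq(1L, nchar(orf) - 2L, by = 3L),
                      seq(3L, nchar(orf), by = 3L))
    last <- cods[length(cods)]
    if (!last %in% STOP_CODONS) reasons <- c(reasons, "stop")
    body <- cods[-length(cods)]
    aa <- CODON2AA[body]
    if (cods[1L] != "ATG" || any(aa == "*") ||
        paste(aa, collapse = "") != protein)
      reasons <- c(reasons, "translation")
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Apply dataset construction filters
#'
#' Retains records that carry a predicted signal peptide, are longer than
#' the minimum length, do not end in the C-terminal ER-retention signal
#' ([HK]DEL), and are not predicted transmembrane; each dropped record is
#' reported with its exclusion reasons.
#'
#' @param set A [SecretionSet-class] with structural annotations attached.
#' @param config A [filterConfig()] list.
#' @return A list with `retained` (a `SecretionSet`, possibly zero-length
#'   represented as `NULL` when all records are dropped) and `exclusions`
#'   (a `data.frame` with columns `id` and `reason`; multiple reasons are
#'   joined with `";"`).
#' @examples
#' ss <- generateProteins(3, 3, effectConfig(), seed = 1)
#' applyFilters(ss, filterConfig())$exclusions
#' @export
applyFilters <- function(set, config = filterConfig()) {
  stopifnot(is(set, "SecretionSet"))
  if (!hasAnnotation(set))
    stop("all records need a structural annotation; none attached")
  ann <- annotations(set)
  ids <- names(set)
  miss <- ids[!ids %in% rownames(ann)]
  if (length(miss))
    stop("missing annotation for record(s): ", paste(miss, collapse = ", "))
  seqs <- as.character(proteins(set))
  reasons <- lapply(seq_along(ids), function(i) {
    r <- character()
    if (config$require_signal_peptide && !isTRUE(ann$sp_flag[i]))
      r <- c(r, "no_signal_peptide")
    if (nchar(seqs[i]) <= config$min_length)
      r <- c(r, "too_short")
    if (config$drop_er_retention && hasErRetention(seqs[i]))
      r <- c(r, "er_retention")
    if (config$drop_transmembrane && isTRUE(ann$tm_flag[i]))
      r <- c(r, "transmembrane")
    r
  })
  keep <- lengths(reasons) == 0L
  excl <- data.frame(
    id = ids[!keep],
    reason = vapply(reasons[!keep], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  list(retained = if (any(keep)) set[which(keep)] else NULL,
       exclusions = excl)
}

#' Pairwise local-alignment identity and coverage
#'
#' Aligns two amino-acid sequences with an optimal local (Smith-Waterman)
#' alignment under fixed scoring (by default match +1, mismatch -1, linear
#' gap -2) and reports the identity over the aligned columns and, per
#' sequence, the fraction of its residues covered by the alignment.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param config A [filterConfig()] supplying the scoring.
#' @return List with `identity` (matches / alignment columns) and
#'   `coverage` (named numeric of length 2: aligned residues of each
#'   sequence / its length).
#' @examples
#' pairwiseIdentity("PEPTIDE", "PEPTIDE")
#' @export
pairwiseIdentity <- function(seq_a, seq_b, config = filterConfig()) {
  assertScalarString(seq_a, "seq_a")
  assertScalarString(seq_b, "seq_b")
  alph <- unique(c(AA20, chars(seq_a), chars(seq_b)))
  sub <- matrix(config$mismatch, length(alph), length(alph),
                dimnames = list(alph, alph))
  diag(sub) <- config$match
  pa <- pairwiseAlignment(seq_a, seq_b, type = "local",
                          substitutionMatrix = sub,
                          gapOpening = 0, gapExtension = -config$gap)
  pat <- as.character(Biostrings::alignedPattern(pa))
  ncols <- nchar(pat)
  if (ncols == 0L)
    return(list(identity = 0, coverage = c(a = 0, b = 0)))
  id <- nmatch(pa) / ncols
  covA <- (end(pattern(pa)) - start(pattern(pa)) + 1L) / nchar(seq_a)
  covB <- (end(subject(pa)) - start(subject(pa)) + 1L) / nchar(seq_b)
  list(identity = id, coverage = c(a = covA, b = covB))
}

# TRUE when the pair is redundant under config thresholds: identity at or
# above the identity threshold with sufficient coverage of at least one
# sequence.
isRedundantPair <- function(seq_a, seq_b, config) {
  pi <- pairwiseIdentity(seq_a, seq_b, config)
  pi$identity >= config$identity_threshold &&
    max(pi$coverage) >= config$coverage_threshold
}

# Minimal union-find for single-linkage components.
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Redundancy reduction by single-linkage identity clustering
#'
#' Clusters records by single linkage over redundant pairs (local-alignment
#' identity at or above `identity_threshold` with coverage of at least one
#' sequence reaching `coverage_threshold`) and keeps one representative per
#' cluster: the member with the shortest mean distance (1 - identity) to
#' the other members, ties broken by lexicographic id. When a cluster mixes
#' production labels, one positive and one negative representative are
#' retained (each chosen within its label group); unknown-label members
#' form a third group treated the same way.
#'
#' @param set A [SecretionSet-class].
#' @param config A [filterConfig()].
#' @return A list with `retained` (a `SecretionSet` of representatives, in
#'   original record order) and `clusters` (list of character vectors of
#'   member ids).
#' @examples
#' ss <- SecretionSet(c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MWWHHPLGGC"),
#'                    label = c(1, 1, -1))
#' names(reduceRedundancy(ss)$retained)
#' @export
reduceRedundancy <- function(set, config = filterConfig()) {
  stopifnot(is(set, "SecretionSet"))
  n <- length(set)
  seqs <- as.character(proteins(set))
  ids <- names(set)
  if (n == 1L) return(list(retained = set, clusters = list(ids)))
  idm <- diag(n)
  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pi <- pairwiseIdentity(seqs[i], seqs[j], config)
      idm[i, j] <- idm[j, i] <- pi$identity
      if (pi$identity >= config$identity_threshold &&
          max(pi$coverage) >= config$coverage_threshold) {
        ri <- ufFind(parent, i); rj <- ufFind(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) ufFind(parent, i), 1L)
  keep <- logical(n)
  labs <- labels(set)
  clusters <- split(seq_len(n), comp)
  pickRep <- function(members) {
    # representative: min mean (1 - identity) to the other members
    if (length(members) == 1L) return(members)
    avg <- vapply(members, function(i)
      mean(1 - idm[i, setdiff(members, i)]), 1)
    ord <- order(avg, ids[members])
    members[ord[1L]]
  }
  for (members in clusters) {
    grp <- ifelse(is.na(labs[members]), "unk", as.character(labs[members]))
    for (g in unique(grp)) {
      sub <- members[grp == g]
      keep[pickRep(sub)] <- TRUE
    }
  }
  list(retained = set[which(keep)],
       clusters = unname(lapply(clusters, function(m) ids[m])))
}

#' Remove test-set records redundant with a training set
#'
#' Drops every test record that is redundant (same identity/coverage
#' criterion as [reduceRedundancy()]) with any training record, so that a
#' classifier trained on one set can be evaluated on the other without
#' homology leakage. The training set is never modified.
#'
#' @param test_set,train_set [SecretionSet-class] objects.
#' @param config A [filterConfig()].
#' @return The reduced test `SecretionSet` (or `NULL` if nothing survives).
#' @export
crossSetReduce <- function(test_set, train_set, config = filterConfig()) {
  stopifnot(is(test_set, "SecretionSet"))
  if (is.null(train_set) || length(train_set) == 0L) return(test_set)
  te <- as.character(proteins(test_set))
  tr <- as.character(proteins(train_set))
  keep <- vapply(te, function(s)
    !any(vapply(tr, function(t) isRedundantPair(s, t, config), TRUE)),
    TRUE)
  if (!any(keep)) return(NULL)
  test_set[which(keep)]
}
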
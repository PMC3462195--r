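REPRESENTATION_KINDS <- c("orf_codons", "signal_peptide", "mature",
                          "acc_string", "buried", "exposed",
                          "ss_string", "helix", "strand", "coil",
                          "buried_rand", "exposed_rand",
                          "helix_rand", "strand_rand", "coil_rand")

#' Split a protein into signal peptide and mature sequence
#'
#' @param protein_seq Amino-acid string.
#' @param cleavage_pos 1-based length of the signal peptide in residues;
#'   must satisfy `0 < cleavage_pos < nchar(protein_seq)` so that both
#'   parts are non-empty.
#' @return List with `signal_peptide` and `mature` strings whose
#'   concatenation equals the input.
#' @examples
#' splitSignalPeptide("MKKAVDA", 3)
#' @export
splitSignalPeptide <- function(protein_seq, cleavage_pos) {
  assertScalarString(protein_seq, "protein_seq")
  n <- nchar(protein_seq)
  cleavage_pos <- as.integer(cleavage_pos)
  if (is.na(cleavage_pos) || cleavage_pos <= 0L || cleavage_pos >= n)
    stop("cleavage_pos must satisfy 0 < cleavage_pos < protein length (",
         n, "), got ", cleavage_pos)
  list(signal_peptide = substr(protein_seq, 1L, cleavage_pos),
       mature = substr(protein_seq, cleavage_pos + 1L, n))
}

#' Tokenize an ORF into its codon sequence
#'
#' @param orf_seq DNA string with length divisible by 3 (case-insensitive).
#'   The stop codon, if present, is kept as an ordinary token of the
#'   64-letter codon alphabet.
#' @return Character vector of consecutive non-overlapping codon triplets.
#' @examples
#' toCodonSequence("ATGGCTTAA")
#' @export
toCodonSequence <- function(orf_seq) {
  assertScalarString(orf_seq, "orf_seq")
  orf <- toupper(orf_seq)
  if (grepl("[^ACGT]", orf)) stop("orf_seq contains non-ACGT characters")
  if (nchar(orf) %% 3L != 0L)
    stop("orf length (", nchar(orf), ") not divisible by 3")
  substring(orf, seq(1L, nchar(orf) - 2L, by = 3L), seq(3L, nchar(orf), by = 3L))
}

#' Extract the residues in given structural states
#'
#' Selects, in original order, the residues of a mature sequence whose
#' per-residue state (buried/exposed or helix/strand/coil) belongs to
#' `keep`.
#'
#' @param mature Amino-acid string.
#' @param states State string of identical length.
#' @param keep Character vector of state symbols to retain.
#' @return Amino-acid string (possibly empty).
#' @examples
#' stateSubsequence("AVDA", "BEBE", "E")   # "VA"
#' @export
stateSubsequence <- function(mature, states, keep) {
  assertScalarString(mature, "mature")
  assertScalarString(states, "states")
  if (nchar(mature) != nchar(states))
    stop("mature (", nchar(mature), ") and states (", nchar(states),
         ") lengths differ")
  st <- chars(states)
  paste(chars(mature)[st %in% keep], collapse = "")
}

#' Randomized structural-control subsequence
#'
#' Draws `length` residues from the positions of `full_seq` uniformly at
#' random without replacement. Used as a control: a structural subsequence
#' is compared to a random subsequence of the same length to test whether
#' its amino-acid content (rather than its length alone) is informative.
#'
#' @param full_seq Amino-acid string to sample from.
#' @param length Number of residues to draw (0..nchar(full_seq)).
#' @param seed Integer seed; the same seed yields the same subsequence.
#' @return Amino-acid string of the requested length.
#' @examples
#' randomizedSubsequence("ACDEFGHIKL", 4, seed = 7)
#' @export
randomizedSubsequence <- function(full_seq, length, seed) {
  assertScalarString(full_seq, "full_seq")
  n <- nchar(full_seq)
  length <- as.integer(length)
  if (length < 0L || length > n)
    stop("length must be in [0, ", n, "], got ", length)
  if (length == 0L) return("")
  withSeed(seed, paste(chars(full_seq)[sample.int(n, length)], collapse = ""))
}

#' Derive a sequence representation for every record
#'
#' Builds one of the sequence representations used throughout the package:
#' the ORF codon token sequence, the signal-peptide or mature amino-acid
#' sequence, the solvent-accessibility (B/E) or secondary-structure (H/E/C)
#' state string, the buried/exposed/helix/strand/coil amino-acid
#' subsequences of the mature sequence, or length-matched randomized
#' controls of the structural subsequences (drawn from the mature
#' sequence).
#'
#' @param set A [SecretionSet-class]; structural annotations are required
#'   for all kinds except `"orf_codons"`, and ORFs for `"orf_codons"`.
#' @param kind One of `"orf_codons"`, `"signal_peptide"`, `"mature"`,
#'   `"acc_string"`, `"buried"`, `"exposed"`, `"ss_string"`, `"helix"`,
#'   `"strand"`, `"coil"`, `"buried_rand"`, `"exposed_rand"`,
#'   `"helix_rand"`, `"strand_rand"`, `"coil_rand"`.
#' @param seed Integer seed for the randomized kinds; each record's draw is
#'   seeded deterministically from `(seed, id, kind)` so representations
#'   are reproducible record by record.
#' @return For `"orf_codons"` a named list of codon-token vectors,
#'   otherwise a named character vector of sequences.
#' @examples
#' ss <- generateProteins(2, 2, effectConfig(), seed = 1)
#' substr(representationOf(ss, "mature")[1], 1, 10)
#' @export
representationOf <- function(set, kind, seed = 1L) {
  stopifnot(is(set, "SecretionSet"))
  kind <- match.arg(kind, REPRESENTATION_KINDS)
  ids <- names(set)
  seqs <- as.character(proteins(set))
  if (kind == "orf_codons") {
    if (length(orfs(set)) == 0L) stop("ORFs required for kind 'orf_codons'")
    return(setNames(lapply(as.character(orfs(set)), toCodonSequence), ids))
  }
  if (!hasAnnotation(set))
    stop("structural annotations required for kind '", kind, "'")
  ann <- annotations(set)
  out <- vapply(seq_along(ids), function(i) {
    parts <- splitSignalPeptide(seqs[i], ann$cleavage_pos[i])
    mat <- parts$mature
    switch(kind,
      signal_peptide = parts$signal_peptide,
      mature = mat,
      acc_string = ann$acc_states[i],
      ss_string = ann$ss_states[i],
      buried  = stateSubsequence(mat, ann$acc_states[i], "B"),
      exposed = stateSubsequence(mat, ann$acc_states[i], "E"),
      helix   = stateSubsequence(mat, ann$ss_states[i], "H"),
      strand  = stateSubsequence(mat, ann$ss_states[i], "E"),
      coil    = stateSubsequence(mat, ann$ss_states[i], "C"),
      buried_rand = randomizedSubsequence(mat,
        nchar(stateSubsequence(mat, ann$acc_states[i], "B")),
        deriveSeed(seed, paste0(ids[i], ":buried_rand"))),
      exposed_rand = randomizedSubsequence(mat,
        nchar(stateSubsequence(mat, ann$acc_states[i], "E")),
        deriveSeed(seed, paste0(ids[i], ":exposed_rand"))),
      helix_rand = randomizedSubsequence(mat,
        nchar(stateSubsequence(mat, ann$ss_states[i], "H")),
        deriveSeed(seed, paste0(ids[i], ":helix_rand"))),
      strand_rand = randomizedSubsequence(mat,
        nchar(stateSubsequence(mat, ann$ss_states[i], "E")),
        deriveSeed(seed, paste0(ids[i], ":strand_rand"))),
      coil_rand = randomizedSubsequence(mat,
        nchar(stateSubsequence(mat, ann$ss_states[i], "C")),
        deriveSeed(seed, paste0(ids[i], ":coil_rand"))))
  }, "")
  setNames(out, ids)
}
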
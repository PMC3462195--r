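# Average amino-acid composition of natural proteins (UniProt-scale
# background), alphabetical order; used as the generator's base.
naturalComposition <- function() {
  v <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  v / sum(v)
}

# Hydrophobic-rich composition for signal peptides (alanine/leucine heavy
# h-region flavour).
signalPeptideComposition <- function() {
  v <- c(A = 16, C = 2, D = 1, E = 1, F = 6, G = 7, H = 1.5, I = 6,
         K = 2.5, L = 22, M = 3, N = 1.5, P = 3, Q = 2, R = 2.5, S = 9,
         T = 6, V = 10, W = 2, Y = 2)
  v / sum(v)
}

#' Synthetic-dataset effect configuration
#'
#' Defines the generative conditions for labelled synthetic secreted
#' proteins: a background amino-acid composition, signed per-letter
#' composition shifts applied to the positive class (the defaults plant
#' the tyrosine/asparagine enrichment and lysine/methionine depletion that
#' the classifier is expected to recover), class-dependent N-glycosylation
#' sequon rates, length ranges, structural-state frequencies, and codon
#' bias for back-translation.
#'
#' @param base_composition Named fractions over the 20 amino acids,
#'   summing to 1. Default: average natural protein composition.
#' @param delta Named signed shifts added to the positive-class
#'   composition (then clipped at 0 and renormalized). Default
#'   `c(Y = 0.03, N = 0.02, K = -0.03, M = -0.01)`.
#' @param sequon_rate_pos,sequon_rate_neg Expected planted sequons per 100
#'   mature residues for positives / negatives. Defaults 1.2 and 0.5
#'   (about 4.8 vs 2.0 sequons on a 400-residue protein).
#' @param length_range Integer bounds on mature-sequence length (uniform).
#'   Default c(200, 600).
#' @param sp_length_range Integer bounds on signal-peptide length.
#'   Default c(15, 30).
#' @param acc_freq Named frequencies of buried/exposed states,
#'   `c(B = , E = )`. Default c(0.45, 0.55).
#' @param ss_freq Named frequencies of helix/strand/coil states,
#'   `c(H = , E = , C = )`. Default c(0.30, 0.20, 0.50).
#' @param codon_bias Optional named per-codon weights for
#'   [backTranslate()]; `NULL` = uniform within each family.
#' @return A list of class `EffectConfig`.
#' @export
effectConfig <- function(base_composition = naturalComposition(),
                         delta = c(Y = 0.03, N = 0.02, K = -0.03, M = -0.01),
                         sequon_rate_pos = 1.2, sequon_rate_neg = 0.5,
                         length_range = c(200L, 600L),
                         sp_length_range = c(15L, 30L),
                         acc_freq = c(B = 0.45, E = 0.55),
                         ss_freq = c(H = 0.30, E = 0.20, C = 0.50),
                         codon_bias = NULL) {
  stopifnot(setequal(names(base_composition), AA20),
            abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition >= 0),
            sequon_rate_pos >= 0, sequon_rate_neg >= 0,
            length_range[1] >= 10, length_range[2] >= length_range[1],
            sp_length_range[1] >= 5,
            sp_length_range[2] >= sp_length_range[1])
  if (length(delta) && is.null(names(delta)))
    stop("delta must be named by amino acid")
  shifted <- base_composition[AA20]
  shifted[names(delta)] <- shifted[names(delta)] + delta
  if (any(shifted < 0))
    stop("delta drives a composition entry negative")
  structure(list(base_composition = base_composition[AA20],
                 pos_composition = shifted / sum(shifted),
                 delta = delta,
                 sequon_rate_pos = sequon_rate_pos,
                 sequon_rate_neg = sequon_rate_neg,
                 length_range = as.integer(length_range),
                 sp_length_range = as.integer(sp_length_range),
                 acc_freq = acc_freq, ss_freq = ss_freq,
                 codon_bias = codon_bias),
            class = "EffectConfig")
}

# Sample one sequence of iid residues from a composition.
sampleResidues <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# Replace the asparagine of every accidental sequon so the only sequons
# in the output are the deliberately planted ones (keeps the configured
# class rates interpretable as total sequon rates).
scrubSequons <- function(seq, comp) {
  nonN <- comp[setdiff(names(comp), "N")]
  nonN <- nonN / sum(nonN)
  for (pass in 1:6) {
    m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
    if (m[1L] == -1L) break
    ch <- chars(seq)
    ch[as.integer(m)] <- sample(names(nonN), length(m), replace = TRUE,
                                prob = nonN)
    seq <- paste(ch, collapse = "")
  }
  seq
}

# Overwrite non-overlapping random triplets with N-x-[S/T] sequons.
plantSequons <- function(mature, n_sequons, comp) {
  L <- nchar(mature)
  mature <- scrubSequons(mature, comp)
  if (n_sequons == 0L || L < 3L) return(mature)
  ch <- chars(mature)
  taken <- logical(L)
  placed <- 0L
  starts <- sample.int(L - 2L)
  mid <- comp[setdiff(names(comp), c("P", "N"))]
  for (s in starts) {
    if (placed >= n_sequons) break
    if (any(taken[s:(s + 2L)])) next
    ch[s] <- "N"
    ch[s + 1L] <- sample(names(mid), 1L, prob = mid)
    ch[s + 2L] <- sample(c("S", "T"), 1L)
    taken[s:(s + 2L)] <- TRUE
    placed <- placed + 1L
  }
  paste(ch, collapse = "")
}

#' Back-translate a protein into an ORF
#'
#' Emits, for every residue, a codon sampled from its synonymous family
#' according to `codon_bias` (uniform within the family when `NULL`), and
#' appends a stop codon, so that [validateOrf()] accepts the result for
#' proteins starting with methionine.
#'
#' @param protein_seq Amino-acid string.
#' @param codon_bias Optional named per-codon weights; families whose
#'   total weight is zero raise an error.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return DNA string of length `3 * (nchar(protein_seq) + 1)`.
#' @examples
#' backTranslate("MAW", seed = 1)
#' @export
backTranslate <- function(protein_seq, codon_bias = NULL, seed = NULL) {
  assertScalarString(protein_seq, "protein_seq")
  aa <- chars(toupper(protein_seq))
  bad <- setdiff(unique(aa), AA20)
  if (length(bad)) stop("invalid amino acid(s): ", paste(bad, collapse = ", "))
  famWeights <- function(letter) {
    fam <- AA2CODONS[[letter]]
    # unspecified codons keep weight 1, so partial bias tables work
    wts <- if (is.null(codon_bias)) rep(1, length(fam))
           else { w <- codon_bias[fam]; w[is.na(w)] <- 1; as.numeric(w) }
    if (sum(wts) <= 0)
      stop("zero-probability codon family for ", letter)
    list(fam = fam, wts = wts)
  }
  withSeed(seed, {
    cod <- character(length(aa))
    for (letter in sort(unique(aa))) {     # vectorized draw per residue type
      fw <- famWeights(letter)
      idx <- which(aa == letter)
      cod[idx] <- if (length(fw$fam) == 1L) fw$fam
                  else sample(fw$fam, length(idx), replace = TRUE, prob = fw$wts)
    }
    fw <- famWeights("*")
    stop_codon <- sample(fw$fam, 1L, prob = fw$wts)
    paste(c(cod, stop_codon), collapse = "")
  })
}

#' Generate a labelled synthetic secreted-protein dataset
#'
#' Draws positive and negative proteins with i.i.d. residues from
#' class-specific compositions, plants N-glycosylation sequons at the
#' class rate (accidental background sequons are scrubbed, then
#' non-overlapping random triplets are overwritten, so the configured rate
#' is the total sequon rate), prefixes a
#' hydrophobic-rich signal peptide starting with methionine, attaches
#' structural annotations with configurable buried/exposed and
#' helix/strand/coil state frequencies, and back-translates every protein
#' into a valid ORF. The same seed reproduces the dataset exactly.
#'
#' @param n_pos,n_neg Number of positive / negative records (>= 1).
#' @param config An [effectConfig()].
#' @param seed Integer seed.
#' @return A [SecretionSet-class] with labels, ORFs and annotations.
#' @examples
#' ss <- generateProteins(5, 5, effectConfig(), seed = 42)
#' table(labels(ss))
#' @export
generateProteins <- function(n_pos, n_neg, config = effectConfig(), seed = 1L) {
  stopifnot(inherits(config, "EffectConfig"), n_pos >= 1L, n_neg >= 1L)
  n <- n_pos + n_neg
  ids <- c(sprintf("pos%04d", seq_len(n_pos)), sprintf("neg%04d", seq_len(n_neg)))
  labs <- c(rep(1L, n_pos), rep(-1L, n_neg))
  withSeed(seed, {
    prot <- character(n); orf <- character(n)
    sp_len <- integer(n); acc <- character(n); ss <- character(n)
    for (i in seq_len(n)) {
      pos <- labs[i] > 0L
      comp <- if (pos) config$pos_composition else config$base_composition
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      mature <- sampleResidues(L, comp)
      rate <- if (pos) config$sequon_rate_pos else config$sequon_rate_neg
      mature <- plantSequons(mature, rpois(1L, rate * L / 100), comp)
      S <- sample(seq(config$sp_length_range[1], config$sp_length_range[2]), 1L)
      sp <- paste0("M", sampleResidues(S - 1L, signalPeptideComposition()))
      full <- paste0(sp, mature)
      # avoid an accidental C-terminal ER-retention signal
      if (grepl("[HK]DEL$", full)) {
        substr(full, nchar(full), nchar(full)) <- "G"
        mature <- substr(full, S + 1L, nchar(full))
      }
      prot[i] <- full
      orf[i] <- backTranslate(full, config$codon_bias)
      sp_len[i] <- S
      acc[i] <- paste(sample(names(config$acc_freq), L, replace = TRUE,
                             prob = config$acc_freq), collapse = "")
      ss[i] <- paste(sample(names(config$ss_freq), L, replace = TRUE,
                            prob = config$ss_freq), collapse = "")
    }
    ann <- data.frame(sp_flag = rep(TRUE, n), cleavage_pos = sp_len,
                      tm_flag = rep(FALSE, n), acc_states = acc,
                      ss_states = ss, row.names = ids,
                      stringsAsFactors = FALSE)
    SecretionSet(setNames(prot, ids), orfs = setNames(orf, ids),
                 label = labs, organism = "synthetic", annotation = ann)
  })
}
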
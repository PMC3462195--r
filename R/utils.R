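# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards (package functions never clobber the global stream).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic sub-seed for (seed, string key): a polynomial string hash
# folded into [0, 2^31 - 2]. Stable across sessions and platforms.
deriveSeed <- function(seed, key) {
  m <- 2147483629
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h)
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty string", call. = FALSE)
}

# Genetic-code helpers --------------------------------------------------

codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Codon -> amino acid map with stops as "*".
CODON2AA <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

# Synonymous families: list amino acid -> codons.
AA2CODONS <- local({
  split(names(CODON2AA), CODON2AA)
})

# The 59 codons belonging to multi-codon synonymous families (excludes the
# single-codon families ATG/Met and TGG/Trp, and the three stop codons).
MULTIFAM_CODONS <- local({
  fams <- AA2CODONS[setdiff(names(AA2CODONS), "*")]
  sort(unlist(fams[vapply(fams, length, 1L) > 1L], use.names = FALSE))
})
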
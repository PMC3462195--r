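test_that("validateOrf checks alphabet, length, stop codon and translation", {
  expect_true(validateOrf("MA", "ATGGCTTAA")$valid)
  expect_true(validateOrf("MA", "atggcttaa")$valid)

  r <- validateOrf("MA", "ATGGCT")
  expect_false(r$valid)
  expect_equal(r$reasons, "length")

  r <- validateOrf("MV", "ATGGCTTAA")
  expect_false(r$valid)
  expect_equal(r$reasons, "translation")

  r <- validateOrf("MA", "ATGGCXTAA")
  expect_false(r$valid)
  expect_true("alphabet" %in% r$reasons)

  # right length, last codon not a stop
  r <- validateOrf("MAA", "ATGGCTGCTGCT")
  expect_false(r$valid)
  expect_true("stop" %in% r$reasons)

  expect_error(validateOrf("", "ATG"), "protein_seq")
})

toyFilterSet <- function() {
  base <- paste(rep("ACDEFGHIKL", 15), collapse = "")  # length 150
  seqs <- c(
    nosp  = base,
    short = substr(base, 1, 90),
    kdel  = paste0(substr(base, 1, 146), "KDEL"),
    tm    = base,
    ok    = base,
    inner = paste0(substr(base, 1, 100), "KDELG",
                   substr(base, 106, 150)))
  ann <- data.frame(
    sp_flag = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    cleavage_pos = rep(20L, 6),
    tm_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    acc_states = vapply(nchar(seqs) - 20L, function(n)
      paste(rep("B", n), collapse = ""), ""),
    ss_states = vapply(nchar(seqs) - 20L, function(n)
      paste(rep("C", n), collapse = ""), ""),
    row.names = names(seqs))
  SecretionSet(seqs, label = c(1, 1, -1, -1, 1, -1), annotation = ann)
}

test_that("applyFilters drops records for the documented reasons", {
  res <- applyFilters(toyFilterSet(), filterConfig())
  expect_setequal(names(res$retained), c("ok", "inner"))
  expect_equal(nrow(res$exclusions), 4L)
  reasons <- setNames(res$exclusions$reason, res$exclusions$id)
  expect_match(reasons[["nosp"]], "no_signal_peptide")
  expect_match(reasons[["short"]], "too_short")
  expect_match(reasons[["kdel"]], "er_retention")
  expect_match(reasons[["tm"]], "transmembrane")
  # HDEL suffix is dropped just like KDEL
  hdel <- sub("KDEL$", "HDEL", as.character(proteins(toyFilterSet()))[["kdel"]])
  ann <- annotations(toyFilterSet())["kdel", , drop = FALSE]
  rownames(ann) <- "hdel"
  s3 <- SecretionSet(c(hdel = hdel), label = -1, annotation = ann)
  expect_match(applyFilters(s3)$exclusions$reason, "er_retention")
  # retained + excluded partitions the input
  expect_equal(length(res$retained) + nrow(res$exclusions),
               length(toyFilterSet()))
})

test_that("applyFilters errors without annotations", {
  ss <- SecretionSet(c(a = paste(rep("ACDEFGHIKL", 15), collapse = "")))
  expect_error(applyFilters(ss), "annotation")
})

test_that("pairwiseIdentity agrees with a dynamic-programming oracle", {
  r <- pairwiseIdentity("PEPTIDE", "PEPTIDE")
  expect_equal(r$identity, 1)
  expect_equal(unname(r$coverage), c(1, 1))

  expect_equal(pairwiseIdentity("AAAA", "TTTT")$identity, 0)

  # the optimal local alignment of A10 vs A9T excludes the trailing
  # mismatch: 9 matched columns, 9/10 coverage of both sequences
  a <- strrep("A", 10); b <- paste0(strrep("A", 9), "T")
  o <- swOracle(a, b)
  r <- pairwiseIdentity(a, b)
  expect_equal(r$identity, o$identity)
  expect_equal(r$identity, 1)
  expect_equal(unname(r$coverage), unname(o$coverage))
  expect_equal(unname(r$coverage), c(0.9, 0.9))

  # random pairs match the oracle
  set.seed(42)
  for (i in 1:5) {
    x <- paste(sample(c("A", "C", "D", "E"), 30, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "D", "E"), 25, TRUE), collapse = "")
    expect_equal(pairwiseIdentity(x, y)$identity, swOracle(x, y)$identity,
                 tolerance = 1e-12)
  }
  expect_error(pairwiseIdentity("", "AA"), "seq_a")
})

chainSet <- function() {
  set.seed(7)
  base <- paste(sample(setdiff(hiSecPred:::AA20, "W"), 50, TRUE), collapse = "")
  mutate <- function(s, at) {
    ch <- strsplit(s, "")[[1]]; ch[at] <- "W"; paste(ch, collapse = "")
  }
  SecretionSet(c(a = mutate(base, 10:14), b = base, c = mutate(base, 36:40)),
               label = c(1, 1, 1))
}

test_that("reduceRedundancy keeps cluster representatives", {
  # two identical positives -> one representative
  ss <- SecretionSet(c(x = strrep("MKTAYIAKQR", 5), y = strrep("MKTAYIAKQR", 5)),
                     label = c(1, 1))
  expect_equal(length(reduceRedundancy(ss)$retained), 1L)

  # identical positive + negative -> both retained
  ss2 <- SecretionSet(c(x = strrep("MKTAYIAKQR", 5), y = strrep("MKTAYIAKQR", 5)),
                      label = c(1, -1))
  expect_equal(length(reduceRedundancy(ss2)$retained), 2L)

  # single-linkage chain a-b, b-c redundant, a-c not: b is the member
  # with minimal average distance and is the lone representative
  cfg <- filterConfig(identity_threshold = 0.85, coverage_threshold = 0.85)
  ss3 <- chainSet()
  idm <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
    pairwiseIdentity(as.character(proteins(ss3))[i],
                     as.character(proteins(ss3))[j], cfg)$identity))
  # brute-force average distance per member over the full cluster
  avg <- sapply(1:3, function(i) mean(1 - idm[i, -i]))
  expect_equal(which.min(avg), 2L)  # b
  red <- reduceRedundancy(ss3, cfg)
  expect_equal(length(red$clusters), 1L)
  expect_equal(names(red$retained), "b")
})

test_that("reduceRedundancy output is irredundant and idempotent", {
  set.seed(3)
  mk <- function() paste(sample(hiSecPred:::AA20, 40, TRUE), collapse = "")
  seqs <- c(replicate(4, mk()), NA)
  seqs[5] <- seqs[1]                      # plant one duplicate
  names(seqs) <- paste0("s", 1:5)
  ss <- SecretionSet(seqs, label = rep(1, 5))
  cfg <- filterConfig()
  r1 <- reduceRedundancy(ss, cfg)
  # recompute all pairs: no same-label retained pair may be redundant
  kept <- as.character(proteins(r1$retained))
  if (length(kept) > 1)
    for (i in 1:(length(kept) - 1)) for (j in (i + 1):length(kept)) {
      pi <- pairwiseIdentity(kept[i], kept[j], cfg)
      expect_false(pi$identity >= cfg$identity_threshold &&
                   max(pi$coverage) >= cfg$coverage_threshold)
    }
  r2 <- reduceRedundancy(r1$retained, cfg)
  expect_identical(names(r2$retained), names(r1$retained))
})

test_that("crossSetReduce removes only train-redundant test records", {
  set.seed(9)
  mk <- function() paste(sample(hiSecPred:::AA20, 40, TRUE), collapse = "")
  tr <- SecretionSet(setNames(replicate(3, mk()), paste0("t", 1:3)))
  dup <- as.character(proteins(tr))[1]
  te <- SecretionSet(setNames(c(dup, mk(), mk()), paste0("q", 1:3)))
  red <- crossSetReduce(te, tr)
  expect_setequal(names(red), c("q2", "q3"))
  # empty train set leaves the test set unchanged
  expect_identical(names(crossSetReduce(te, NULL)), names(te))
  # no remaining pair meets the redundancy criterion (verified directly)
  cfg <- filterConfig()
  ok <- all(outer(as.character(proteins(te[2:3])), as.character(proteins(tr)),
                  Vectorize(function(a, b) {
                    pi <- pairwiseIdentity(a, b, cfg)
                    pi$identity >= cfg$identity_threshold &&
                      max(pi$coverage) >= cfg$coverage_threshold
                  })) == FALSE)
  expect_true(ok)
  expect_identical(names(crossSetReduce(te[2:3], tr)), c("q2", "q3"))
})
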
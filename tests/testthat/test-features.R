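AA <- hiSecPred:::AA20

test_that("composition computes letter fractions over the given alphabet", {
  v <- composition("AAY")
  expect_equal(unname(v[c("A", "Y")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v), 1)
  expect_equal(unname(composition("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  cv <- composition(c("ATG", "GCT", "TAA"), hiSecPred:::CODONS64)
  expect_equal(unname(cv[c("ATG", "GCT", "TAA")]), rep(1 / 3, 3))
  expect_equal(sum(cv), 1)
  expect_error(composition(""), "empty")
  expect_error(composition("AXZ"), "X")
})

test_that("cluster composition matches the predefined physicochemical table", {
  v <- clusterComposition("DE")
  expect_equal(v[["acidic"]], 1)
  expect_equal(v[["charged"]], 1)
  expect_equal(v[["polar"]], 1)
  expect_equal(v[["small"]], 0.5)
  expect_equal(unname(v[c("basic", "aromatic", "hydrophobic", "tiny",
                          "nonpolar", "aliphatic", "polar_uncharged")]),
               rep(0, 7))
  # a cluster covering the whole alphabet always gives 1
  expect_equal(unname(clusterComposition("MKYW", AAClusters(list(AA)))), 1)
  # cluster value equals the sum of member composition entries
  set.seed(1)
  s <- paste(sample(AA, 60, TRUE), collapse = "")
  comp <- composition(s)
  for (cl in clusterList(predefinedClusters()))
    expect_equal(unname(clusterComposition(s)[
      which(vapply(clusterList(predefinedClusters()), identical, TRUE, cl))]),
      sum(comp[cl]))
})

test_that("codon usage normalizes within synonymous families", {
  u <- codonUsage(c("ATG", "GCT", "GCC", "TAA"))
  expect_length(u, 59)
  expect_equal(unname(u[c("GCT", "GCC", "GCA", "GCG")]), c(0.5, 0.5, 0, 0))
  # leucine absent -> all six leucine codons zero
  leu <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  expect_equal(unname(u[leu]), rep(0, 6))
  # only single-codon families and stops -> all zero
  expect_equal(sum(codonUsage(c("ATG", "TGG", "TAA"))), 0)
  expect_error(codonUsage(character(0)), "empty")
})

test_that("codon usage family sums equal 1 for amino acids present", {
  ss <- generateProteins(2, 2, effectConfig(), seed = 8)
  cods <- representationOf(ss, "orf_codons")[[1]]
  u <- codonUsage(cods)
  aas <- hiSecPred:::CODON2AA[cods]
  for (aa in setdiff(unique(aas), "*")) {
    fam <- hiSecPred:::AA2CODONS[[aa]]
    if (length(fam) > 1) expect_equal(sum(u[fam]), 1)
  }
})

test_that("reference index and CAI follow the relative-adaptiveness construction", {
  coll <- list(c(rep("GCT", 90), rep("GCC", 10)))
  w <- buildReferenceIndex(coll)
  expect_equal(unname(w[c("GCT", "GCC", "GCA", "GCG")]),
               c(1, 1 / 9, 0.01, 0.01))
  # uniform counts -> w = 1 everywhere in the family
  wu <- buildReferenceIndex(list(c("GCT", "GCC", "GCA", "GCG")))
  expect_equal(unname(wu[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
  w1 <- buildReferenceIndex(list(c("ATG", "GCT", "TAA")))
  expect_equal(w1[["GCT"]], 1)

  # CAI: geometric mean over eligible codons only
  wAll1 <- setNames(rep(1, 59), hiSecPred:::MULTIFAM_CODONS)
  expect_equal(codonAdaptationIndex(c("ATG", "GCT", "AAA", "TAA"), wAll1), 1)
  wHalf <- wAll1; wHalf["GCC"] <- 0.25
  expect_equal(codonAdaptationIndex(c("GCT", "GCC"), wHalf), 0.5)
  expect_error(codonAdaptationIndex(c("ATG", "TAA"), wAll1), "CAI undefined")
  # permutation invariance
  set.seed(2)
  cods <- sample(hiSecPred:::MULTIFAM_CODONS, 30, TRUE)
  wr <- setNames(runif(59, 0.1, 1), hiSecPred:::MULTIFAM_CODONS)
  expect_equal(codonAdaptationIndex(cods, wr),
               codonAdaptationIndex(sample(cods), wr))
})

test_that("isoelectric point is a root of the charge curve", {
  # two ionizable groups only: pI is the midpoint of the terminal pKas
  pka <- hiSecPred:::bjellqvistPKa()
  expect_equal(isoelectricPoint("GG"),
               (pka$positive[["Nterm"]] + pka$negative[["Cterm"]]) / 2,
               tolerance = 0.01)
  expect_gt(isoelectricPoint("KKKK"), isoelectricPoint("DDDD"))
  expect_gt(isoelectricPoint("KKKK"), 7)
  expect_lt(isoelectricPoint("DDDD"), 7)
})

test_that("kmerCounts counts overlapping windows", {
  expect_equal(kmerCounts("NANAS", 2),
               setNames(c(1L, 1L, 2L), c("AN", "AS", "NA")))
  expect_equal(kmerCounts("AAAA", 3), c(AAA = 2L))
  s <- "MKYWAVDA"
  k1 <- kmerCounts(s, 1)
  expect_equal(as.numeric(k1), unname(composition(s)[names(k1)] * nchar(s)))
  expect_warning(k <- kmerCounts("AB", 3), "exceeds")
  expect_length(k, 0)
})

test_that("spectrum kernel equals brute-force k-mer inner products", {
  K <- spectrumKernelMatrix(c(a = "AAA", b = "AAB"), 2)
  expect_equal(K["a", "b"], 2)          # shared AA k-mer: 2 x 1
  expect_equal(K["a", "a"], 4)          # 2^2
  set.seed(6)
  seqs <- vapply(1:10, function(i)
    paste(sample(AA[1:5], 30, TRUE), collapse = ""), "")
  for (k in 2:3) {
    Kf <- spectrumKernelMatrix(seqs, k)
    Kb <- bruteSpectrumKernel(seqs, k)
    expect_equal(unname(Kf), Kb)
    expect_true(isSymmetric(Kf))
    expect_true(all(eigen(Kf, only.values = TRUE)$values > -1e-8))
  }
  expect_error(spectrumKernelMatrix(c(x = "ABCD", y = "AB"), 3), "y")
})

test_that("ttestPrefilter selects class-separated columns by Welch t-test", {
  set.seed(4)
  n <- 50
  y <- rep(c(1, -1), each = n)
  X <- cbind(strong = c(rnorm(n, 10), rnorm(n, 0)),
             flat = rnorm(2 * n),
             const = rep(1, 2 * n))
  out <- ttestPrefilter(X, y, alpha = 0.05)
  expect_true("strong" %in% out$feature)
  expect_false("const" %in% out$feature)
  expect_equal(out$feature[1], "strong")   # sorted by |t|
  all_out <- ttestPrefilter(X, y, alpha = 1)
  expect_setequal(all_out$feature, c("strong", "flat"))  # const never selected
  # cross-check against stats::t.test
  tt <- t.test(X[y > 0, "strong"], X[y < 0, "strong"])
  expect_equal(out$t[out$feature == "strong"], unname(tt$statistic),
               tolerance = 1e-10)
  expect_error(ttestPrefilter(X, rep(1, 2 * n)), "both classes")
})

toyRecord <- function() {
  ann <- data.frame(sp_flag = TRUE, cleavage_pos = 3L, tm_flag = FALSE,
                    acc_states = "BEBE", ss_states = "HHEC",
                    row.names = "t1")
  SecretionSet(c(t1 = "MKKAVDA"), orfs = c(t1 = "ATGAAAAAAGCTGTTGATGCTTAA"),
               label = 1, annotation = ann)
}

test_that("assembleFeatures produces the documented columns", {
  ss <- toyRecord()
  f2 <- assembleFeatures(ss, "f2")
  expect_equal(ncol(f2), 20)
  expect_equal(unname(f2[1, c("comp:A", "comp:V", "comp:D")]),
               c(0.5, 0.25, 0.25))
  expect_equal(ncol(assembleFeatures(ss, "f10")), 11)
  expect_equal(colnames(assembleFeatures(ss, "f13")),
               c("sp_length", "protein_length", "cai", "pI"))
  expect_equal(ncol(assembleFeatures(ss, "f0")), 64)
  expect_equal(ncol(assembleFeatures(ss, "f3")), 2)
  expect_equal(ncol(assembleFeatures(ss, "f6")), 3)
  expect_equal(ncol(assembleFeatures(ss, "f12")), 59)
  expect_error(assembleFeatures(SecretionSet(c(a = "MKY")), "f0"), "ORF")
})

test_that("feature-set invariants hold on generated data", {
  ss <- generateProteins(5, 5, effectConfig(), seed = 13)
  for (fs in c("f0", "f1", "f2")) {
    X <- assembleFeatures(ss, fs)
    expect_equal(unname(rowSums(X)), rep(1, 10), tolerance = 1e-12)
  }
  # cluster columns are sums of the matching composition columns
  X2 <- assembleFeatures(ss, "f2")
  X10 <- assembleFeatures(ss, "f10")
  for (nm in names(clusterList(predefinedClusters()))) {
    members <- clusterList(predefinedClusters())[[nm]]
    expect_equal(unname(X10[, paste0("cluster:", nm)]),
                 unname(rowSums(X2[, paste0("comp:", members), drop = FALSE])))
  }
  # the selection pool stacks exactly 124 uniquely named columns
  pool <- selectionPool(ss)
  expect_equal(ncol(pool), 124)
  expect_false(anyDuplicated(colnames(pool)) > 0)
})

test_that("empty structural subsequences give zero rows with a warning", {
  ann <- data.frame(sp_flag = TRUE, cleavage_pos = 3L, tm_flag = FALSE,
                    acc_states = "BBBB", ss_states = "CCCC",
                    row.names = "t1")
  ss <- SecretionSet(c(t1 = "MKKAVDA"), label = 1, annotation = ann)
  expect_warning(X <- assembleFeatures(ss, "f5"), "empty")
  expect_equal(unname(rowSums(X)), 0)
})
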
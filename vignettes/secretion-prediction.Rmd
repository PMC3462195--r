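---
title: "Predicting high-level protein secretion from sequence: methods and design"
author: "hiSecPred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting high-level protein secretion from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

hiSecPred implements a sequence-based analysis of which protein and codon
features predict successful high-level production of secreted proteins in
*Aspergillus niger*. The pipeline has five stages: dataset construction
(validation, filtering, redundancy reduction), sequence representations,
feature extraction, linear-SVM classification with nested cross-validation
and interpretation, and fixed-pattern motif analysis. A synthetic-data
generator stands in for the proprietary screening datasets so that every
stage is exercisable and testable from code.

This vignette explains the models and the design decisions; the README
shows a worked example. No number quoted here goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

# Dataset construction

## Input contract

A dataset (`SecretionSet`) holds uppercase 20-letter protein sequences
with unique ids, optional ORFs, production labels (+1 successful, −1
unsuccessful, NA unknown), organism tags, and per-record structural
annotations. Annotations are *inputs*, standing in for upstream predictor
output: a signal-peptide flag and cleavage position (1-based signal
peptide length, so the mature sequence is residues `cleavage_pos + 1`
onward), a transmembrane flag, and per-residue buried/exposed (B/E) and
helix/strand/coil (H/E/C) state strings covering the mature sequence. The
package never runs structure predictors itself.

`validateOrf()` accepts an ORF iff it spans start codon through stop
codon: length `3·(protein length + 1)`, leading ATG, trailing
TAA/TAG/TGA, and standard-genetic-code translation equal to the protein.
Reason codes distinguish `alphabet`, `length`, `stop` and `translation`
failures; `stop` was added because a length-consistent ORF whose final
codon is not a stop is neither a length nor a translation problem.

## Filters

`applyFilters()` retains records that (i) carry a predicted signal
peptide, (ii) are longer than `min_length` residues (default 100,
strictly greater), (iii) do not end in the C-terminal ER-retention signal
HDEL/KDEL (an exact suffix match — an internal `KDELG` is not a retention
signal), and (iv) are not flagged transmembrane. Each dropped record gets
all applicable reasons, and retained + excluded always partitions the
input.

## Redundancy reduction

Near-identical sequences inflate cross-validation estimates, so the
dataset is reduced to cluster representatives. Two sequences are
*redundant* when an optimal local (Smith–Waterman) alignment under fixed
scoring — match +1, mismatch −1, linear gap −2, recorded in
`filterConfig()` — has identity (matches / alignment columns) at or above
`identity_threshold` with at least `coverage_threshold` of one of the two
sequences inside the aligned span. Redundant pairs are single-linkage
clustered; per cluster the member with the smallest mean `1 − identity`
to the other members is kept, ties broken by lexicographic id for
determinism. A cluster mixing labels keeps one representative per label
(chosen within the label subgroup), because a positive and a negative
observation of near-identical sequences are two genuinely different
data points; consequently the no-redundant-pair guarantee holds among
same-label pairs only. `crossSetReduce()` applies the same criterion
between a test and a training set, dropping only test records.

Design notes. The identity/coverage thresholds default to 0.8/0.8; they
are deliberate configuration parameters rather than fixed constants
because reasonable clustering stringencies vary by application. Identity
is computed over the local-alignment span, which matches how
alignment-based clustering tools score pairs; a consequence worth knowing
is that terminal mismatches are trimmed away (aligning `AAAAAAAAAA` with
`AAAAAAAAAT` gives identity 1.0 over 9 columns at coverage 0.9, not 0.9
over 10 columns), so coverage, not identity, is what penalizes length
differences.

# Representations

Ten representations are derived per record: the ORF codon token sequence
(64-letter alphabet, stop codon included as a token); the signal-peptide
and mature amino-acid sequences; the B/E and H/E/C state strings; and the
buried, exposed, helix, strand and coil amino-acid subsequences of the
mature sequence (order-preserving selections, so buried + exposed
reassembles the mature sequence exactly).

Each structural subsequence has a *randomized control*: a draw of the
same number of residues from the mature sequence, uniformly at random
without replacement. Comparing a structural feature set with its control
asks whether the structural *content* is informative or only the
subsequence *length*. Sampling without replacement keeps the letter
multiset a true subset of the source (a with-replacement draw would
inflate composition variance). Controls are drawn from the mature
sequence — not the full protein — because the structural states are
defined on the mature sequence. Each record's draw is seeded
deterministically from `(seed, record id, representation)`, so controls
are reproducible record by record regardless of evaluation order.

# Feature sets

All composition features are fractions in [0, 1] summing to 1 over their
alphabet; this is also why feature standardization is off by default (an
optional concern the SVM's `C` grid absorbs). The sets:

* **f0** — 64 codon compositions; **f1/f2** — 20 amino-acid compositions
  of signal peptide / mature sequence; **f3** — B/E state composition
  (2 features); **f6** — H/E/C state composition (3).
* **f4/f5, f7–f9** — 20 amino-acid compositions of the structural
  subsequences; **f4r/f5r/f7r–f9r** their randomized controls. An empty
  subsequence (e.g. a protein with no predicted strand) yields a zero
  row plus a warning rather than record exclusion, keeping rows aligned
  across feature sets.
* **f10** — 11 predefined physicochemical cluster compositions (small,
  polar uncharged, aromatic, acidic, charged, basic, hydrophobic, tiny,
  nonpolar, aliphatic, polar). These groups overlap by nature — serine is
  simultaneously small, tiny, polar and polar-uncharged — so the
  `AAClusters` container does not force disjointness; state-dependent
  memberships (cysteine's polarity depends on disulfide bonding) are
  resolved by leaving the amino acid out of the cluster, since
  per-residue states are unknown from sequence.
* **f11** — compositions of data-driven clusters from the greedy
  algorithm (below); these *are* disjoint by construction.
* **f12** — codon usage: for each of the 59 codons in multi-codon
  synonymous families, its count divided by the count of its amino acid;
  family entries sum to 1 when the amino acid occurs and are 0 otherwise.
  ATG, TGG and stops are excluded because usage is uninformative for
  single-codon families — whereas the 64-letter **f0** composition keeps
  stops, reading each definition literally.
* **f13** — four sequence-derived scalars: signal-peptide length
  (residues), protein length (residues), codon adaptation index, and
  isoelectric point.
* **f15–f22** — overlapping k-mer counts (k = 2..5) of the protein and
  the signal peptide, used directly or through the spectrum kernel
  (`spectrumKernelMatrix()`, the inner product of k-mer count vectors).

CAI follows the classical relative-adaptiveness construction: per family,
`w_c = count_c / max family count` over a reference gene set, zero counts
floored at `w = 0.01` so the geometric mean stays finite, and the CAI of
a gene is the geometric mean of `w` over its eligible codons. The
reference defaults to the dataset's own ORFs; an external reference
(e.g. a whole-genome gene set) can be passed instead.

The isoelectric point solves net charge = 0 with Henderson–Hasselbalch
terms for both termini and the D/E/C/Y/H/K/R side chains, using the
Bjellqvist pKa table (the table behind the field's standard pI
calculators), by bisection on pH 0–14 to 1e-4. The pKa table is an
explicit argument so an alternative set can be swapped in.

## The selection pool

The t-test prefilter (`ttestPrefilter()`, Welch two-sample t per column,
keep p < α, default α = 0.05, constant columns get p = 1) feeds greedy
forward selection. Its default pool (`selectionPool()`) stacks
f0 ∪ f1 ∪ f2 ∪ f3 ∪ f6 ∪ f10 ∪ f13 = 64 + 20 + 20 + 2 + 3 + 11 + 4 = 124
uniquely named columns — the union of all composition-scale sets plus the
four scalars, chosen as the natural "everything compositional, nothing
duplicated" pool; it is an argument, not a constant.

# Classification and interpretation

`trainLinearSVM()` fits a soft-margin linear SVM (libsvm via e1071,
features used as-is) and stores the dual form; scores are
`f(x) = Σ α_i y_i ⟨x_i, x⟩ + b`, normalised so positive scores mean the
+1 class regardless of input label order. The primal weight vector
`w = Σ α_i y_i φ(x_i)` must reproduce the kernel-expansion scores to
1e-6 — an invariant the tests enforce on every trained model.

Evaluation uses the Mann–Whitney AUROC (ties counted ½). `nestedCV()`
runs stratified, seeded outer folds; per outer fold, `C` is chosen by an
inner CV loop on the training portion as the *smallest* grid value
achieving the maximal inner mean AUROC (prefer simpler models,
deterministic under ties). The default grid is `10^(-3..3)`: wide enough
to bracket under- and over-regularization for features on a [0, 1]
scale. Stratification and seeding are choices made for reproducibility
on the modest class-balanced datasets this method targets. Feature
standardization, when enabled, uses training-fold statistics only, to
avoid information leakage.

For interpretation, weight vectors are normalized by their maximum
absolute entry (signs preserved), compared across classifiers by Pearson
correlation over name-aligned entries, and optionally correlated with an
external per-amino-acid property (e.g. a user-supplied synthesis-cost
table) over the name intersection with an exclusion list.

`forwardFeatureSelection()` adds, at fixed `C` (default 1, the grid
midpoint, matching the fixed-C shortcut customary inside selection
loops), the candidate maximizing inner-CV AUROC, stopping as soon as the
best achievable score falls *strictly below* the current score; equal
scores continue, ties break by candidate order. The fold assignment is
fixed once per run so step scores are comparable.

# Greedy amino-acid clustering

The data-driven reduced alphabet is built by `greedyAAClustering()`. The
evaluator maps a cluster list to a score; the default
(`makeCVClusterEvaluator()`) scores cluster-composition features by inner
10-fold CV AUROC of a linear SVM at fixed `C`, on a fold assignment fixed
once so all candidate states are scored on identical folds. The search:

1. Start with the single best-scoring amino acid as the first cluster.
2. For each remaining amino acid, evaluate adding it as a new singleton
   cluster and merging it into *each* existing cluster; commit the single
   best placement. ("Each existing cluster" is the only reading
   compatible with multi-cluster outputs.)
3. Repeat until all amino acids are placed; return the best-scoring
   committed state ever observed, so amino acids placed after the peak
   drop out of the result.

Determinism: candidates are evaluated in alphabetical order, new-cluster
before merges, first maximum wins. The trace records every committed
placement with a monotone running best. On alphabets of ≤ 4 letters with
deterministic additive evaluators the tests verify the returned optimum
against exhaustive enumeration of all set-partitions-with-omissions.
Repeated clusterings (e.g. per CV fold) aggregate into a 20×20
co-occurrence matrix (`clusterCooccurrence()`): diagonal = how often an
amino acid was retained at all, off-diagonal = how often two shared a
cluster.

# Motifs

`countNglycSequons()` counts the canonical N-glycosylation acceptor
sequon N-X-[S/T] with X ≠ P, counting overlapping matches (`NNST` has
two); a switch admits the permissive N-X-[S/T] form. The default scope
for class summaries is the full protein sequence with a `mature` option,
since a signal peptide is cleaved before glycosylation but sequon counts
in it are rare either way. `hasErRetention()` is the strict C-terminal
[HK]DEL suffix test used by the dataset filter.

# The synthetic-data generator

`generateProteins()` emulates exactly the statistical structure the
analysis exploits, and nothing more:

* i.i.d. residues from a natural background composition
  (UniProt-scale average), with signed per-letter shifts added for the
  positive class — default Δ(Y) = +0.03, Δ(N) = +0.02, Δ(K) = −0.03,
  Δ(M) = −0.01, the effect directions and magnitudes the classifier is
  expected to recover;
* class-dependent N-glycosylation sequon rates, default 1.2 vs 0.5
  sequons per 100 mature residues (about 4.8 vs 2.0 on a 400-residue
  protein, the positive/negative contrast regime of real screening
  data). Accidental background sequons are scrubbed before planting, so
  the configured rates are *total* rates and directly recoverable by
  `countNglycSequons()`;
* mature lengths uniform on 200–600 residues and signal peptides of
  15–30 residues starting with methionine, drawn from a
  hydrophobic-rich (alanine/leucine-heavy) composition, so every record
  passes the dataset filters by construction;
* annotation state strings drawn i.i.d. with B/E frequencies 0.45/0.55
  and H/E/C frequencies 0.30/0.20/0.50 — label-independent, which is
  what makes the randomized-control comparison meaningful on synthetic
  data;
* ORFs by biased back-translation (uniform within synonymous families by
  default; any per-codon weighting can be supplied), always validating
  against the protein.

The same seed reproduces a dataset byte for byte; every stochastic step
runs inside a restored-RNG scope so package calls never disturb the
caller's random stream.

What the generator does *not* emulate: positional structure beyond
planted sequons, domains, folds, phylogenetic relatedness between
records, organism-specific codon usage, or any coupling between
annotation states and labels. Passing tests therefore demonstrate that
the pipeline recovers the statistical structure it assumes — composition
shifts and sequon-rate differences — not that real secretion data
contains that structure, and AUROCs on synthetic data say nothing
quantitative about AUROCs on screening data.

# Numerical choices and degenerate inputs

* pI bisection tolerance 1e-4 on pH; primal/dual score agreement 1e-6;
  composition row sums exact to 1e-12 in tests.
* Empty structural subsequence → zero feature row + warning (keeps
  matrices aligned). `k > nchar(seq)` → empty k-mer map + warning.
* Constant columns in the t-test prefilter get p = 1 and are never
  selected. Single-class inputs error early and explicitly.
* Representative-selection ties → lexicographic id; C-grid ties →
  smallest C; clustering ties → alphabetical letter, new-cluster first.
* Zero-count reference codons floored at w = 0.01; CAI is an error when
  no codon from a multi-codon family is present.

# Problem sizes

The test suite and the acceptance script run the full pipeline at the
scale the method is designed for: 400-record balanced datasets for
parameter recovery, null calibration over 10 seeded replicates, 50
random sequences for the kernel oracle, and ≤ 4-letter alphabets for the
exhaustive clustering oracle. Unit and property tests use smaller
constructions (tens of records, 5-fold CV) chosen so each property is
sharply testable.

# Limitations

* Structural annotations are consumed, never predicted; garbage states
  in, garbage structural features out.
* The linear SVM is the only classifier, by design — the point is the
  interpretable weight vector, not maximal accuracy; the spectrum kernel
  is the only nonlinearity.
* Redundancy reduction computes all pairwise alignments (quadratic); it
  targets datasets of hundreds to a few thousand sequences, not
  proteome-scale collections.
* The greedy clustering returns one deterministic path; it explores no
  tie alternatives and can miss optima for adversarial evaluators (the
  oracle equivalence is demonstrated for well-behaved additive
  evaluators).
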
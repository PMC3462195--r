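# hiSecPred

Sequence-based prediction of high-level production of secreted proteins in
*Aspergillus niger*.

## The problem

Industrial enzyme production relies on filamentous fungi secreting large
amounts of protein, but when a gene is over-expressed from a standard
cassette, only some proteins ever reach detectable extracellular levels.
Which ones succeed turns out to be partly encoded in the protein and codon
sequence itself. hiSecPred is a toolkit for exploring that signal: it
builds sequence representations and feature sets from labelled
secreted-protein datasets, trains and interprets linear support vector
machine (SVM) classifiers, derives data-driven reduced amino-acid
alphabets, and counts N-glycosylation sequons — the features repeatedly
found to separate high-level producers (tyrosine/asparagine-enriched) from
non-producers (lysine/methionine-enriched).

It is aimed at computational biologists and protein engineers who want to
screen candidate sequences, reproduce the analysis pipeline on their own
expression data, or study which compositional features drive secretion.

## The model

Each protein `x` is mapped to a feature vector `φ(x)` — amino-acid or
codon compositions (`comp_a(x) = count(a, x) / |x|`), physicochemical
cluster compositions, codon usage, codon adaptation index, isoelectric
point, or k-mer spectra. A soft-margin linear SVM scores a candidate as

    f(x) = Σ_i α_i y_i ⟨φ(x_i), φ(x)⟩ + b,

summing over support vectors `x_i` with labels `y_i ∈ {+1, −1}` (+1 =
successful high-level production). Performance is estimated by nested
(double) 10-fold cross-validation with the regularization constant `C`
chosen in the inner loop, measured as the area under the ROC curve
(AUROC). The classifier is interpreted through its explicit weight vector

    w = Σ_i α_i y_i φ(x_i),

whose named entries are per-feature contributions; normalized weight
vectors from different datasets are compared by Pearson correlation. A
greedy clustering algorithm additionally learns reduced amino-acid
alphabets directly from the data: starting from the single most predictive
amino acid, each remaining amino acid is tried as a new cluster or merged
into an existing one, committing the best-scoring placement, and the best
state ever visited is returned.

Because real datasets of this kind are proprietary and the structural
annotations come from external predictors, the package ships a
synthetic-data generator (`generateProteins()`) that emulates the relevant
statistical structure — class-dependent composition shifts, class-dependent
N-glycosylation sequon rates, signal peptides, structural state strings and
biased back-translated ORFs — so the entire pipeline is testable and
reproducible from code alone.

## Worked example

```r
library(hiSecPred)

## a labelled synthetic dataset: Y +0.03, N +0.02, K -0.03, M -0.01
## composition shifts in positives, class-dependent sequon rates
ss <- generateProteins(100, 100, effectConfig(), seed = 42)
ss
#> SecretionSet with 200 records
#>   labels: 100 positive, 100 negative, 0 unknown
#>   ORFs: present; annotations: present

## mature-sequence amino-acid composition -> nested 10-fold CV
X  <- assembleFeatures(ss, "f2")
cv <- nestedCV(X, unname(labels(ss)), outer_folds = 10, seed = 42,
               keep_weights = TRUE)
cv
#> Nested cross-validation result
#>   mean AUROC: 1 over 10 outer folds
#>   chosen C: 1e-03 1e-03 1e+01 1e-03 1e-03 1e+01 1e-03 1e-03 1e-03 1e-03

## interpretation: normalized mean fold weights recover the planted signs
w <- normalizeContributions(rowMeans(cv$fold_weights))
round(sort(w)[c(1:3, 18:20)], 2)
#> comp:K comp:M comp:P comp:E comp:N comp:Y
#>  -1.00  -0.35  -0.13   0.05   0.76   0.99

## N-glycosylation sequons are enriched in the positive class
round(classMotifSummary(ss, scope = "mature")$class_means, 2)
#>  pos  neg
#> 4.49 2.22
```

The mean AUROC of 1 says the planted composition shift is fully
recoverable at this sample size; the weight vector shows lysine (K) and
methionine (M) with the strongest negative contributions and tyrosine (Y)
and asparagine (N) with the strongest positive ones, exactly the planted
effect directions; and positives carry roughly twice as many sequons as
negatives, matching the generator's class rates.

A command-line wrapper for the common steps is installed at
`system.file("exec", "hisecpred", package = "hiSecPred")` with subcommands
`simulate`, `filter`, `dedup`, `featurize`, `cv` and `motifs`.

## Package layout

- `R/` — S4 classes (`SecretionSet`, `AAClusters`, `LinearSVM`), dataset
  filters and redundancy reduction, representations, feature extraction,
  SVM training/evaluation/interpretation, greedy amino-acid clustering,
  motif counting, the synthetic-data generator, and reporting helpers.
- `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for the alignment, kernel and clustering code.
- `vignettes/secretion-prediction.Rmd` — the methods vignette: model,
  assumptions, parameter choices and limitations.
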
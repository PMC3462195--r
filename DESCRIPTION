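Package: hiSecPred
Title: Sequence-Based Prediction of High-Level Protein Secretion in Aspergillus niger
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring which protein and codon sequence features
    predict successful high-level production of secreted proteins in
    filamentous fungi. Provides containers for labelled secreted-protein
    datasets with structural annotations, dataset filtering and redundancy
    reduction, ten sequence representations (codon, signal peptide, mature,
    solvent-accessibility and secondary-structure subsequences plus
    randomized controls), compositional, codon-usage, codon-adaptation-index,
    isoelectric-point and k-mer spectrum features, linear support vector
    machine training with nested cross-validation and AUROC evaluation,
    classifier interpretation through feature weight vectors, a data-driven
    greedy amino-acid clustering algorithm, N-glycosylation sequon counting,
    and a synthetic-data generator emulating the class-dependent composition
    and sequon-frequency differences the method exploits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    e1071,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
biocViews: Classification, Proteomics, SupportVectorMachine, FeatureExtraction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
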
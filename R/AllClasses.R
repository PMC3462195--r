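#' @import methods
#' @importFrom Biostrings AAStringSet DNAStringSet readAAStringSet readDNAStringSet
#'   writeXStringSet pairwiseAlignment nmatch score pattern subject GENETIC_CODE
#' @importFrom BiocGenerics organism start end
#' @importFrom stats cor cor.test pt rpois runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Standard 20-letter amino-acid alphabet, alphabetical order (fixed column
# order for all composition features).
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# All 64 codons in lexicographic order.
CODONS64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
CODONS64 <- sort(CODONS64)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' SecretionSet: a labelled secreted-protein dataset
#'
#' Central container holding protein sequences, optional matching ORF coding
#' sequences, binary production labels (+1 = successful high-level
#' production, -1 = unsuccessful, NA = unknown), an organism tag per record,
#' and per-record structural annotations (signal-peptide presence and
#' cleavage position, transmembrane flag, per-residue buried/exposed and
#' helix/strand/coil state strings over the mature sequence).
#'
#' @slot proteins An [Biostrings::AAStringSet] with unique names (record ids).
#' @slot orfs A [Biostrings::DNAStringSet]; empty when ORFs are unavailable,
#'   otherwise named identically to `proteins`.
#' @slot label Integer vector over \{1, -1, NA\}, one per record.
#' @slot organism Character vector, one tag per record.
#' @slot annotation A `data.frame` with rownames equal to the record ids and
#'   columns `sp_flag` (logical), `cleavage_pos` (integer), `tm_flag`
#'   (logical), `acc_states` (character over \{B,E\}), `ss_states` (character
#'   over \{H,E,C\}); zero rows when no annotation is attached.
#'
#' @seealso [SecretionSet()] for construction, [generateProteins()] for
#'   simulated datasets, [applyFilters()], [reduceRedundancy()].
#' @export
setClass("SecretionSet",
  slots = c(
    proteins   = "AAStringSet",
    orfs       = "DNAStringSet",
    label      = "integer",
    organism   = "character",
    annotation = "data.frame"
  )
)

setValidity("SecretionSet", function(object) {
  msg <- character()
  ids <- names(object@proteins)
  n <- length(object@proteins)
  if (n == 0L) msg <- c(msg, "at least one protein record is required")
  if (is.null(ids) || anyDuplicated(ids) || any(ids == ""))
    msg <- c(msg, "protein ids must be unique non-empty names")
  seqs <- as.character(object@proteins)
  if (any(nchar(seqs) == 0L)) msg <- c(msg, "empty protein sequence")
  bad <- vapply(seqs, function(s) grepl(sprintf("[^%s]", paste(AA20, collapse = "")), s),
                logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("non-standard amino-acid letters in: %s",
                          paste(head(ids[bad], 3), collapse = ", ")))
  if (length(object@orfs) > 0L && !identical(names(object@orfs), ids))
    msg <- c(msg, "orf names must match protein names exactly")
  if (length(object@label) != n) msg <- c(msg, "label length mismatch")
  if (!all(object@label %in% c(1L, -1L, NA_integer_)))
    msg <- c(msg, "labels must be +1, -1 or NA")
  if (length(object@organism) != n) msg <- c(msg, "organism length mismatch")
  if (nrow(object@annotation) > 0L) {
    need <- c("sp_flag", "cleavage_pos", "tm_flag", "acc_states", "ss_states")
    if (!all(need %in% colnames(object@annotation)))
      msg <- c(msg, sprintf("annotation must have columns: %s",
                            paste(need, collapse = ", ")))
    else if (!identical(rownames(object@annotation), ids))
      msg <- c(msg, "annotation rownames must match protein ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SecretionSet
#'
#' @param proteins Named character vector or [Biostrings::AAStringSet] of
#'   protein sequences (uppercase, 20-letter alphabet).
#' @param orfs Optional named character vector or
#'   [Biostrings::DNAStringSet] of coding sequences (start codon through
#'   stop codon) matching `proteins` by name.
#' @param label Numeric/integer vector of +1 / -1 / NA production labels;
#'   defaults to all NA.
#' @param organism Character scalar or vector of organism tags.
#' @param annotation Optional `data.frame` of structural annotations (see
#'   [SecretionSet-class]); rows are matched to records by rownames.
#' @return A [SecretionSet-class] object.
#' @examples
#' ss <- SecretionSet(c(p1 = "MKKAVDA"), label = 1)
#' ss
#' @export
SecretionSet <- function(proteins, orfs = NULL, label = NULL,
                         organism = "unknown", annotation = NULL) {
  if (is.character(proteins)) proteins <- AAStringSet(toupper(proteins))
  n <- length(proteins)
  if (is.null(orfs)) {
    orfs <- DNAStringSet()
  } else {
    if (is.character(orfs)) orfs <- DNAStringSet(toupper(orfs))
    orfs <- orfs[names(proteins)]
  }
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (length(organism) == 1L) organism <- rep(organism, n)
  if (is.null(annotation)) {
    annotation <- data.frame(sp_flag = logical(0), cleavage_pos = integer(0),
                             tm_flag = logical(0), acc_states = character(0),
                             ss_states = character(0))
  } else {
    annotation <- as.data.frame(annotation)
    if (!is.null(rownames(annotation)) && nrow(annotation) > 0L)
      annotation <- annotation[names(proteins), , drop = FALSE]
    rownames(annotation) <- names(proteins)
  }
  new("SecretionSet", proteins = proteins, orfs = orfs, label = label,
      organism = organism, annotation = annotation)
}

#' @describeIn SecretionSet-class Number of records.
#' @param x,object A `SecretionSet`.
#' @export
setMethod("length", "SecretionSet", function(x) length(x@proteins))

#' @describeIn SecretionSet-class Record identifiers.
#' @export
setMethod("names", "SecretionSet", function(x) names(x@proteins))

#' @describeIn SecretionSet-class Subset records by index or id.
#' @param i Index, logical or character vector of record ids.
#' @export
setMethod("[", "SecretionSet", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@proteins))
  ann <- x@annotation
  if (nrow(ann) > 0L) ann <- ann[i, , drop = FALSE]
  orfs <- x@orfs
  if (length(orfs) > 0L) orfs <- orfs[i]
  new("SecretionSet", proteins = x@proteins[i], orfs = orfs,
      label = x@label[i], organism = x@organism[i], annotation = ann)
})

#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))
#' @describeIn SecretionSet-class Protein sequences as an `AAStringSet`.
#' @export
setMethod("proteins", "SecretionSet", function(object) object@proteins)

#' @export
setGeneric("orfs", function(object) standardGeneric("orfs"))
#' @describeIn SecretionSet-class ORF sequences as a `DNAStringSet` (possibly empty).
#' @export
setMethod("orfs", "SecretionSet", function(object) object@orfs)

#' @describeIn SecretionSet-class Production labels (+1/-1/NA), named by id.
#' @param ... Ignored.
#' @export
setMethod("labels", "SecretionSet",
          function(object, ...) setNames(object@label, names(object@proteins)))

#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @describeIn SecretionSet-class Structural annotation `data.frame`.
#' @export
setMethod("annotations", "SecretionSet", function(object) object@annotation)

#' @describeIn SecretionSet-class Organism tags.
#' @export
setMethod("organism", "SecretionSet", function(object) object@organism)

#' @export
setGeneric("hasAnnotation", function(object) standardGeneric("hasAnnotation"))
#' @describeIn SecretionSet-class TRUE when structural annotations are attached.
#' @export
setMethod("hasAnnotation", "SecretionSet",
          function(object) nrow(object@annotation) > 0L)

setMethod("show", "SecretionSet", function(object) {
  lab <- object@label
  cat("SecretionSet with", length(object@proteins), "records\n")
  cat("  labels: ", sum(lab %in% 1L), " positive, ", sum(lab %in% -1L),
      " negative, ", sum(is.na(lab)), " unknown\n", sep = "")
  cat("  ORFs: ", if (length(object@orfs)) "present" else "absent",
      "; annotations: ", if (nrow(object@annotation)) "present" else "absent",
      "\n", sep = "")
})

#' AAClusters: disjoint amino-acid clusters
#'
#' An ordered list of amino-acid sets used as a reduced alphabet: the
#' summed composition of each set is one feature. Not every amino acid
#' needs to belong to a cluster. Predefined physicochemical groupings may
#' overlap (an amino acid can be both small and polar); the data-driven
#' clustering of [greedyAAClustering()] produces pairwise disjoint sets by
#' construction.
#'
#' @slot clusters Named (or unnamed) list of character vectors of one-letter
#'   codes (normally amino acids; reduced toy alphabets are allowed); each
#'   set is non-empty without internal duplicates.
#' @seealso [predefinedClusters()] for the 11 physicochemical clusters,
#'   [greedyAAClustering()] for data-driven clusters.
#' @export
setClass("AAClusters", slots = c(clusters = "list"))

setValidity("AAClusters", function(object) {
  cl <- object@clusters
  msg <- character()
  if (length(cl) == 0L) msg <- c(msg, "at least one cluster required")
  if (any(vapply(cl, length, 1L) == 0L)) msg <- c(msg, "empty cluster")
  all_aa <- unlist(cl)
  if (length(all_aa) && any(nchar(all_aa) != 1L))
    msg <- c(msg, "cluster members must be single letters")
  if (any(vapply(cl, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "duplicate member within a cluster")
  if (length(msg)) msg else TRUE
})

#' Construct an AAClusters object
#'
#' @param clusters List of character vectors of one-letter amino-acid codes
#'   (a vector like `c("D","E")`, or a single string `"DE"`).
#' @return An [AAClusters-class] object.
#' @examples
#' AAClusters(list(acidic = "DE", basic = c("K", "R", "H")))
#' @export
AAClusters <- function(clusters) {
  clusters <- lapply(clusters, function(x) {
    if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
  })
  new("AAClusters", clusters = clusters)
}

#' @export
setGeneric("clusterList", function(object) standardGeneric("clusterList"))
#' @describeIn AAClusters-class The underlying list of amino-acid sets.
#' @param object An `AAClusters` object.
#' @export
setMethod("clusterList", "AAClusters", function(object) object@clusters)

#' @describeIn AAClusters-class Number of clusters.
#' @param x An `AAClusters` object.
#' @export
setMethod("length", "AAClusters", function(x) length(x@clusters))

#' @describeIn AAClusters-class Cluster names (may be `NULL`).
#' @export
setMethod("names", "AAClusters", function(x) names(x@clusters))

setMethod("show", "AAClusters", function(object) {
  cat("AAClusters with", length(object@clusters), "clusters\n")
  nm <- names(object@clusters)
  for (i in seq_along(object@clusters)) {
    lab <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("cluster", i)
    cat("  ", lab, ": ", paste(object@clusters[[i]], collapse = ""), "\n", sep = "")
  }
})

#' The 11 predefined physicochemical amino-acid clusters
#'
#' Classical physicochemical groupings (small, polar uncharged, aromatic,
#' acidic, charged, basic, hydrophobic, tiny, nonpolar, aliphatic, polar)
#' used as the predefined reduced-alphabet feature set. Ambiguous
#' state-dependent memberships (e.g. cysteine's polarity, which depends on
#' disulfide bonding) are resolved by excluding the amino acid from the
#' cluster, since per-residue states are unknown from sequence alone.
#'
#' @return An [AAClusters-class] object with 11 named clusters.
#' @examples
#' predefinedClusters()
#' @export
predefinedClusters <- function() {
  AAClusters(list(
    small           = c("V", "C", "A", "G", "T", "P", "S", "D", "N"),
    polar_uncharged = c("S", "W", "N", "Q", "T", "Y"),
    aromatic        = c("F", "Y", "W", "H"),
    acidic          = c("D", "E"),
    charged         = c("H", "K", "R", "E", "D"),
    basic           = c("K", "R", "H"),
    hydrophobic     = c("I", "L", "V", "M", "F", "Y", "W", "H", "C", "A", "T", "K"),
    tiny            = c("A", "G", "S"),
    nonpolar        = c("A", "V", "L", "I", "M", "G", "F", "P"),
    aliphatic       = c("I", "L", "V"),
    polar           = c("Y", "W", "H", "K", "R", "D", "E", "T", "S", "N", "Q")
  ))
}

#' LinearSVM: a trained linear support vector machine
#'
#' Stores the soft-margin linear SVM in its dual (support-vector) form: the
#' decision score of a feature vector x is
#' \deqn{f(x) = \sum_i \alpha_i y_i \langle x_i, x\rangle + b,}
#' where the sum runs over support vectors x_i with signed coefficients
#' alpha_i y_i. The equivalent explicit (primal) weight vector
#' w = sum_i alpha_i y_i x_i is available via [weightVector()].
#'
#' @slot supportCoefs Numeric vector of signed dual coefficients alpha_i y_i.
#' @slot supportX Numeric matrix of support-vector feature rows.
#' @slot bias Numeric scalar b.
#' @slot cost Regularization constant C used for training.
#' @slot columnNames Feature (column) names of the training matrix.
#' @seealso [trainLinearSVM()], [decisionScores()], [weightVector()].
#' @export
setClass("LinearSVM",
  slots = c(supportCoefs = "numeric", supportX = "matrix", bias = "numeric",
            cost = "numeric", columnNames = "character"))

setValidity("LinearSVM", function(object) {
  msg <- character()
  if (nrow(object@supportX) != length(object@supportCoefs))
    msg <- c(msg, "one coefficient per support vector required")
  if (ncol(object@supportX) != length(object@columnNames))
    msg <- c(msg, "columnNames must match supportX columns")
  if (length(object@bias) != 1L || length(object@cost) != 1L)
    msg <- c(msg, "bias and cost must be scalars")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LinearSVM", function(object) {
  cat("LinearSVM (C =", object@cost, ")\n")
  cat("  support vectors:", length(object@supportCoefs),
      " features:", length(object@columnNames), "\n")
  cat("  bias:", format(object@bias, digits = 4), "\n")
})
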
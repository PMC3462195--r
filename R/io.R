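#' Read a SecretionSet from FASTA/TSV files
#'
#' Assembles a dataset from a protein FASTA file plus optional ORF FASTA,
#' labels TSV (columns `id`, `label` with values `pos`/`neg`) and
#' annotations TSV (columns `id`, `sp_flag`, `cleavage_pos`, `tm_flag`,
#' `acc_states`, `ss_states`). Records are matched across files by id;
#' every id referenced in an auxiliary file must exist in the protein
#' FASTA.
#'
#' @param protein_fasta Path to the protein FASTA file.
#' @param orf_fasta Optional path to the matching ORF FASTA file.
#' @param labels_tsv Optional path to the labels TSV.
#' @param annotations_tsv Optional path to the annotations TSV.
#' @param organism Organism tag applied to all records. Default "unknown".
#' @return A [SecretionSet-class].
#' @export
readSecretionSet <- function(protein_fasta, orf_fasta = NULL,
                             labels_tsv = NULL, annotations_tsv = NULL,
                             organism = "unknown") {
  prot <- readAAStringSet(protein_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  ids <- names(prot)
  orfs <- NULL
  if (!is.null(orf_fasta)) {
    orfs <- readDNAStringSet(orf_fasta)
    names(orfs) <- sub("\\s.*$", "", names(orfs))
    miss <- setdiff(ids, names(orfs))
    if (length(miss))
      stop("ORF FASTA lacks: ", paste(head(miss, 3), collapse = ", "))
  }
  label <- NULL
  if (!is.null(labels_tsv)) {
    lt <- read.delim(labels_tsv, stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% colnames(lt)))
      stop("labels TSV needs columns id, label")
    if (!all(lt$label %in% c("pos", "neg")))
      stop("labels must be 'pos' or 'neg'")
    label <- rep(NA_integer_, length(ids))
    label[match(lt$id, ids)] <- ifelse(lt$label == "pos", 1L, -1L)
  }
  ann <- NULL
  if (!is.null(annotations_tsv)) {
    at <- read.delim(annotations_tsv, stringsAsFactors = FALSE)
    need <- c("id", "sp_flag", "cleavage_pos", "tm_flag", "acc_states", "ss_states")
    if (!all(need %in% colnames(at)))
      stop("annotations TSV needs columns: ", paste(need, collapse = ", "))
    miss <- setdiff(ids, at$id)
    if (length(miss))
      stop("annotation rows missing for: ", paste(head(miss, 3), collapse = ", "))
    at <- at[match(ids, at$id), ]
    ann <- data.frame(sp_flag = as.logical(at$sp_flag),
                      cleavage_pos = as.integer(at$cleavage_pos),
                      tm_flag = as.logical(at$tm_flag),
                      acc_states = at$acc_states,
                      ss_states = at$ss_states,
                      row.names = ids, stringsAsFactors = FALSE)
  }
  SecretionSet(prot, orfs = orfs, label = label, organism = organism,
               annotation = ann)
}

#' Write a SecretionSet to FASTA/TSV files
#'
#' Inverse of [readSecretionSet()]: writes `<prefix>_protein.fasta` and,
#' when present, `<prefix>_orf.fasta`, `<prefix>_labels.tsv` and
#' `<prefix>_annotations.tsv`.
#'
#' @param set A [SecretionSet-class].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
writeSecretionSet <- function(set, prefix) {
  stopifnot(is(set, "SecretionSet"))
  files <- character(0)
  f <- paste0(prefix, "_protein.fasta")
  writeXStringSet(proteins(set), f)
  files <- c(files, f)
  if (length(orfs(set))) {
    f <- paste0(prefix, "_orf.fasta")
    writeXStringSet(orfs(set), f)
    files <- c(files, f)
  }
  labs <- labels(set)
  if (any(!is.na(labs))) {
    f <- paste0(prefix, "_labels.tsv")
    write.table(data.frame(id = names(set),
                           label = ifelse(labs > 0, "pos", "neg")),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (hasAnnotation(set)) {
    f <- paste0(prefix, "_annotations.tsv")
    ann <- annotations(set)
    write.table(cbind(id = rownames(ann), ann), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write a feature matrix as TSV
#'
#' @param X Numeric matrix with row and column names.
#' @param path Output path; the id column comes first.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path TSV path with an `id` column.
#' @return Numeric matrix with ids as rownames.
#' @export
readFeatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(colnames(df), "id"), drop = FALSE])
  rownames(X) <- df$id
  X
}
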
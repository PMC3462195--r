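#' Count N-glycosylation sequons
#'
#' Counts occurrences of the canonical N-glycosylation acceptor sequon
#' N-X-[S/T] with X != P (switchable to the permissive N-X-[S/T]).
#' Overlapping matches are all counted.
#'
#' @param seq Amino-acid string.
#' @param allow_proline If `TRUE`, use the permissive pattern N-X-[S/T]
#'   (any middle residue). Default `FALSE` (X != P).
#' @return Integer sequon count.
#' @examples
#' countNglycSequons("NAS")   # 1
#' countNglycSequons("NPS")   # 0
#' countNglycSequons("NNST")  # 2 (overlap counted)
#' @export
countNglycSequons <- function(seq, allow_proline = FALSE) {
  assertScalarString(seq, "seq")
  pat <- if (allow_proline) "N(?=.[ST])" else "N(?=[^P][ST])"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) 0L else length(m)
}

#' C-terminal ER-retention signal
#'
#' `TRUE` iff the sequence ends with the most common ER retention signal,
#' HDEL or KDEL.
#'
#' @param seq Amino-acid string.
#' @return Logical scalar.
#' @examples
#' hasErRetention("MAWKDEL")  # TRUE
#' hasErRetention("KDELG")    # FALSE
#' @export
hasErRetention <- function(seq) {
  assertScalarString(seq, "seq")
  grepl("[HK]DEL$", seq)
}

#' Per-class N-glycosylation sequon summary
#'
#' Counts sequons per protein (on the full sequence or the mature sequence
#' after signal-peptide removal) and summarizes them per production class.
#'
#' @param set A labelled [SecretionSet-class]; both classes must be
#'   present. Annotations are required for `scope = "mature"`.
#' @param scope `"full"` (default) or `"mature"`.
#' @param allow_proline Passed to [countNglycSequons()].
#' @return List with `counts` (named integer per protein), `class_means`
#'   (named numeric: `pos`, `neg`), `overall_mean` and `scope`.
#' @export
classMotifSummary <- function(set, scope = c("full", "mature"),
                              allow_proline = FALSE) {
  stopifnot(is(set, "SecretionSet"))
  scope <- match.arg(scope)
  labs <- labels(set)
  if (!any(labs %in% 1L) || !any(labs %in% -1L))
    stop("both a positive and a negative class are required")
  seqs <- if (scope == "full") as.character(proteins(set))
          else representationOf(set, "mature")
  counts <- vapply(seqs, countNglycSequons, 1L,
                   allow_proline = allow_proline)
  names(counts) <- names(set)
  list(counts = counts,
       class_means = c(pos = mean(counts[labs %in% 1L]),
                       neg = mean(counts[labs %in% -1L])),
       overall_mean = mean(counts),
       scope = scope)
}
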
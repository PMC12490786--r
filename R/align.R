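#' Global affine-gap alignment (Needleman-Wunsch)
#'
#' Optimal global alignment with affine gap costs under EMBOSS-needle
#' default scoring: match 5, mismatch -4, gap opening 10 (charged on the
#' first base of a gap), gap extension 0.5 per additional base. End gaps
#' are penalized like internal gaps. `N` scores 0 against anything. Ties
#' are broken deterministically: substitution preferred over gap, then
#' gap-in-query over gap-in-reference, scanning back from the sequence
#' ends.
#'
#' @param query,reference DNA strings (A/C/G/T/N).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters.
#' @param id identifier stored on the result.
#' @return an [AlignedRead-class].
#' @examples
#' aln <- alignGlobal("ACGT", "ACT")
#' aln@score  # 3 matches - gap open = 5
#' @export
alignGlobal <- function(query, reference, match = 5, mismatch = -4,
                        gapOpen = 10, gapExtend = 0.5, id = "query") {
  r <- nw_align_cpp(query, reference, match, mismatch, gapOpen, gapExtend)
  new("AlignedRead", id = id, score = r$score[1],
      alignedQuery = r$query[1], alignedReference = r$reference[1])
}

#' @rdname AlignedRead-class
#' @param object an `AlignedRead`.
#' @export
setMethod("show", "AlignedRead", function(object) {
  cat("AlignedRead '", object@id, "' score ", object@score, "\n  ",
      object@alignedQuery, "\n  ", object@alignedReference, "\n", sep = "")
})

# Parse one gapped alignment (query/reference strings of equal length)
# against the inner reference of a locus. Returns substitutions (inner
# reference offsets) and indel runs.
.parseAlignment <- function(aq, ar) {
  qc <- strsplit(aq, "")[[1]]
  rc <- strsplit(ar, "")[[1]]
  refPos <- cumsum(rc != "-")           # inner reference offset per column
  isSub <- qc != "-" & rc != "-" & qc != rc
  subs <- data.frame(refOffset = refPos[isSub], refBase = rc[isSub],
                     altBase = qc[isSub], stringsAsFactors = FALSE)

  indels <- list()
  gapQ <- qc == "-"                      # deletion from the read
  gapR <- rc == "-"                      # insertion into the read
  for (g in list(list(mask = gapQ, type = "deletion"),
                 list(mask = gapR, type = "insertion"))) {
    r <- rle(g$mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      colA <- starts[i]; colB <- ends[i]
      if (g$type == "deletion") {
        indels[[length(indels) + 1L]] <- list(
          type = "deletion", size = colB - colA + 1L,
          refStart = refPos[colA], refEnd = refPos[colB],
          seq = paste(rc[colA:colB], collapse = ""))
      } else {
        # query-adjacent k-mers allow tandem-duplication detection even
        # when the duplicated copy carries a substitution
        qAll <- qc[qc != "-"]
        qPos <- cumsum(qc != "-")
        k <- colB - colA + 1L
        qs <- qPos[colA]                 # query index of first inserted base
        qUp <- if (qs - k >= 1L)
          paste(qAll[(qs - k):(qs - 1L)], collapse = "") else ""
        qDn <- if (qs + 2L * k - 1L <= length(qAll))
          paste(qAll[(qs + k):(qs + 2L * k - 1L)], collapse = "") else ""
        indels[[length(indels) + 1L]] <- list(
          type = "insertion", size = k,
          refStart = if (colA > 1L) refPos[colA - 1L] else 0L,  # after this base
          refEnd = if (colA > 1L) refPos[colA - 1L] else 0L,
          seq = paste(qc[colA:colB], collapse = ""),
          qUp = qUp, qDn = qDn)
      }
    }
  }
  list(subs = subs, indels = indels, refPos = refPos, qc = qc, rc = rc)
}
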
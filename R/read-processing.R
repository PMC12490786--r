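#' Merge one overlapping read pair
#'
#' Scans all overlap lengths from `minOverlap` up to the shorter read,
#' after reverse-complementing read 2 onto the forward strand, and keeps
#' the overlap with the most matching bases among those whose mismatch
#' fraction is at most `maxOverlapMismatchFrac`; ties on match count go to
#' the longer overlap. In the overlap the base with the higher Phred score
#' wins and the consensus quality is the maximum of the two. Failure to
#' merge is a typed outcome (`merged = FALSE`), not an error.
#'
#' @param seq1,qual1 forward read and its Phred+33 quality string.
#' @param seq2,qual2 reverse read (as sequenced) and quality.
#' @param minOverlap minimum acceptable overlap (bases).
#' @param maxOverlapMismatchFrac maximum mismatch fraction in the overlap.
#' @return list with `merged` (logical), `seq`, `qual`, `overlap`.
#' @examples
#' frag <- "ACGTACGTACGTACGTACGTACGTACGTAC"
#' r1 <- substr(frag, 1, 20)
#' r2 <- revComp(substr(frag, 11, 30))
#' mergeReadPair(r1, strrep("F", 20), r2, strrep("F", 20))$overlap
#' @export
mergeReadPair <- function(seq1, qual1, seq2, qual2, minOverlap = 10L,
                          maxOverlapMismatchFrac = 0.25) {
  r <- merge_pairs_cpp(seq1, qual1, seq2, qual2,
                       as.integer(minOverlap), maxOverlapMismatchFrac)
  list(merged = r$merged[1], seq = r$seq[1], qual = r$qual[1],
       overlap = r$overlap[1])
}

#' Quality-filter a merged read
#'
#' A read fails if it has more than `maxLowQBases` bases with Phred
#' quality below `lowQThreshold` (strictly more than, so a read with
#' exactly `maxLowQBases` low-quality bases passes).
#'
#' @param qual Phred+33 quality string of the merged read.
#' @param lowQThreshold Phred score below which a base counts as low
#'   quality.
#' @param maxLowQBases maximum tolerated number of low-quality bases.
#' @return `TRUE` if the read passes.
#' @export
filterByQuality <- function(qual, lowQThreshold = 20L, maxLowQBases = 2L) {
  count_low_q_cpp(qual, as.integer(lowQThreshold))[1] <= maxLowQBases
}

.orientHamming <- function(seqs, fwdPrimer, revPrimer, maxMismatch) {
  lf <- nchar(fwdPrimer); lr <- nchar(revPrimer)
  L <- nchar(seqs)
  rcRev <- revComp(revPrimer)
  ok <- L >= lf + lr + 1L
  pre <- ifelse(ok, substr(seqs, 1L, lf), strrep("N", lf + 1L))
  suf <- ifelse(ok, substring(seqs, L - lr + 1L, L), strrep("N", lr + 1L))
  dPre <- hamming_cpp(pre, fwdPrimer)
  dSuf <- hamming_cpp(suf, rcRev)
  ok & !is.na(dPre) & !is.na(dSuf) & dPre <= maxMismatch & dSuf <= maxMismatch
}

#' Anchor a merged read between its primers
#'
#' Requires an ungapped (Hamming) match of the forward primer at the 5'
#' end and of the reverse-complemented reverse primer at the 3' end, each
#' with at most `maxMismatch` substitutions and no indels, in either read
#' orientation. The read is reoriented to the reference strand and trimmed
#' to the inter-primer segment.
#'
#' @param seq merged read sequence.
#' @param fwdPrimer,revPrimer primer sequences.
#' @param maxMismatch maximum substitutions tolerated per primer.
#' @return list with `anchored` (logical), `seq` (trimmed,
#'   reference-oriented) and `orientation` (`"+"` or `"-"`).
#'   Throws an error if both orientations match (malformed amplicon).
#' @export
anchorPrimers <- function(seq, fwdPrimer, revPrimer, maxMismatch = 2L) {
  if (nchar(fwdPrimer) + nchar(revPrimer) >= nchar(seq))
    return(list(anchored = FALSE, seq = NA_character_,
                orientation = NA_character_))
  fwdOk <- .orientHamming(seq, fwdPrimer, revPrimer, maxMismatch)
  revOk <- .orientHamming(revComp(seq), fwdPrimer, revPrimer, maxMismatch)
  if (fwdOk && revOk)
    stop("both orientations match the primers: malformed amplicon")
  if (!fwdOk && !revOk)
    return(list(anchored = FALSE, seq = NA_character_,
                orientation = NA_character_))
  oriented <- if (fwdOk) seq else revComp(seq)
  L <- nchar(oriented)
  list(anchored = TRUE,
       seq = substr(oriented, nchar(fwdPrimer) + 1L, L - nchar(revPrimer)),
       orientation = if (fwdOk) "+" else "-")
}

#' Process raw read pairs into anchored amplicon reads
#'
#' Runs the full pre-alignment contract: merge overlapping pairs, apply
#' the read-level quality filter to the merged read, then anchor and trim
#' at the primers. Reads where both orientations match the primers count
#' as primer failures.
#'
#' @param seq1,qual1,seq2,qual2 character vectors of paired reads, or
#'   `seq2 = NULL` with pre-merged reads in `seq1`/`qual1`.
#' @param locus an [AmpliconLocus-class] providing the primers.
#' @param minOverlap,maxOverlapMismatchFrac merge thresholds (see
#'   [mergeReadPair()]).
#' @param lowQThreshold,maxLowQBases quality-filter thresholds (see
#'   [filterByQuality()]).
#' @param maxPrimerMismatch primer-anchoring threshold (see
#'   [anchorPrimers()]).
#' @param id optional read names.
#' @return list with `seq` (anchored inter-primer sequences,
#'   reference-oriented), `id`, and `report` (a [FilterReport-class]).
#' @export
processReads <- function(seq1, qual1, seq2 = NULL, qual2 = NULL,
                         locus = hbbLocus(),
                         minOverlap = 10L, maxOverlapMismatchFrac = 0.25,
                         lowQThreshold = 20L, maxLowQBases = 2L,
                         maxPrimerMismatch = 2L,
                         id = NULL) {
  n <- length(seq1)
  if (is.null(id)) id <- sprintf("read%07d", seq_len(n))
  if (!is.null(seq2)) {
    m <- merge_pairs_cpp(seq1, qual1, seq2, qual2,
                         as.integer(minOverlap), maxOverlapMismatchFrac)
    merged <- m$merged
    mseq <- m$seq; mqual <- m$qual
  } else {
    merged <- rep(TRUE, n)
    mseq <- seq1; mqual <- qual1
  }
  failedMerge <- sum(!merged)

  lowQ <- count_low_q_cpp(mqual, as.integer(lowQThreshold))
  qPass <- merged & lowQ <= maxLowQBases
  failedQuality <- sum(merged & !qPass)

  fwd <- locus@primerFwd; rev <- locus@primerRev
  keep <- which(qPass)
  seqs <- mseq[keep]
  fwdOk <- .orientHamming(seqs, fwd, rev, maxPrimerMismatch)
  revOk <- .orientHamming(revComp(seqs), fwd, rev, maxPrimerMismatch)
  ambiguous <- fwdOk & revOk
  anchored <- xor(fwdOk, revOk)
  failedPrimer <- sum(qPass) - sum(anchored)

  oriented <- ifelse(fwdOk & !ambiguous, seqs,
                     ifelse(revOk & !ambiguous, revComp(seqs),
                            NA_character_))
  oriented <- oriented[anchored]
  L <- nchar(oriented)
  trimmed <- substr(oriented, nchar(fwd) + 1L, L - nchar(rev))

  report <- new("FilterReport",
                total = as.integer(n),
                merged = as.integer(n - failedMerge),
                failedMerge = as.integer(failedMerge),
                failedQuality = as.integer(failedQuality),
                failedPrimer = as.integer(failedPrimer),
                retained = as.integer(length(trimmed)))
  list(seq = trimmed, id = id[keep][anchored], report = report)
}
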
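#' The published MIT (Hsu) position weight vector
#'
#' Per-position mismatch weights for the MIT specificity score, positions
#' 1-20 from the 5' (PAM-distal) end of the protospacer. These are the
#' published weights of Hsu et al. (2013), as used by CRISPR off-target
#' ranking tools; they are an external constant, embedded here so that
#' candidate sites can be ranked without network access.
#'
#' @return numeric vector of length 20.
#' @export
hsuWeights <- function() {
  c(0.000, 0.000, 0.014, 0.000, 0.000, 0.395, 0.317, 0.000, 0.389, 0.079,
    0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804, 0.685, 0.583)
}

#' MIT specificity score for one candidate site
#'
#' `score = 100 * prod(1 - W[p]) * 1 / (((19 - dbar) / 19) * 4 + 1) *
#' 1 / m^2` over the `m` mismatch positions `p`, where `dbar` is the mean
#' pairwise distance between mismatch positions and `W` the published
#' weight vector. A perfect match scores 100; with a single mismatch the
#' distance term is 1 by convention.
#'
#' @param mismatchPositions integer vector of protospacer positions
#'   (1-20) carrying mismatches; empty for a perfect match.
#' @param weights position weight vector, by default [hsuWeights()].
#' @return score in `[0, 100]`.
#' @examples
#' scoreMit(integer())    # 100
#' scoreMit(c(1L))        # weight 0 at position 1 -> still 100
#' scoreMit(c(14L, 16L))  # heavily weighted PAM-proximal pair
#' @export
scoreMit <- function(mismatchPositions, weights = hsuWeights()) {
  m <- length(mismatchPositions)
  if (m == 0L) return(100)
  if (any(mismatchPositions < 1L | mismatchPositions > 20L))
    stop("mismatch positions must lie in 1..20")
  t1 <- prod(1 - weights[mismatchPositions])
  t2 <- if (m < 2L) 1 else {
    dbar <- mean(stats::dist(mismatchPositions))
    1 / (((19 - dbar) / 19) * 4 + 1)
  }
  100 * t1 * t2 / m^2
}

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.pamMatches <- function(pams, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  ok <- rep(TRUE, length(pams))
  for (i in seq_along(pat)) {
    allowed <- .IUPAC[[pat[i]]]
    if (is.null(allowed)) stop("invalid IUPAC code in PAM pattern: ", pat[i])
    ok <- ok & substring(pams, i, i) %in% allowed
  }
  ok
}

.mismatchPositions <- function(siteSeqs, spacer) {
  sp <- strsplit(spacer, "")[[1]]
  lapply(strsplit(siteSeqs, ""), function(s) which(s != sp))
}

#' Enumerate candidate off-target sites by mismatch scan
#'
#' Scans every 20-mer window on both strands of the reference for sites
#' within `maxMismatches` Hamming distance of the spacer (no bulges) whose
#' 3'-adjacent 3-mer matches the IUPAC PAM pattern. Windows whose PAM
#' would run off the contig are skipped; `N` in the reference counts as a
#' mismatch. Each retained site is scored with [scoreMit()].
#'
#' @param reference a named character vector of contig sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param spacer 20-mer spacer sequence.
#' @param pamPattern IUPAC 3-mer PAM pattern (default `"NNN"`, i.e.
#'   unconstrained).
#' @param maxMismatches maximum Hamming distance.
#' @return a [GenomicRanges::GRanges] of the 20-mer protospacer
#'   footprints (1-based, inclusive), sorted by contig, start and strand,
#'   with metadata columns `siteSeq` (spacer-matching strand), `pam`,
#'   `mismatches`, `mismatchPositions` (comma-separated) and `score`.
#' @examples
#' ref <- c(chr1 = paste0(strrep("A", 30), "TTCTCCTCAGGAGTCAGATG", "TGG",
#'                        strrep("A", 30)))
#' enumerateCandidateSites(ref, "TTCTCCTCAGGAGTCAGATG", maxMismatches = 0)
#' @export
enumerateCandidateSites <- function(reference, spacer, pamPattern = "NNN",
                                    maxMismatches = 4L) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(reference)
  if (!length(reference) || all(Biostrings::width(reference) == 0L))
    stop("empty reference")
  if (nchar(spacer) != 20L) stop("spacer must be a 20-mer")
  spacer <- toupper(spacer)
  rcSpacer <- revComp(spacer)

  hits <- list()
  for (ci in seq_along(reference)) {
    contig <- names(reference)[ci]
    subj <- reference[[ci]]
    L <- length(subj)
    if (L < 23L) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else rcSpacer
      m <- Biostrings::matchPattern(pat, subj,
                                    max.mismatch = maxMismatches,
                                    with.indels = FALSE, fixed = TRUE)
      st <- BiocGenerics::start(m)
      if (!length(st)) next
      if (strand == "+") {
        keep <- st + 22L <= L
        st <- st[keep]
        if (!length(st)) next
        pam <- as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(st + 20L, st + 22L)))
        siteSeq <- as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(st, st + 19L)))
      } else {
        keep <- st >= 4L
        st <- st[keep]
        if (!length(st)) next
        pam <- revComp(as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(st - 3L, st - 1L))))
        siteSeq <- revComp(as.character(Biostrings::extractAt(
          subj, IRanges::IRanges(st, st + 19L))))
      }
      ok <- .pamMatches(pam, pamPattern)
      if (!any(ok)) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig = contig, start = st[ok], strand = strand,
        siteSeq = siteSeq[ok], pam = pam[ok], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      siteSeq = character(), pam = character(), mismatches = integer(),
      mismatchPositions = character(), score = numeric())
    return(gr)
  }
  df <- do.call(rbind, hits)
  mmPos <- .mismatchPositions(df$siteSeq, spacer)
  df$mismatches <- lengths(mmPos)
  df <- df[df$mismatches <= maxMismatches, ]
  mmPos <- mmPos[lengths(mmPos) <= maxMismatches]
  df$mismatchPositions <- vapply(mmPos, paste, character(1), collapse = ",")
  df$score <- vapply(mmPos, scoreMit, numeric(1))
  o <- order(df$contig, df$start, df$strand)
  df <- df[o, ]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, width = 20L),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    siteSeq = df$siteSeq, pam = df$pam, mismatches = df$mismatches,
    mismatchPositions = df$mismatchPositions, score = df$score)
  names(gr) <- sprintf("site%04d", seq_along(gr))
  gr
}

#' Rank candidate sites and select the panel
#'
#' All sites with fewer than the maximum mismatch count are always
#' retained; sites at the maximum mismatch count fill the remaining slots
#' in descending score order, ties broken by contig, position and strand.
#' The output is ordered by (mismatch count, score descending,
#' coordinates).
#'
#' @param sites a `GRanges` from [enumerateCandidateSites()].
#' @param k total number of sites to select.
#' @param maxMismatches mismatch count treated as the fill tier; defaults
#'   to the maximum observed.
#' @return the selected subset, ordered.
#' @export
rankAndSelect <- function(sites, k, maxMismatches = NULL) {
  if (k < 0L) stop("k must be non-negative")
  if (!length(sites)) return(sites)
  mm <- S4Vectors::mcols(sites)$mismatches
  if (is.null(maxMismatches)) maxMismatches <- max(mm)
  low <- mm < maxMismatches
  if (k < sum(low))
    stop("k = ", k, " cannot honor all ", sum(low),
         " sites below the maximum mismatch count")
  coordKey <- order(as.character(GenomicRanges::seqnames(sites)),
                    BiocGenerics::start(sites),
                    as.character(BiocGenerics::strand(sites)))
  rankWithin <- integer(length(sites))
  rankWithin[coordKey] <- seq_along(sites)
  sc <- S4Vectors::mcols(sites)$score
  ord <- order(mm, -sc, rankWithin)
  sorted <- sites[ord]
  mmS <- S4Vectors::mcols(sorted)$mismatches
  nFill <- k - sum(low)
  sel <- c(which(mmS < maxMismatches),
           which(mmS == maxMismatches)[seq_len(min(nFill,
                                                   sum(mmS == maxMismatches)))])
  sorted[sort(sel)]
}

#' Export candidate sites as BED6 and extended TSV
#'
#' BED uses 0-based half-open coordinates; the TSV carries 1-based
#' inclusive coordinates plus sequence, mismatch and score columns.
#'
#' @param sites a `GRanges` from [enumerateCandidateSites()].
#' @param bedPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
exportCandidateSites <- function(sites, bedPath = NULL, tsvPath = NULL) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(sites)),
    start = BiocGenerics::start(sites),
    end = BiocGenerics::end(sites),
    name = names(sites) %||% sprintf("site%04d", seq_along(sites)),
    strand = as.character(BiocGenerics::strand(sites)),
    S4Vectors::mcols(sites), stringsAsFactors = FALSE)
  out <- character()
  if (!is.null(bedPath)) {
    bed <- data.frame(df$contig, df$start - 1L, df$end, df$name,
                      as.integer(round(df$score)), df$strand)
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out <- c(out, bedPath)
  }
  if (!is.null(tsvPath)) {
    writeTsv(df, tsvPath)
    out <- c(out, tsvPath)
  }
  invisible(out)
}
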
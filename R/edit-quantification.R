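#' Classify one aligned read against the amplicon
#'
#' Implements the read-grouping contract: a read is `INDEL` if any
#' alignment gap overlaps the protospacer extended by `flank` bases on
#' each side; otherwise `EDIT` with the set of named adenines carrying
#' A-to-G (precedence over incidental substitutions elsewhere); otherwise
#' `WT` if no substitution falls at any protospacer position; otherwise
#' `SUBST_OTHER`.
#'
#' @param aln an [AlignedRead-class] of the primer-trimmed read against
#'   the inner (primer-trimmed) reference of `locus`.
#' @param locus an [AmpliconLocus-class].
#' @param flank indel classification window, bases beyond the protospacer.
#' @return list with `class` (`"WT"`, `"EDIT"`, `"SUBST_OTHER"`,
#'   `"INDEL"`), `edits` (edited named adenines), `psBases` (read base at
#'   each protospacer position, protospacer strand; `NA` for INDEL reads),
#'   `indels` (list of indel records) and `subs` (substitution table in
#'   inner-reference offsets).
#' @export
classifyRead <- function(aln, locus, flank = 10L) {
  p <- .parseAlignment(aln@alignedQuery, aln@alignedReference)
  innerStart <- .innerProtospacerStart(locus)
  wStart <- innerStart - flank
  wEnd <- innerStart + 19L + flank

  inWindow <- vapply(p$indels, function(ind) {
    if (ind$type == "deletion") ind$refEnd >= wStart && ind$refStart <= wEnd
    else ind$refStart >= wStart - 1L && ind$refStart <= wEnd
  }, logical(1))
  if (any(inWindow)) {
    return(list(class = "INDEL", edits = character(),
                psBases = rep(NA_character_, 20L),
                indels = p$indels[inWindow], subs = p$subs))
  }

  psOffsets <- protospacerToReference(locus, 1:20) - nchar(locus@primerFwd)
  # read base at each protospacer position (columns where the reference
  # base is consumed and the read has a base)
  psBasesRef <- vapply(psOffsets, function(off) {
    cols <- which(p$refPos == off & p$rc != "-")
    if (!length(cols) || p$qc[cols[1]] == "-") NA_character_
    else p$qc[cols[1]]
  }, character(1))
  if (anyNA(psBasesRef))
    return(list(class = "INDEL", edits = character(),
                psBases = rep(NA_character_, 20L),
                indels = p$indels, subs = p$subs))
  psBases <- .toProtospacerStrand(psBasesRef, locus)

  np <- locus@namedPositions
  aPos <- np[startsWith(names(np), "A")]
  edited <- names(aPos)[psBases[aPos] == "G"]
  if (length(edited)) {
    return(list(class = "EDIT", edits = edited[order(aPos[edited])],
                psBases = psBases, indels = list(), subs = p$subs))
  }
  ps <- strsplit(protospacer(locus), "")[[1]]
  if (any(psBases != ps))
    return(list(class = "SUBST_OTHER", edits = character(),
                psBases = psBases, indels = list(), subs = p$subs))
  list(class = "WT", edits = character(), psBases = psBases,
       indels = list(), subs = p$subs)
}

#' Classify a vector of anchored reads
#'
#' Deduplicates, aligns each distinct read to the inner reference with
#' [alignGlobal()] scoring, and classifies it with [classifyRead()].
#' The result feeds [tabulatePositions()], [tabulateCombinations()] and
#' [catalogIndels()].
#'
#' @param seqs anchored, primer-trimmed, reference-oriented reads.
#' @param locus an [AmpliconLocus-class].
#' @param flank indel window beyond the protospacer (bases).
#' @param match,mismatch,gapOpen,gapExtend alignment scoring parameters.
#' @return list with `uniq` (distinct reads), `counts` (their
#'   multiplicities), `class`, `editLabel`, `psBases` (matrix of
#'   protospacer-strand bases), `indels` and `nRetained`.
#' @export
classifyAmpliconReads <- function(seqs, locus, flank = 10L,
                                  match = 5, mismatch = -4,
                                  gapOpen = 10, gapExtend = 0.5) {
  .classifyBatch(seqs, locus, flank, match, mismatch, gapOpen, gapExtend)
}

# Classify a vector of anchored reads with deduplication. Returns the
# per-unique-read classification plus weights, the protospacer base matrix
# for non-indel reads, and protospacer-relative indel records.
.classifyBatch <- function(seqs, locus, flank = 10L,
                           match = 5, mismatch = -4,
                           gapOpen = 10, gapExtend = 0.5) {
  if (!length(seqs)) stop("no retained reads to classify")
  innerRef <- .innerReference(locus)
  tab <- table(seqs)
  uniq <- names(tab)
  counts <- as.integer(tab)
  n <- length(uniq)

  cls <- character(n)
  editLabel <- character(n)
  psBases <- matrix(NA_character_, n, 20L)
  indelRecs <- vector("list", n)

  isRef <- uniq == innerRef
  psCols <- strsplit(protospacer(locus), "")[[1]]
  if (any(isRef)) {
    cls[isRef] <- "WT"
    psBases[isRef, ] <- matrix(psCols, sum(isRef), 20L, byrow = TRUE)
  }
  todo <- which(!isRef)
  if (length(todo)) {
    alns <- nw_align_cpp(uniq[todo], innerRef, match, mismatch,
                         gapOpen, gapExtend)
    for (k in seq_along(todo)) {
      i <- todo[k]
      a <- new("AlignedRead", id = paste0("u", i), score = alns$score[k],
               alignedQuery = alns$query[k],
               alignedReference = alns$reference[k])
      r <- classifyRead(a, locus, flank)
      cls[i] <- r$class
      editLabel[i] <- paste(r$edits, collapse = "+")
      psBases[i, ] <- r$psBases
      indelRecs[[i]] <- r$indels
    }
  }
  list(uniq = uniq, counts = counts, class = cls, editLabel = editLabel,
       psBases = psBases, indels = indelRecs,
       nRetained = sum(counts))
}

#' Quantify editing outcomes for one sample
#'
#' Aligns anchored reads to the wild-type amplicon and produces the full
#' set of per-sample summaries: the per-position base-frequency table
#' (indel reads excluded), the edit-combination table, the indel catalog
#' and the cytosine-deamination table.
#'
#' @param seqs character vector of anchored, primer-trimmed,
#'   reference-oriented reads (output of [processReads()]).
#' @param locus an [AmpliconLocus-class].
#' @param sample sample identifier.
#' @param flank indel classification window beyond the protospacer
#'   (bases).
#' @param match,mismatch,gapOpen,gapExtend alignment scoring parameters.
#' @return list with `positions` ([PositionFrequencyTable-class]),
#'   `combinations` (data.frame), `indels` (data.frame with attribute
#'   `cumulativeFrequency`), `cytosine` (data.frame), `classCounts`
#'   (named vector) and `nRetained`.
#' @examples
#' cfg <- simConfig(depth = 300L, perBaseError = 0, lowQualityRate = 0,
#'                  seed = 3L)
#' sim <- simulateAmpliconReads(cfg)
#' pr <- processReads(sim$seq1, sim$qual1, sim$seq2, sim$qual2, cfg$locus)
#' q <- quantifyAmplicon(pr$seq, cfg$locus, "demo")
#' q$combinations
#' @export
quantifyAmplicon <- function(seqs, locus, sample = "sample", flank = 10L,
                             match = 5, mismatch = -4, gapOpen = 10,
                             gapExtend = 0.5) {
  b <- .classifyBatch(seqs, locus, flank, match, mismatch, gapOpen,
                      gapExtend)
  positions <- tabulatePositions(b, locus, sample)
  list(positions = positions,
       combinations = tabulateCombinations(b),
       indels = catalogIndels(b, locus),
       cytosine = quantifyCytosineDeamination(positions, locus),
       classCounts = tapply(b$counts, factor(b$class,
                            levels = c("WT", "EDIT", "SUBST_OTHER", "INDEL")),
                            sum, default = 0L),
       nRetained = b$nRetained)
}

#' Tabulate per-position base counts
#'
#' Builds the [PositionFrequencyTable-class] for a classified sample.
#' Reads classified as `INDEL` are excluded: gapped columns make
#' per-position base identity ill-defined, and indels are reported
#' separately by [catalogIndels()].
#'
#' @param classified result of the internal classification (as produced
#'   within [quantifyAmplicon()]).
#' @param locus an [AmpliconLocus-class].
#' @param sample sample identifier.
#' @return a [PositionFrequencyTable-class] over protospacer positions
#'   1-20.
#' @export
tabulatePositions <- function(classified, locus, sample = "sample") {
  keep <- classified$class != "INDEL"
  if (!any(keep)) stop("no non-indel reads: empty position table")
  m <- matrix(0, 20L, 4L, dimnames = list(1:20, .BASES))
  bases <- classified$psBases[keep, , drop = FALSE]
  w <- classified$counts[keep]
  for (p in 1:20) {
    t <- tapply(w, factor(bases[, p], levels = .BASES), sum, default = 0)
    m[p, ] <- t
  }
  positionFrequencyTable(sample, m, strsplit(protospacer(locus), "")[[1]])
}

#' Tabulate edit combinations
#'
#' Partition of retained reads into `WT`, each observed combination of
#' edited named adenines (e.g. `A9`, `A9+A12`), `SUBST_OTHER` and
#' `INDEL`; fractions sum to 1.
#'
#' @inheritParams tabulatePositions
#' @return data.frame with `combination`, `count`, `fraction`.
#' @export
tabulateCombinations <- function(classified) {
  lab <- ifelse(classified$class == "EDIT", classified$editLabel,
                classified$class)
  agg <- tapply(classified$counts, lab, sum)
  df <- data.frame(combination = names(agg), count = as.integer(agg),
                   stringsAsFactors = FALSE)
  df$fraction <- df$count / sum(df$count)
  fixed <- c("WT", "SUBST_OTHER", "INDEL")
  df <- df[order(match(df$combination, fixed, nomatch = 0L),
                 df$combination), ]
  rownames(df) <- NULL
  df
}

#' Catalog indel alleles
#'
#' One record per distinct (type, protospacer span, sequence). An
#' insertion whose sequence equals the immediately adjacent reference
#' k-mer is reported as a duplication. Spans are protospacer-relative,
#' 1-based inclusive, and may extend beyond 1-20 with signed coordinates.
#' Frequencies are fractions of all retained reads, so they are unaffected
#' by the indel-exclusion rule of [tabulatePositions()].
#'
#' @inheritParams tabulatePositions
#' @return data.frame with `type`, `size`, `psStart`, `psEnd`, `seq`,
#'   `count`, `frequency`; attribute `cumulativeFrequency` holds the sum.
#' @export
catalogIndels <- function(classified, locus) {
  innerRef <- .innerReference(locus)
  innerStart <- .innerProtospacerStart(locus)
  toPs <- function(refOff) {
    if (locus@protospacerStrand == "+") refOff - innerStart + 1L
    else innerStart + 20L - refOff
  }
  rows <- list()
  for (i in seq_along(classified$indels)) {
    for (ind in classified$indels[[i]]) {
      type <- ind$type
      sq <- ind$seq
      if (type == "insertion") {
        k <- nchar(sq)
        p <- ind$refStart
        up <- if (p - k + 1L >= 1L) substr(innerRef, p - k + 1L, p) else ""
        dn <- substr(innerRef, p + 1L, p + k)
        # tandem duplication: inserted copy equals the adjacent reference
        # k-mer, or the adjacent stretch of the read itself (the latter
        # catches duplications whose copies carry a base edit)
        if (sq %in% c(up, dn, ind$qUp %||% "", ind$qDn %||% ""))
          type <- "duplication"
      }
      psSpan <- sort(toPs(c(ind$refStart, ind$refEnd)))
      if (locus@protospacerStrand == "-") sq <- revComp(sq)
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, size = ind$size,
        psStart = psSpan[1], psEnd = psSpan[2], seq = sq,
        count = classified$counts[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(type = character(), size = integer(),
                      psStart = integer(), psEnd = integer(),
                      seq = character(), count = integer(),
                      frequency = numeric())
    attr(out, "cumulativeFrequency") <- 0
    return(out)
  }
  df <- do.call(rbind, rows)
  key <- paste(df$type, df$size, df$psStart, df$psEnd, df$seq, sep = "|")
  agg <- tapply(df$count, key, sum)
  first <- !duplicated(key)
  out <- df[first, c("type", "size", "psStart", "psEnd", "seq")]
  out$count <- as.integer(agg[key[first]])
  out$frequency <- out$count / classified$nRetained
  out <- out[order(-out$count, out$psStart), ]
  rownames(out) <- NULL
  attr(out, "cumulativeFrequency") <- sum(out$frequency)
  out
}

#' Quantify cytosine deamination
#'
#' Reads the C>T, C>G and C>A frequencies at the named cytosine positions
#' off a position-frequency table.
#'
#' @param table a [PositionFrequencyTable-class].
#' @param locus an [AmpliconLocus-class].
#' @return data.frame with `label`, `position`, `substitution`,
#'   `frequency`.
#' @export
quantifyCytosineDeamination <- function(table, locus) {
  np <- locus@namedPositions
  cPos <- np[startsWith(names(np), "C")]
  f <- baseFrequencies(table)
  rows <- lapply(names(cPos), function(lab) {
    p <- cPos[[lab]]
    if (table@ref[p] != "C")
      stop("named position ", lab, " is not a C in the reference")
    data.frame(label = lab, position = p,
               substitution = c("C>T", "C>G", "C>A"),
               frequency = unname(f[p, c("T", "G", "A")]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag positions above control background
#'
#' A (position, base) frequency in the post-treatment table is flagged
#' when it exceeds `mean(controls) + 2 * sd(controls)`; with a single
#' control table the rule degenerates to exceeding twice the control
#' value.
#'
#' @param post a [PositionFrequencyTable-class].
#' @param controls list of control [PositionFrequencyTable-class] objects
#'   (e.g. pre-treatment samples).
#' @return data.frame with `position`, `base`, `frequency`, `threshold`,
#'   `flagged`; reference bases are skipped.
#' @export
flagAboveBackground <- function(post, controls) {
  if (!length(controls)) stop("at least one control table is required")
  fPost <- baseFrequencies(post)
  fCtrl <- lapply(controls, baseFrequencies)
  rows <- list()
  for (p in seq_len(nrow(fPost))) {
    for (b in .BASES) {
      if (b == post@ref[p]) next
      ctrl <- vapply(fCtrl, function(m) m[p, b], numeric(1))
      thr <- if (length(ctrl) == 1L) 2 * ctrl else
        mean(ctrl) + 2 * stats::sd(ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, base = b, frequency = fPost[p, b],
        threshold = thr, flagged = fPost[p, b] > thr)
    }
  }
  do.call(rbind, rows)
}

#' Summarize editing over a timecourse
#'
#' @param samples named list of [PositionFrequencyTable-class] objects,
#'   one per timepoint, in temporal order (names are the timepoint
#'   labels).
#' @param locus an [AmpliconLocus-class].
#' @return long-format data.frame with `timepoint`, `label`, `position`,
#'   `frequency` (non-reference frequency at each named position),
#'   preserving input order.
#' @export
summarizeTimecourse <- function(samples, locus) {
  if (!length(samples))
    return(data.frame(timepoint = character(), label = character(),
                      position = integer(), frequency = numeric()))
  labs <- names(samples)
  if (is.null(labs) || anyDuplicated(labs))
    stop("samples must be uniquely named by timepoint")
  np <- locus@namedPositions
  rows <- lapply(labs, function(tp) {
    er <- errorRates(samples[[tp]])
    data.frame(timepoint = tp, label = names(np), position = unname(np),
               frequency = unname(er[np]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$timepoint <- factor(out$timepoint, levels = labs)
  out
}
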
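#' Simulation configuration for amplicon reads
#'
#' Defines the generative model for one amplicon sequencing sample: a
#' population of edited alleles (A-to-G edits with A12 linked to A9,
#' low-frequency cytosine deamination, and whole-allele indels), sequenced
#' as overlapping read pairs with independent per-base substitution errors
#' and an independent low-quality-base process.
#'
#' The A12 linkage is parameterised as
#' `P(A12) = editRateA9 * condRateA12GivenA9 +
#' (1 - editRateA9) * marginalRateA12`, so setting `marginalRateA12 = 0`
#' makes A12 edits occur exclusively on A9-edited alleles.
#'
#' @param locus an [AmpliconLocus-class]; defaults to [hbbLocus()].
#' @param editRateA9 allele fraction carrying the on-target surrogate A9
#'   edit.
#' @param condRateA12GivenA9 probability of an A12 edit on an A9-edited
#'   allele.
#' @param marginalRateA12 probability of an A12 edit on an allele without
#'   the A9 edit.
#' @param editRateA16,editRateA18 independent bystander edit rates.
#' @param cytosineRates named list (by position label, e.g. `"C5"`) of
#'   named numeric vectors of per-substitution rates
#'   (`C>T`, `C>G`, `C>A`).
#' @param indelSpecs list of indel specifications, each a list with
#'   `type` (`"duplication"`, `"deletion"` or `"insertion"`), `start`
#'   (protospacer position), `size` (bp), `frequency` (allele fraction)
#'   and, for insertions, `seq`.
#' @param perBaseError substitution error probability per sequenced base.
#' @param lowQualityRate probability that a base is emitted at Phred 2
#'   (errors themselves keep Phred 37, so quality does not reveal them).
#' @param depth number of read pairs.
#' @param readLength bases per read.
#' @param paired emit overlapping pairs (`TRUE`) or pre-merged single
#'   reads (`FALSE`).
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @return a validated configuration list of class `abequant_sim_config`.
#' @seealso [simulateAmpliconReads()]
#' @export
simConfig <- function(locus = hbbLocus(),
                      editRateA9 = 0.6,
                      condRateA12GivenA9 = 0.08,
                      marginalRateA12 = 0,
                      editRateA16 = 5e-4,
                      editRateA18 = 5e-4,
                      cytosineRates = list(
                        C5 = c("C>T" = 8e-4, "C>G" = 4e-4, "C>A" = 1e-4),
                        C6 = c("C>T" = 8e-4, "C>G" = 4e-4, "C>A" = 1e-4),
                        C8 = c("C>T" = 8e-4, "C>G" = 4e-4, "C>A" = 1e-4)),
                      indelSpecs = list(
                        list(type = "duplication", start = 5L, size = 8L,
                             frequency = 1e-3),
                        list(type = "duplication", start = 6L, size = 7L,
                             frequency = 5e-4)),
                      perBaseError = 1e-3,
                      lowQualityRate = 1e-3,
                      depth = 10000L,
                      readLength = 150L,
                      paired = TRUE,
                      seed = 1L) {
  cfg <- list(locus = locus, editRateA9 = editRateA9,
              condRateA12GivenA9 = condRateA12GivenA9,
              marginalRateA12 = marginalRateA12,
              editRateA16 = editRateA16, editRateA18 = editRateA18,
              cytosineRates = cytosineRates, indelSpecs = indelSpecs,
              perBaseError = perBaseError, lowQualityRate = lowQualityRate,
              depth = as.integer(depth), readLength = as.integer(readLength),
              paired = paired, seed = seed)
  class(cfg) <- "abequant_sim_config"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  rates <- c(cfg$editRateA9, cfg$condRateA12GivenA9, cfg$marginalRateA12,
             cfg$editRateA16, cfg$editRateA18, cfg$perBaseError,
             cfg$lowQualityRate, unlist(cfg$cytosineRates),
             vapply(cfg$indelSpecs, `[[`, numeric(1), "frequency"))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (length(cfg$indelSpecs) &&
      sum(vapply(cfg$indelSpecs, `[[`, numeric(1), "frequency")) > 1)
    stop("indel frequencies must sum to at most 1")
  if (cfg$depth <= 0L) stop("depth must be positive")
  locus <- cfg$locus
  L <- nchar(locus@reference)
  if (cfg$readLength < nchar(locus@primerFwd) + 20L ||
      cfg$readLength < nchar(locus@primerRev) + 20L)
    stop("readLength shorter than primer + protospacer span")
  for (sp in cfg$indelSpecs) {
    refSpan <- range(protospacerToReference(
      locus, c(sp$start, sp$start + sp$size - 1L)))
    if (sp$type != "insertion" && (refSpan[1] < 1L || refSpan[2] > L))
      stop("indel span outside amplicon")
  }
  if (cfg$paired) {
    maxFrag <- L + max(c(0L, vapply(
      cfg$indelSpecs,
      function(sp) if (sp$type == "deletion") 0L else as.integer(sp$size),
      integer(1))))
    if (2L * cfg$readLength - maxFrag < 10L)
      stop("reads must overlap by at least 10 bases on the longest allele")
    if (cfg$readLength > L) stop("readLength exceeds amplicon length")
  }
  for (lab in names(cfg$cytosineRates)) {
    if (!lab %in% names(locus@namedPositions))
      stop("cytosineRates position not among namedPositions: ", lab)
  }
  invisible(cfg)
}

# apply one indel spec to an allele sequence given in reference orientation;
# spans are protospacer positions, converted to reference offsets
.applyIndel <- function(seqChars, spec, locus) {
  span <- sort(protospacerToReference(
    locus, c(spec$start, spec$start + spec$size - 1L)))
  if (spec$type == "duplication") {
    append(seqChars, seqChars[span[1]:span[2]], after = span[2])
  } else if (spec$type == "deletion") {
    seqChars[-(span[1]:span[2])]
  } else if (spec$type == "insertion") {
    ins <- strsplit(if (locus@protospacerStrand == "+") spec$seq
                    else revComp(spec$seq), "")[[1]]
    append(seqChars, ins, after = span[1] - 1L)
  } else stop("unknown indel type: ", spec$type)
}

# sprinkle substitution errors (or low-quality marks) over a vector of
# equal-importance strings; returns modified strings
.sprinkle <- function(strings, rate, replaceFun) {
  lens <- nchar(strings)
  nTot <- sum(lens)
  if (nTot == 0L || rate <= 0) return(strings)
  n <- stats::rbinom(1L, nTot, rate)
  if (n == 0L) return(strings)
  idx <- sample.int(length(strings), n, replace = TRUE, prob = lens)
  pos <- 1L + floor(stats::runif(n) * lens[idx])
  # vectorised substr<- only applies one event per string per round
  while (length(idx)) {
    first <- !duplicated(idx)
    i <- idx[first]; p <- pos[first]
    old <- substring(strings[i], p, p)
    substr(strings[i], p, p) <- replaceFun(old)
    idx <- idx[!first]; pos <- pos[!first]
  }
  strings
}

.randomOtherBase <- function(old) {
  vapply(old, function(b) {
    alt <- setdiff(.BASES, b)
    alt[1L + floor(stats::runif(1) * length(alt))]
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon sequencing reads with ground truth
#'
#' Draws one allele per read pair from the generative model of
#' [simConfig()] (edit pattern, cytosine deamination, whole-allele indel),
#' emits overlapping paired reads (R1 forward, R2 reverse-complement) with
#' Phred-37 base qualities, then overlays independent per-base substitution
#' errors (silent in quality) and a low-quality-base process (Phred 2).
#'
#' @param config a [simConfig()].
#' @return a list with elements `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (or `seq`/`qual` when `config$paired` is `FALSE`) and `truth`, a list
#'   holding the realized allele counts: `positionEdits` (per named
#'   adenine), `cytosine` (per C position and substitution), `indels` (per
#'   spec) and `alleles` (counts per distinct allele pattern, summing to
#'   `depth`).
#' @examples
#' cfg <- simConfig(depth = 200L, seed = 7L)
#' sim <- simulateAmpliconReads(cfg)
#' sim$truth$positionEdits
#' @export
simulateAmpliconReads <- function(config) {
  .validateSimConfig(config)
  locus <- config$locus
  if (!is.null(config$seed)) set.seed(config$seed)
  depth <- config$depth
  nInd <- length(config$indelSpecs)

  indelFreq <- vapply(config$indelSpecs, `[[`, numeric(1), "frequency")
  indel <- if (nInd) {
    sample.int(nInd + 1L, depth, replace = TRUE,
               prob = c(1 - sum(indelFreq), indelFreq)) - 1L
  } else integer(depth)

  a9 <- stats::rbinom(depth, 1L, config$editRateA9)
  a12 <- stats::rbinom(depth, 1L, ifelse(a9 == 1L,
                                         config$condRateA12GivenA9,
                                         config$marginalRateA12))
  a16 <- stats::rbinom(depth, 1L, config$editRateA16)
  a18 <- stats::rbinom(depth, 1L, config$editRateA18)

  cyLabels <- names(config$cytosineRates)
  cySub <- matrix(0L, nrow = depth, ncol = length(cyLabels),
                  dimnames = list(NULL, cyLabels))
  for (lab in cyLabels) {
    r <- config$cytosineRates[[lab]]
    cySub[, lab] <- sample.int(4L, depth, replace = TRUE,
                               prob = c(1 - sum(r), r)) - 1L
  }

  pattern <- cbind(indel = indel, A9 = a9, A12 = a12, A16 = a16, A18 = a18,
                   cySub)
  key <- apply(pattern, 1L, paste, collapse = ":")
  tab <- table(key)
  uniq <- names(tab)

  refChars <- strsplit(locus@reference, "")[[1]]
  np <- locus@namedPositions
  cyAlt <- c("T", "G", "A")  # substitution codes 1..3 = C>T, C>G, C>A
  buildAllele <- function(k) {
    v <- as.integer(strsplit(k, ":", fixed = TRUE)[[1]])
    names(v) <- colnames(pattern)
    s <- refChars
    setPs <- function(s, psPos, base) {
      off <- protospacerToReference(locus, psPos)
      s[off] <- if (locus@protospacerStrand == "+") base
                else unname(.COMP[base])
      s
    }
    for (lab in c("A9", "A12", "A16", "A18"))
      if (v[[lab]] == 1L) s <- setPs(s, np[[lab]], "G")
    for (lab in cyLabels)
      if (v[[lab]] > 0L) s <- setPs(s, np[[lab]], cyAlt[v[[lab]]])
    if (v[["indel"]] > 0L)
      s <- .applyIndel(s, config$indelSpecs[[v[["indel"]]]], locus)
    paste(s, collapse = "")
  }
  alleleSeq <- vapply(uniq, buildAllele, character(1))
  frag <- alleleSeq[match(key, uniq)]

  truth <- list(
    positionEdits = data.frame(
      label = c("A9", "A12", "A16", "A18"),
      count = c(sum(a9[indel == 0L]), sum(a12[indel == 0L]),
                sum(a16[indel == 0L]), sum(a18[indel == 0L])),
      countAllReads = c(sum(a9), sum(a12), sum(a16), sum(a18)),
      stringsAsFactors = FALSE),
    cytosine = do.call(rbind, lapply(cyLabels, function(lab) data.frame(
      label = lab, substitution = paste0("C>", cyAlt),
      count = vapply(1:3, function(s) sum(cySub[, lab] == s & indel == 0L),
                     numeric(1)),
      stringsAsFactors = FALSE))),
    indels = if (nInd) data.frame(
      spec = seq_len(nInd),
      type = vapply(config$indelSpecs, `[[`, character(1), "type"),
      size = vapply(config$indelSpecs, function(s) as.integer(s$size),
                    integer(1)),
      count = vapply(seq_len(nInd), function(i) sum(indel == i),
                     numeric(1)),
      stringsAsFactors = FALSE) else
      data.frame(spec = integer(), type = character(), size = integer(),
                 count = numeric()),
    alleles = data.frame(pattern = uniq, count = as.integer(tab),
                         stringsAsFactors = FALSE),
    depth = depth)
  truth$positionEdits$fraction <- truth$positionEdits$count /
    max(1L, sum(indel == 0L))
  truth$cytosine$fraction <- truth$cytosine$count / max(1L, sum(indel == 0L))
  truth$indels$fraction <- truth$indels$count / depth

  id <- sprintf("read%07d", seq_len(depth))
  if (config$paired) {
    rl <- config$readLength
    fl <- nchar(frag)
    seq1 <- substr(frag, 1L, rl)
    seq2 <- revComp(substring(frag, fl - rl + 1L, fl))
    seq1 <- .sprinkle(seq1, config$perBaseError, .randomOtherBase)
    seq2 <- .sprinkle(seq2, config$perBaseError, .randomOtherBase)
    q <- strrep("F", rl)  # Phred 37
    qual1 <- .sprinkle(rep(q, depth), config$lowQualityRate,
                       function(old) rep("#", length(old)))  # Phred 2
    qual2 <- .sprinkle(rep(q, depth), config$lowQualityRate,
                       function(old) rep("#", length(old)))
    out <- list(id = id, seq1 = seq1, qual1 = qual1,
                seq2 = seq2, qual2 = qual2, truth = truth,
                paired = TRUE)
  } else {
    seqs <- .sprinkle(frag, config$perBaseError, .randomOtherBase)
    qual <- .sprinkle(strrep("F", nchar(seqs)), config$lowQualityRate,
                      function(old) rep("#", length(old)))
    out <- list(id = id, seq = seqs, qual = qual, truth = truth,
                paired = FALSE)
  }
  class(out) <- "abequant_simulated_reads"
  out
}

#' Write simulated reads as FASTQ and the truth table as TSV
#'
#' @param sim result of [simulateAmpliconReads()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
writeSimulatedFastq <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (isTRUE(sim$paired)) {
    p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
    p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
    writeFastq(sim$id, sim$seq1, sim$qual1, p1)
    writeFastq(sim$id, sim$seq2, sim$qual2, p2)
    paths <- c(paths, p1, p2)
  } else {
    p <- file.path(dir, paste0(prefix, ".fastq"))
    writeFastq(sim$id, sim$seq, sim$qual, p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  truthDf <- rbind(
    data.frame(kind = "edit", label = sim$truth$positionEdits$label,
               detail = "A>G", count = sim$truth$positionEdits$count,
               fraction = sim$truth$positionEdits$fraction),
    data.frame(kind = "cytosine", label = sim$truth$cytosine$label,
               detail = sim$truth$cytosine$substitution,
               count = sim$truth$cytosine$count,
               fraction = sim$truth$cytosine$fraction),
    if (nrow(sim$truth$indels)) data.frame(
      kind = "indel", label = paste0("spec", sim$truth$indels$spec),
      detail = paste0(sim$truth$indels$type, sim$truth$indels$size),
      count = sim$truth$indels$count,
      fraction = sim$truth$indels$fraction))
  writeTsv(truthDf, tp)
  invisible(c(paths, tp))
}
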
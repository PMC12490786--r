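#' @useDynLib abequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.BASES <- c("A", "C", "G", "T")

.validDna <- function(x, allowN = TRUE) {
  alpha <- if (allowN) "ACGTN" else "ACGT"
  grepl(sprintf("^[%s]+$", alpha), x)
}

#' AmpliconLocus: a reference amplicon with protospacer placement
#'
#' Holds the wild-type amplicon sequence, the position and strand of the
#' 20-bp protospacer within it, the PAM, the primer pair that brackets the
#' amplicon, and the named protospacer positions (adenines and cytosines)
#' against which all editing outcomes are reported. Protospacer positions
#' are numbered 1-20 from the 5' (PAM-distal) end of the protospacer
#' strand.
#'
#' @slot name locus label.
#' @slot reference wild-type amplicon sequence (uppercase DNA), including
#'   the primer footprints at both ends.
#' @slot protospacerStart 1-based start of the 20-bp protospacer footprint
#'   in reference coordinates.
#' @slot protospacerStrand `"+"` if the protospacer reads off the reference
#'   strand, `"-"` if off its reverse complement.
#' @slot pam 3-mer immediately 3' of the protospacer, on the protospacer
#'   strand.
#' @slot namedPositions named integer vector mapping labels such as `A9` or
#'   `C5` to protospacer positions.
#' @slot primerFwd,primerRev amplification primers; the reference begins
#'   with `primerFwd` and ends with the reverse complement of `primerRev`.
#'
#' @seealso [ampliconLocus()], [hbbLocus()]
#' @export
setClass("AmpliconLocus",
  representation(
    name = "character",
    reference = "character",
    protospacerStart = "integer",
    protospacerStrand = "character",
    pam = "character",
    namedPositions = "integer",
    primerFwd = "character",
    primerRev = "character"
  )
)

setValidity("AmpliconLocus", function(object) {
  msg <- character()
  if (!.validDna(object@reference, allowN = FALSE))
    msg <- c(msg, "reference must be uppercase A/C/G/T")
  L <- nchar(object@reference)
  st <- object@protospacerStart
  if (!(object@protospacerStrand %in% c("+", "-")))
    msg <- c(msg, "protospacerStrand must be '+' or '-'")
  if (st < 1L || st + 19L > L)
    msg <- c(msg, "protospacer footprint outside reference")
  if (nchar(object@pam) != 3L)
    msg <- c(msg, "pam must be a 3-mer")
  np <- object@namedPositions
  if (length(np)) {
    if (is.null(names(np)) || any(!nzchar(names(np))))
      msg <- c(msg, "namedPositions must be named")
    if (any(np < 1L | np > 20L))
      msg <- c(msg, "namedPositions must lie in 1..20")
    ps <- protospacer(object)
    want <- substr(names(np), 1L, 1L)
    have <- substring(ps, np, np)
    bad <- want %in% c("A", "C") & want != have
    if (any(bad))
      msg <- c(msg, sprintf("named position %s is %s in the protospacer",
                            paste(names(np)[bad], collapse = ","),
                            paste(have[bad], collapse = ",")))
  }
  pf <- object@primerFwd; pr <- object@primerRev
  if (nzchar(pf) && substr(object@reference, 1L, nchar(pf)) != pf)
    msg <- c(msg, "reference must begin with primerFwd")
  if (nzchar(pr)) {
    tail <- substr(object@reference, L - nchar(pr) + 1L, L)
    if (tail != revComp(pr))
      msg <- c(msg, "reference must end with reverse complement of primerRev")
  }
  if (length(msg)) msg else TRUE
})

#' PositionFrequencyTable: per protospacer position base counts for a sample
#'
#' The atomic statistical object of the package: for one sample, the count
#' of each base observed at each protospacer position (on the protospacer
#' strand), from which per-position editing frequencies, error rates and
#' deamination frequencies are derived.
#'
#' @slot sample sample identifier.
#' @slot counts integer matrix, positions x bases (columns `A,C,G,T`).
#' @slot ref reference (wild-type) base at each position, protospacer strand.
#'
#' @seealso [tabulatePositions()], [baseFrequencies()], [errorRates()]
#' @export
setClass("PositionFrequencyTable",
  representation(
    sample = "character",
    counts = "matrix",
    ref = "character"
  )
)

setValidity("PositionFrequencyTable", function(object) {
  msg <- character()
  cn <- colnames(object@counts)
  if (is.null(cn) || !identical(cn, .BASES))
    msg <- c(msg, "counts columns must be A,C,G,T")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@ref) != nrow(object@counts))
    msg <- c(msg, "ref must have one base per row of counts")
  if (length(object@ref) && any(!object@ref %in% .BASES))
    msg <- c(msg, "ref bases must be A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' BackgroundModel: pre-treatment sequencing-error background
#'
#' Mean and sample standard deviation of per-position base error rates
#' pooled across all protospacer positions of all depth-passing sites of a
#' subject's pre-treatment panel sample, after exclusion of germline SNP
#' positions. `mean + 2 * sd` is the calling threshold for candidate
#' off-target positions.
#'
#' @slot subject subject identifier.
#' @slot meanError,sdError pooled mean and sample (n-1) SD of error rates.
#' @slot nPositions number of (site, position) pairs in the pool.
#' @slot snpPositions data.frame of excluded SNP positions
#'   (columns `site`, `position`, `base`).
#'
#' @seealso [estimateBackground()], [callCandidatePositions()]
#' @export
setClass("BackgroundModel",
  representation(
    subject = "character",
    meanError = "numeric",
    sdError = "numeric",
    nPositions = "integer",
    snpPositions = "data.frame"
  )
)

setValidity("BackgroundModel", function(object) {
  msg <- character()
  if (object@meanError < 0 || object@sdError < 0)
    msg <- c(msg, "meanError and sdError must be >= 0")
  if (object@nPositions < 2L)
    msg <- c(msg, "background pool must contain at least 2 positions")
  if (length(msg)) msg else TRUE
})

#' TraceProportions: Sanger-style per-position base proportions
#'
#' One clonal colony's trace, represented as the proportion of A/C/G/T
#' signal at each amplicon position (rows sum to 1). Chromatogram peak
#' deconvolution is out of scope; traces enter as proportion tables.
#'
#' @slot id colony identifier.
#' @slot proportions numeric matrix, positions x bases (columns `A,C,G,T`).
#' @slot protospacerStart row index at which the protospacer begins.
#'
#' @seealso [estimateSiteFraction()], [callColonyGenotype()],
#'   [flagTraceIndel()]
#' @export
setClass("TraceProportions",
  representation(
    id = "character",
    proportions = "matrix",
    protospacerStart = "integer"
  )
)

setValidity("TraceProportions", function(object) {
  msg <- character()
  p <- object@proportions
  if (is.null(colnames(p)) || !identical(colnames(p), .BASES))
    msg <- c(msg, "proportions columns must be A,C,G,T")
  if (any(p < -1e-9 | p > 1 + 1e-9))
    msg <- c(msg, "proportions must lie in [0,1]")
  if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-6))
    msg <- c(msg, "proportions rows must sum to 1")
  st <- object@protospacerStart
  if (st < 1L || st + 19L > nrow(p))
    msg <- c(msg, "protospacer must fit within the trace")
  if (length(msg)) msg else TRUE
})

#' FilterReport: read accounting for one processing run
#'
#' Conservation holds by construction: `total = retained + failedMerge +
#' failedQuality + failedPrimer`.
#'
#' @slot total,merged,failedMerge,failedQuality,failedPrimer,retained counts.
#' @seealso [processReads()]
#' @export
setClass("FilterReport",
  representation(
    total = "integer",
    merged = "integer",
    failedMerge = "integer",
    failedQuality = "integer",
    failedPrimer = "integer",
    retained = "integer"
  )
)

setValidity("FilterReport", function(object) {
  msg <- character()
  v <- c(object@total, object@merged, object@failedMerge,
         object@failedQuality, object@failedPrimer, object@retained)
  if (any(v < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (object@total != object@retained + object@failedMerge +
      object@failedQuality + object@failedPrimer)
    msg <- c(msg, "conservation violated: total != retained + failures")
  if (object@merged != object@total - object@failedMerge)
    msg <- c(msg, "merged must equal total - failedMerge")
  if (length(msg)) msg else TRUE
})

#' PanelSample: one multiplexed amplicon panel sample
#'
#' Per-site, per-position base counts for one sequencing sample of a
#' multi-site off-target panel, with the total read count per site used by
#' the depth filter. Counts are stored as a single positions x bases x
#' sites array so that large longitudinal panels stay cheap to handle;
#' [siteTable()] extracts an individual site as a
#' [PositionFrequencyTable-class].
#'
#' @slot subject,timepoint sample labels.
#' @slot isPretreatment `TRUE` for the subject's pre-treatment sample.
#' @slot counts integer array `[position, base, site]` with base columns
#'   `A,C,G,T` and site names on the third dimension.
#' @slot ref character matrix `[position, site]` of reference bases.
#' @slot reads named numeric vector of total reads per site.
#'
#' @seealso [panelSample()], [simulatePanel()], [filterByDepth()]
#' @export
setClass("PanelSample",
  representation(
    subject = "character",
    timepoint = "character",
    isPretreatment = "logical",
    counts = "array",
    ref = "matrix",
    reads = "numeric"
  )
)

setValidity("PanelSample", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msg <- c(msg, "counts must be a 3-d array")
  else {
    if (!identical(dimnames(object@counts)[[2]], .BASES))
      msg <- c(msg, "counts base dimension must be A,C,G,T")
    if (!identical(dim(object@ref), d[c(1L, 3L)]))
      msg <- c(msg, "ref must be positions x sites")
    if (length(object@reads) != d[3L])
      msg <- c(msg, "reads must have one entry per site")
  }
  if (any(object@reads < 0)) msg <- c(msg, "read counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AlignedRead: one global alignment of a read to the amplicon
#'
#' @slot id read identifier.
#' @slot score alignment score.
#' @slot alignedQuery,alignedReference gapped alignment strings
#'   (`-` for gaps); stripping gaps recovers the inputs.
#' @seealso [alignGlobal()]
#' @export
setClass("AlignedRead",
  representation(
    id = "character",
    score = "numeric",
    alignedQuery = "character",
    alignedReference = "character"
  )
)

setValidity("AlignedRead", function(object) {
  if (nchar(object@alignedQuery) != nchar(object@alignedReference))
    return("aligned strings must have equal length")
  TRUE
})
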
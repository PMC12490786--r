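#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revComp("TTCTCCTCAGGAGTCAGATG")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct an AmpliconLocus
#'
#' @param name locus label.
#' @param reference wild-type amplicon sequence (5'->3' on the reference
#'   strand, beginning with the forward primer and ending with the reverse
#'   complement of the reverse primer).
#' @param protospacerStart 1-based start of the protospacer footprint in
#'   `reference`.
#' @param protospacerStrand `"+"` or `"-"`.
#' @param pam PAM 3-mer on the protospacer strand.
#' @param namedPositions named integer vector of tracked protospacer
#'   positions, e.g. `c(A9 = 9, A12 = 12)`.
#' @param primerFwd,primerRev primer sequences.
#' @return an [AmpliconLocus-class] object.
#' @examples
#' locus <- hbbLocus()
#' protospacer(locus)
#' @export
ampliconLocus <- function(name, reference, protospacerStart,
                          protospacerStrand = "+", pam = "NGG",
                          namedPositions = integer(),
                          primerFwd = "", primerRev = "") {
  new("AmpliconLocus",
      name = as.character(name),
      reference = toupper(reference),
      protospacerStart = as.integer(protospacerStart),
      protospacerStrand = protospacerStrand,
      pam = toupper(pam),
      namedPositions = vapply(namedPositions, as.integer, integer(1)),
      primerFwd = toupper(primerFwd),
      primerRev = toupper(primerRev))
}

# synthetic HBB-like amplicon: real protospacer context, primer and filler
# sequence are synthetic
.HBB_REFERENCE <- paste0(
  "ACATTTGCTTCTGACACAAC",                  # forward primer footprint
  "TGTGTTCACTAGCAACCTCAAACAGACACC",        # upstream spacer context
  "TTCTCCTCAGGAGTCAGATG",                  # protospacer (positions 1-20)
  "AGG",                                   # PAM
  "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGT",
  "ACCCTAAGCCTCAGGATTGC"                   # reverse complement of reverse primer
)

#' The built-in synthetic HBB Makassar locus
#'
#' A synthetic amplicon carrying the HBB Makassar-surrogate protospacer
#' `TTCTCCTCAGGAGTCAGATG` on the plus strand with an AGG PAM, bracketed by
#' 20-bp primers. The tracked positions are the on-target surrogate A9, the
#' bystander adenines A12, A16 and A18, and the deamination-prone cytosines
#' C3, C5, C6 and C8.
#'
#' @return an [AmpliconLocus-class].
#' @export
hbbLocus <- function() {
  ampliconLocus(
    name = "HBB_makassar_synthetic",
    reference = .HBB_REFERENCE,
    protospacerStart = 51L,
    protospacerStrand = "+",
    pam = "AGG",
    namedPositions = c(A9 = 9L, A12 = 12L, A16 = 16L, A18 = 18L,
                       C3 = 3L, C5 = 5L, C6 = 6L, C8 = 8L),
    primerFwd = "ACATTTGCTTCTGACACAAC",
    primerRev = "GCAATCCTGAGGCTTAGGGT")
}

#' @rdname AmpliconLocus-class
#' @export
setMethod("protospacer", "AmpliconLocus", function(x) {
  s <- substr(x@reference, x@protospacerStart, x@protospacerStart + 19L)
  if (x@protospacerStrand == "-") revComp(s) else s
})

#' @rdname AmpliconLocus-class
#' @export
setMethod("referenceSequence", "AmpliconLocus", function(x) x@reference)

#' @rdname AmpliconLocus-class
#' @param object an `AmpliconLocus`.
#' @export
setMethod("show", "AmpliconLocus", function(object) {
  cat("AmpliconLocus:", object@name, "\n",
      " reference: ", nchar(object@reference), " bp\n",
      " protospacer: ", protospacer(object), " (", object@protospacerStrand,
      ", start ", object@protospacerStart, ", PAM ", object@pam, ")\n",
      " named positions: ",
      paste(names(object@namedPositions), collapse = " "), "\n", sep = "")
})

#' Map protospacer positions to reference coordinates
#'
#' Protospacer positions run 1-20 from the 5' end of the protospacer
#' strand; on a minus-strand locus they therefore run antiparallel to the
#' reference.
#'
#' @param locus an [AmpliconLocus-class].
#' @param positions protospacer positions (1-20).
#' @return 1-based reference offsets.
#' @export
protospacerToReference <- function(locus, positions = 1:20) {
  if (locus@protospacerStrand == "+") locus@protospacerStart + positions - 1L
  else locus@protospacerStart + 20L - positions
}

# reference between (exclusive of) the primer footprints, still on the
# reference strand
.innerReference <- function(locus) {
  L <- nchar(locus@reference)
  substr(locus@reference, nchar(locus@primerFwd) + 1L,
         L - nchar(locus@primerRev))
}

# protospacer start relative to the inner (primer-trimmed) reference
.innerProtospacerStart <- function(locus) {
  locus@protospacerStart - nchar(locus@primerFwd)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# base on the protospacer strand at protospacer position p, given a vector
# of reference-strand bases at the mapped offsets
.toProtospacerStrand <- function(bases, locus) {
  if (locus@protospacerStrand == "+") bases else unname(.COMP[bases])
}

#' Read or write a locus definition as YAML
#'
#' The YAML carries the fields of [ampliconLocus()] verbatim.
#'
#' @param path file path.
#' @param locus an [AmpliconLocus-class].
#' @return `readLocusYaml` returns an [AmpliconLocus-class];
#'   `writeLocusYaml` returns `path` invisibly.
#' @export
readLocusYaml <- function(path) {
  y <- yaml::read_yaml(path)
  np <- unlist(y$named_positions)
  ampliconLocus(name = y$name, reference = y$reference,
                protospacerStart = y$protospacer_start,
                protospacerStrand = y$protospacer_strand %||% "+",
                pam = y$pam %||% "NNN",
                namedPositions = if (length(np)) np else integer(),
                primerFwd = y$primer_fwd %||% "",
                primerRev = y$primer_rev %||% "")
}

#' @rdname readLocusYaml
#' @export
writeLocusYaml <- function(locus, path) {
  y <- list(name = locus@name,
            reference = locus@reference,
            protospacer_start = locus@protospacerStart,
            protospacer_strand = locus@protospacerStrand,
            pam = locus@pam,
            named_positions = as.list(locus@namedPositions),
            primer_fwd = locus@primerFwd,
            primer_rev = locus@primerRev)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
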
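# Independent oracles and fixture builders (kept free of the package's
# own kernels so the dual-route checks stay meaningful).

BASES <- c("A", "C", "G", "T")

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

revCompOracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) paste(rev(comp[strsplit(s, "")[[1]]]),
                              collapse = ""), character(1),
         USE.NAMES = FALSE)
}

# plain-R affine-gap global DP (Gotoh), score only; end gaps penalized,
# first gap base costs `open`, later bases `ext`
nwScoreOracle <- function(q, r, match = 5, mismatch = -4, open = 10,
                          ext = 0.5) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in query
  Y <- matrix(NEG, n + 1, m + 1)   # gap in reference
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- -(open + (j - 2) * ext)
  if (n >= 1) for (i in 2:(n + 1)) Y[i, 1] <- -(open + (i - 2) * ext)
  s <- function(a, b) if (a == "N" || b == "N") 0 else if (a == b) match else mismatch
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      M[i, j] <- s(qc[i - 1], rc[j - 1]) +
        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - open,
                     X[i, j - 1] - ext)
      Y[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - open,
                     Y[i - 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive position-by-position mismatch scan, both strands; returns a
# data.frame keyed like the enumerator's output
enumerateOracle <- function(ref, spacer, maxMismatch = 4L,
                            pamPattern = "NNN") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", N = BASES,
                R = c("A", "G"), Y = c("C", "T"))
  pamOk <- function(pams) {
    pat <- strsplit(pamPattern, "")[[1]]
    ok <- rep(TRUE, length(pams))
    for (i in seq_along(pat))
      ok <- ok & substring(pams, i, i) %in% iupac[[pat[i]]]
    ok
  }
  spChars <- strsplit(spacer, "")[[1]]
  out <- list()
  for (contig in names(ref)) {
    seqc <- strsplit(ref[[contig]], "")[[1]]
    L <- length(seqc)
    if (L < 23) next
    # plus strand: windows [i, i+19], PAM [i+20, i+22]
    starts <- seq_len(L - 22L)
    mm <- rep(0L, length(starts))
    for (p in 1:20) mm <- mm + (seqc[starts + p - 1L] != spChars[p])
    pams <- vapply(starts, function(i) paste(seqc[(i + 20):(i + 22)],
                                             collapse = ""), character(1))
    keep <- mm <= maxMismatch & pamOk(pams)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = starts[keep], strand = "+",
        mismatches = mm[keep], stringsAsFactors = FALSE)
    # minus strand: spacer matches revcomp(window [i, i+19]), PAM at
    # [i-3, i-1] revcomp'd
    starts <- 4:(L - 19L)
    rcSp <- strsplit(revCompOracle(spacer), "")[[1]]
    mm <- rep(0L, length(starts))
    for (p in 1:20) mm <- mm + (seqc[starts + p - 1L] != rcSp[p])
    pams <- vapply(starts, function(i) revCompOracle(
      paste(seqc[(i - 3):(i - 1)], collapse = "")), character(1))
    keep <- mm <= maxMismatch & pamOk(pams)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = starts[keep], strand = "-",
        mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand), ]
}

# a random contig with copies of the spacer planted at known offsets,
# carrying 0..5 mismatches, on both strands, each followed by a PAM
plantSites <- function(len, spacer, nPlants = 24L) {
  seqc <- sample(BASES, len, replace = TRUE)
  offsets <- sort(sample(seq(30L, len - 60L, by = 60L), nPlants))
  for (k in seq_along(offsets)) {
    site <- strsplit(spacer, "")[[1]]
    nmm <- k %% 6L
    if (nmm > 0) {
      pos <- sample(20L, nmm)
      for (p in pos) site[p] <- sample(setdiff(BASES, site[p]), 1L)
    }
    cassette <- c(site, sample(BASES, 3L, replace = TRUE))
    if (k %% 2L == 0L)
      cassette <- rev(c(T = "A", A = "T", G = "C", C = "G")[cassette])
    seqc[offsets[k]:(offsets[k] + 22L)] <- cassette
  }
  paste(seqc, collapse = "")
}

# MIT-style score computed straight from the published formula, kept
# separate from the package implementation
mitScoreOracle <- function(pos, w) {
  m <- length(pos)
  if (m == 0) return(100)
  t1 <- prod(1 - w[pos])
  t2 <- if (m < 2) 1 else {
    d <- mean(dist(pos))
    1 / (((19 - d) / 19) * 4 + 1)
  }
  100 * t1 * t2 / m^2
}

# build an artificial classified-read set without going through the
# aligner: a quick way to feed the tabulators known inputs
makeReads <- function(locus, spec) {
  # spec: list of list(edits=character vector of named positions, n=count)
  inner <- strsplit(abequant:::.innerReference(locus), "")[[1]]
  psStart <- abequant:::.innerProtospacerStart(locus)
  np <- locus@namedPositions
  out <- character()
  for (s in spec) {
    seqc <- inner
    for (lab in s$edits) {
      off <- protospacerToReference(locus, np[[lab]]) -
        nchar(locus@primerFwd)
      seqc[off] <- if (locus@protospacerStrand == "+") "G" else "C"
    }
    out <- c(out, rep(paste(seqc, collapse = ""), s$n))
  }
  out
}
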
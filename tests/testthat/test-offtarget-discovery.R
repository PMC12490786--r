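SPACER <- "TTCTCCTCAGGAGTCAGATG"

test_that("the specificity score matches the published formula", {
  w <- hsuWeights()
  expect_equal(scoreMit(integer()), 100)
  expect_equal(scoreMit(1L), 100)          # weight 0 at position 1
  expect_equal(scoreMit(3L), 100 * (1 - 0.014))
  # frozen hand-computed two-mismatch case: positions 6 and 14,
  # dbar = 8 -> distance term 1 / (((19-8)/19)*4 + 1), m^2 = 4
  expect_equal(scoreMit(c(6L, 14L)),
               100 * (1 - 0.395) * (1 - 0.851) /
                 ((((19 - 8) / 19) * 4 + 1)) / 4)
  # random cases against the independently coded formula
  set.seed(61)
  for (i in 1:25) {
    pos <- sort(sample(20L, sample(0:4, 1)))
    expect_equal(scoreMit(pos), mitScoreOracle(pos, w))
  }
})

test_that("adding a weighted mismatch strictly lowers the score", {
  base <- c(2L, 8L)      # zero-weight positions
  expect_equal(scoreMit(base), 100 / (((19 - 6) / 19 * 4 + 1)) / 4)
  more <- c(base, 14L)
  expect_lt(scoreMit(more), scoreMit(base))
  # score is 100 iff no mismatches (weighted positions always reduce it)
  for (p in which(hsuWeights() > 0)) expect_lt(scoreMit(p), 100)
})

test_that("exact and reverse-complement embeddings are found", {
  flank <- strrep("A", 30)
  ref <- c(chr1 = paste0(flank, SPACER, "TGG", flank))
  hits <- enumerateCandidateSites(ref, SPACER, "NNN", 0L)
  expect_equal(length(hits), 1L)
  expect_equal(as.character(BiocGenerics::strand(hits)), "+")
  expect_equal(BiocGenerics::start(hits), 31L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$score, 100)

  refRc <- c(chr1 = paste0(flank, revComp(paste0(SPACER, "TGG")), flank))
  hitsRc <- enumerateCandidateSites(refRc, SPACER, "NNN", 0L)
  expect_equal(length(hitsRc), 1L)
  expect_equal(as.character(BiocGenerics::strand(hitsRc)), "-")
  expect_equal(hitsRc$siteSeq, SPACER)
  expect_equal(hitsRc$pam, "TGG")
})

test_that("the PAM pattern constrains hits", {
  flank <- strrep("A", 30)
  ref <- c(chr1 = paste0(flank, SPACER, "TAA", flank))
  expect_equal(length(enumerateCandidateSites(ref, SPACER, "NGG", 0L)), 0L)
  expect_equal(length(enumerateCandidateSites(ref, SPACER, "NNN", 0L)), 1L)
  # PAM running off the contig end is skipped
  ref2 <- c(chr1 = paste0(flank, SPACER))
  expect_equal(length(enumerateCandidateSites(ref2, SPACER, "NNN", 0L)), 0L)
})

test_that("enumeration equals the naive oracle scan on a planted contig", {
  set.seed(62)
  ref <- c(chrA = plantSites(20000L, SPACER, nPlants = 18L))
  for (mm in c(0L, 2L, 4L)) {
    mine <- enumerateCandidateSites(ref, SPACER, "NNN", mm)
    oracle <- enumerateOracle(ref, SPACER, mm, "NNN")
    mineKey <- paste(as.character(GenomicRanges::seqnames(mine)),
                     BiocGenerics::start(mine),
                     as.character(BiocGenerics::strand(mine)))
    oracleKey <- paste(oracle$contig, oracle$start, oracle$strand)
    expect_setequal(mineKey, oracleKey)
    expect_equal(mine$mismatches[match(oracleKey, mineKey)],
                 oracle$mismatches)
  }
})

test_that("mismatch counts agree with the site sequences", {
  set.seed(63)
  ref <- c(chrA = plantSites(8000L, SPACER, nPlants = 10L))
  hits <- enumerateCandidateSites(ref, SPACER, "NNN", 4L)
  sp <- strsplit(SPACER, "")[[1]]
  for (i in seq_along(hits)) {
    d <- sum(strsplit(hits$siteSeq[i], "")[[1]] != sp)
    expect_equal(hits$mismatches[i], d)
  }
})

test_that("reverse-complementing the reference swaps strands only", {
  set.seed(64)
  ref <- c(chrA = plantSites(6000L, SPACER, nPlants = 8L))
  fwd <- enumerateCandidateSites(ref, SPACER, "NNN", 4L)
  rev <- enumerateCandidateSites(c(chrA = revComp(ref[["chrA"]])),
                                 SPACER, "NNN", 4L)
  expect_equal(length(fwd), length(rev))
  expect_setequal(fwd$siteSeq, rev$siteSeq)
  expect_setequal(fwd$pam, rev$pam)
  L <- nchar(ref[["chrA"]])
  mapped <- sort(L - BiocGenerics::end(rev) + 1L)
  expect_equal(sort(BiocGenerics::start(fwd)), mapped)
})

test_that("panel selection honors the mismatch tiers and is deterministic", {
  set.seed(65)
  ref <- c(chrA = plantSites(30000L, SPACER, nPlants = 30L))
  sites <- enumerateCandidateSites(ref, SPACER, "NNN", 4L)
  nLow <- sum(sites$mismatches < 4L)
  k <- nLow + 3L
  sel <- rankAndSelect(sites, k)
  expect_equal(length(sel), min(k, length(sites)))
  expect_true(all(sites$siteSeq[sites$mismatches < 4L] %in% sel$siteSeq))
  kept4 <- sel$score[sel$mismatches == 4L]
  dropped4 <- setdiff(sites$score[sites$mismatches == 4L], kept4)
  if (length(dropped4) && length(kept4))
    expect_gte(min(kept4), max(dropped4))
  expect_error(rankAndSelect(sites, nLow - 1L), "cannot honor")
  # same input, same output
  expect_identical(as.data.frame(rankAndSelect(sites, k)),
                   as.data.frame(sel))
})

test_that("site export writes BED6 and TSV with consistent coordinates", {
  flank <- strrep("A", 30)
  ref <- c(chr1 = paste0(flank, SPACER, "TGG", flank))
  hits <- enumerateCandidateSites(ref, SPACER, "NNN", 0L)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  exportCandidateSites(hits, bed, tsv)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 30L)          # 0-based start
  expect_equal(b$V3, 50L)
  t <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(t$start, 31L)       # 1-based inclusive
  expect_equal(t$siteSeq, SPACER)
})
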
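test_that("an exact overlap merges to the underlying fragment", {
  set.seed(21)
  frag <- randomDna(70)
  r1 <- substr(frag, 1, 50)
  r2 <- revComp(substr(frag, 21, 70))
  m <- mergeReadPair(r1, strrep("F", 50), r2, strrep("F", 50))
  expect_true(m$merged)
  expect_equal(m$overlap, 30)
  expect_identical(m$seq, frag)
  expect_equal(nchar(m$seq), 50 + 50 - 30)
})

test_that("the higher-quality base wins inside the overlap", {
  set.seed(22)
  frag <- randomDna(40)
  r1 <- substr(frag, 1, 30)
  r2true <- substr(frag, 11, 40)
  # corrupt one overlap base on read 2 and mark it low quality
  r2c <- r2true
  substr(r2c, 5, 5) <- setdiff(BASES, substr(r2true, 5, 5))[1]
  q2 <- strrep("F", 30); substr(q2, 5, 5) <- "#"   # Phred 2
  m <- mergeReadPair(r1, strrep("F", 30), revComp(r2c),
                     paste(rev(strsplit(q2, "")[[1]]), collapse = ""))
  expect_true(m$merged)
  expect_identical(m$seq, frag)   # the Q37 base from read 1 won
})

test_that("disjoint reads fail to merge as a typed outcome", {
  m <- mergeReadPair(strrep("A", 20), strrep("F", 20),
                     strrep("C", 20), strrep("F", 20))
  expect_false(m$merged)
})

test_that("merging is orientation-symmetric", {
  set.seed(23)
  for (i in 1:10) {
    frag <- randomDna(60)
    r1 <- substr(frag, 1, 40); r2 <- revComp(substr(frag, 21, 60))
    q1 <- strrep("F", 40); q2 <- strrep("F", 40)
    m1 <- mergeReadPair(r1, q1, r2, q2)
    # swapping the roles of the two reads reconstructs the fragment on
    # the opposite strand
    m2 <- mergeReadPair(r2, q2, r1, q1)
    expect_identical(m1$seq, revComp(m2$seq))
    expect_equal(m1$overlap, m2$overlap)
  }
})

test_that("the quality filter is strict at more-than-two low-quality bases", {
  q <- strrep("F", 50)
  expect_true(filterByQuality(q))
  three <- q; substr(three, 1, 3) <- "###"
  expect_false(filterByQuality(three))                 # 3 at Phred 2
  two19 <- q; substr(two19, 1, 2) <- "44"              # Phred 19, boundary
  expect_true(filterByQuality(two19))
  # Phred 20 is not low quality under the default threshold
  many20 <- strrep("5", 50)
  expect_true(filterByQuality(many20))
})

test_that("primer anchoring tolerates two substitutions and rejects three", {
  locus <- hbbLocus()
  ref <- referenceSequence(locus)
  a <- anchorPrimers(ref, locus@primerFwd, locus@primerRev)
  expect_true(a$anchored)
  expect_identical(a$seq, abequant:::.innerReference(locus))
  mut <- function(s, positions) {
    for (p in positions) substr(s, p, p) <- setdiff(BASES, substr(s, p, p))[1]
    s
  }
  expect_true(anchorPrimers(mut(ref, c(2, 5)), locus@primerFwd,
                            locus@primerRev)$anchored)
  expect_false(anchorPrimers(mut(ref, c(2, 5, 9)), locus@primerFwd,
                             locus@primerRev)$anchored)
})

test_that("reverse-orientation reads are anchored onto the reference strand", {
  locus <- hbbLocus()
  a <- anchorPrimers(revComp(referenceSequence(locus)), locus@primerFwd,
                     locus@primerRev)
  expect_true(a$anchored)
  expect_equal(a$orientation, "-")
  expect_identical(a$seq, abequant:::.innerReference(locus))
})

test_that("a palindromic-primer amplicon raises an ambiguity error", {
  fwd <- "ACGTACGT"
  rev <- revComp(fwd)        # makes both orientations match
  mid <- strrep("A", 30)
  read <- paste0(fwd, mid, revComp(rev))
  expect_error(anchorPrimers(read, fwd, rev), "orientation")
})

test_that("error-free synthetic pairs all merge and anchor, conserving counts", {
  cfg <- simConfig(depth = 400L, perBaseError = 0, lowQualityRate = 0,
                   indelSpecs = list(), seed = 24L)
  sim <- simulateAmpliconReads(cfg)
  pr <- processReads(sim$seq1, sim$qual1, sim$seq2, sim$qual2, cfg$locus)
  rep <- pr$report
  expect_equal(rep@retained, 400L)
  expect_equal(rep@failedMerge + rep@failedQuality + rep@failedPrimer, 0L)
  expect_equal(rep@total,
               rep@retained + rep@failedMerge + rep@failedQuality +
                 rep@failedPrimer)
})

test_that("the filter report conserves reads under realistic noise", {
  cfg <- simConfig(depth = 600L, perBaseError = 0.01,
                   lowQualityRate = 0.01, seed = 25L)
  sim <- simulateAmpliconReads(cfg)
  pr <- processReads(sim$seq1, sim$qual1, sim$seq2, sim$qual2, cfg$locus)
  rep <- pr$report
  expect_equal(rep@total, 600L)
  expect_equal(rep@total,
               rep@retained + rep@failedMerge + rep@failedQuality +
                 rep@failedPrimer)
  expect_gt(rep@failedQuality, 0L)   # the low-quality process is active
  expect_equal(length(pr$seq), rep@retained)
})
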
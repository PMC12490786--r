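locusP <- hbbLocus()
innerP <- abequant:::.innerReference(locusP)

alignTo <- function(q, locus) alignGlobal(q, abequant:::.innerReference(locus))

test_that("read classification follows the grouping contract", {
  expect_equal(classifyRead(alignTo(innerP, locusP), locusP)$class, "WT")

  edited <- innerP
  off <- protospacerToReference(locusP, 9L) - nchar(locusP@primerFwd)
  substr(edited, off, off) <- "G"
  r <- classifyRead(alignTo(edited, locusP), locusP)
  expect_equal(r$class, "EDIT")
  expect_equal(r$edits, "A9")

  # EDIT takes precedence over an incidental substitution elsewhere
  both <- edited
  substr(both, 5, 5) <- setdiff(BASES, substr(both, 5, 5))[1]
  expect_equal(classifyRead(alignTo(both, locusP), locusP)$class, "EDIT")

  # substitution inside the protospacer but not an A-to-G
  sub <- innerP
  off3 <- protospacerToReference(locusP, 3L) - nchar(locusP@primerFwd)
  substr(sub, off3, off3) <- "T"
  expect_equal(classifyRead(alignTo(sub, locusP), locusP)$class,
               "SUBST_OTHER")

  # 8-bp duplication inside the protospacer
  psRef <- protospacerToReference(locusP, 5L) - nchar(locusP@primerFwd)
  dup <- paste0(substr(innerP, 1, psRef + 7),
                substr(innerP, psRef, psRef + 7),
                substring(innerP, psRef + 8))
  expect_equal(classifyRead(alignTo(dup, locusP), locusP)$class, "INDEL")
})

test_that("position frequencies are exact on constructed mixtures", {
  reads <- makeReads(locusP, list(list(edits = "A9", n = 600),
                                  list(edits = character(), n = 400)))
  q <- quantifyAmplicon(reads, locusP, "mix")
  f <- baseFrequencies(q$positions)
  expect_equal(unname(f[9, "G"]), 0.6)
  expect_equal(unname(f[9, "A"]), 0.4)
  expect_equal(unname(f[12, "A"]), 1)
  expect_equal(unname(positionCoverage(q$positions)), rep(1000, 20))
})

test_that("classification partitions the retained reads", {
  cfg <- simConfig(depth = 4000L, seed = 41L)
  sim <- simulateAmpliconReads(cfg)
  pr <- processReads(sim$seq1, sim$qual1, sim$seq2, sim$qual2, cfg$locus)
  q <- quantifyAmplicon(pr$seq, cfg$locus)
  expect_equal(sum(q$classCounts), q$nRetained)
  expect_equal(sum(q$combinations$count), q$nRetained)
  expect_equal(sum(q$combinations$fraction), 1)
})

test_that("combination recovery matches a configured mixture", {
  reads <- makeReads(locusP, list(
    list(edits = "A9", n = 5000),
    list(edits = c("A9", "A12"), n = 2000),
    list(edits = character(), n = 3000)))
  q <- quantifyAmplicon(reads, locusP)
  comb <- q$combinations
  get <- function(lab) comb$fraction[comb$combination == lab]
  expect_equal(get("A9"), 0.5)
  expect_equal(get("A9+A12"), 0.2)
  expect_equal(get("WT"), 0.3)
  expect_equal(length(comb$fraction[comb$combination == "A12"]), 0L)
})

test_that("indel catalog aggregates distinct alleles and sums frequencies", {
  psRef <- protospacerToReference(locusP, 5L) - nchar(locusP@primerFwd)
  del1 <- paste0(substr(innerP, 1, psRef - 1), substring(innerP, psRef + 2))
  del2 <- paste0(substr(innerP, 1, psRef + 3), substring(innerP, psRef + 9))
  reads <- c(rep(innerP, 94), rep(del1, 4), rep(del2, 2))
  q <- quantifyAmplicon(reads, locusP)
  ind <- q$indels
  expect_equal(nrow(ind), 2)
  expect_setequal(ind$type, "deletion")
  expect_equal(sum(ind$frequency), attr(ind, "cumulativeFrequency"))
  expect_equal(attr(ind, "cumulativeFrequency"), 6 / 100)
  # no indel reads -> empty catalog
  q0 <- quantifyAmplicon(rep(innerP, 10), locusP)
  expect_equal(nrow(q0$indels), 0)
  expect_equal(attr(q0$indels, "cumulativeFrequency"), 0)
})

test_that("duplications are recognized also on edited alleles", {
  off <- protospacerToReference(locusP, 9L) - nchar(locusP@primerFwd)
  psRef <- protospacerToReference(locusP, 5L) - nchar(locusP@primerFwd)
  edited <- innerP
  substr(edited, off, off) <- "G"
  dup <- paste0(substr(edited, 1, psRef + 7),
                substr(edited, psRef, psRef + 7),
                substring(edited, psRef + 8))
  q <- quantifyAmplicon(c(rep(innerP, 99), dup), locusP)
  expect_equal(q$indels$type, "duplication")
  expect_equal(q$indels$size, 8L)
})

test_that("indel frequencies use all retained reads as denominator", {
  psRef <- protospacerToReference(locusP, 5L) - nchar(locusP@primerFwd)
  del <- paste0(substr(innerP, 1, psRef - 1), substring(innerP, psRef + 2))
  reads <- c(rep(innerP, 90), rep(del, 10))
  q <- quantifyAmplicon(reads, locusP)
  expect_equal(q$indels$frequency, 0.1)
  # while position coverage excludes the indel reads
  expect_equal(unname(positionCoverage(q$positions))[1], 90)
})

test_that("cytosine deamination is read off the table per substitution", {
  c5 <- protospacerToReference(locusP, 5L) - nchar(locusP@primerFwd)
  c5t <- innerP; substr(c5t, c5, c5) <- "T"
  reads <- c(rep(innerP, 992), rep(c5t, 8))
  q <- quantifyAmplicon(reads, locusP)
  cy <- q$cytosine
  expect_equal(cy$frequency[cy$label == "C5" & cy$substitution == "C>T"],
               0.008)
  expect_true(all(cy$frequency[cy$label == "C3"] == 0))
  # error-free wild-type data is all zero
  q0 <- quantifyAmplicon(rep(innerP, 50), locusP)
  expect_true(all(q0$cytosine$frequency == 0))
})

test_that("background flagging uses mean plus two SD of the controls", {
  mkTable <- function(gFreq, n = 10000) {
    reads <- makeReads(locusP, list(
      list(edits = "A9", n = round(gFreq * n)),
      list(edits = character(), n = n - round(gFreq * n))))
    quantifyAmplicon(reads, locusP)$positions
  }
  post <- mkTable(0.25)
  controls <- list(mkTable(0.001), mkTable(0.0015), mkTable(0.0005))
  fl <- flagAboveBackground(post, controls)
  expect_true(fl$flagged[fl$position == 9 & fl$base == "G"])
  # a position equal to the controls is not flagged
  same <- flagAboveBackground(controls[[1]], controls)
  expect_false(any(same$flagged[same$position == 9 & same$base == "G"]))
})

test_that("timecourse summaries preserve order and reject duplicates", {
  tables <- lapply(c(0.45, 0.38, 0.31, 0.25), function(f) {
    reads <- makeReads(locusP, list(
      list(edits = "A9", n = round(f * 2000)),
      list(edits = character(), n = 2000 - round(f * 2000))))
    quantifyAmplicon(reads, locusP)$positions
  })
  names(tables) <- paste0("d", c(30, 60, 90, 180))
  tc <- summarizeTimecourse(tables, locusP)
  a9 <- tc$frequency[tc$label == "A9"]
  expect_true(all(diff(a9) < 0))        # the configured decline
  expect_equal(levels(tc$timepoint), names(tables))
  expect_error(summarizeTimecourse(stats::setNames(tables[c(1, 1)],
                                                   c("a", "a")), locusP),
               "uniquely")
  empty <- summarizeTimecourse(list(), locusP)
  expect_equal(nrow(empty), 0)
})

test_that("a minus-strand locus yields identical summaries", {
  plus <- locusP
  ref <- revComp(referenceSequence(plus))
  L <- nchar(ref)
  minus <- ampliconLocus("minus", ref, protospacerStart = L - 70L + 1L,
                         protospacerStrand = "-", pam = plus@pam,
                         namedPositions = plus@namedPositions,
                         primerFwd = plus@primerRev,
                         primerRev = plus@primerFwd)
  reads <- makeReads(plus, list(list(edits = c("A9", "A12"), n = 60),
                                list(edits = character(), n = 40)))
  qPlus <- quantifyAmplicon(reads, plus)
  # the same molecules read on the opposite strand
  qMinus <- quantifyAmplicon(revComp(reads), minus)
  expect_equal(baseFrequencies(qPlus$positions),
               baseFrequencies(qMinus$positions))
  expect_equal(qPlus$combinations, qMinus$combinations)
  expect_equal(qPlus$cytosine, qMinus$cytosine)
})
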
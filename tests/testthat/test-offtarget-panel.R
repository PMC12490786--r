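# Small hand-built panels ----------------------------------------------

mkCounts <- function(ref, total, alt = NULL) {
  # ref: 20-mer site sequence; alt: list(position=, base=, count=)
  m <- matrix(0L, 20, 4, dimnames = list(1:20, BASES))
  refIdx <- match(strsplit(ref, "")[[1]], BASES)
  m[cbind(1:20, refIdx)] <- total
  for (a in alt) {
    m[a$position, a$base] <- m[a$position, a$base] + a$count
    m[a$position, refIdx[a$position]] <- m[a$position, refIdx[a$position]] -
      a$count
  }
  m
}

SITE1 <- "TTCTCCTCAGGAGTCAGATG"
SITE2 <- "ATCTCCTCAGGAGTCAGATG"

mkSample <- function(timepoint, pre, alt1 = NULL, alt2 = NULL,
                     total = 5000L) {
  computeSiteFrequencies(
    list(s1 = mkCounts(SITE1, total, alt1), s2 = mkCounts(SITE2, total, alt2)),
    c(s1 = SITE1, s2 = SITE2), "subjA", timepoint, pre)
}

test_that("site frequencies and error rates are plain ratios", {
  sm <- mkSample("pre", TRUE,
                 alt1 = list(list(position = 7L, base = "G", count = 10L)),
                 total = 1000L)
  t1 <- siteTable(sm, "s1")
  expect_equal(unname(errorRates(t1))[7], 0.01)
  expect_equal(unname(errorRates(t1))[1], 0)
  expect_error(computeSiteFrequencies(list(sX = mkCounts(SITE1, 10L)),
                                      c(s1 = SITE1), "a", "b", TRUE),
               "not found")
})

test_that("the depth filter is strictly greater-than", {
  sm <- mkSample("pre", TRUE, total = 5000L)
  sm@reads[] <- c(1001, 1000)
  expect_equal(filterByDepth(sm, 1000L), "s1")
  sm@reads[] <- c(0, 1000)
  expect_equal(length(filterByDepth(sm, 1000L)), 0L)
  # raising the threshold never adds sites
  sm@reads[] <- c(1500, 3000)
  for (thr in c(0, 1000, 2000, 5000)) {
    lower <- filterByDepth(sm, thr)
    higher <- filterByDepth(sm, thr + 500L)
    expect_true(all(higher %in% lower))
  }
})

test_that("the SNP rule needs presence before and at every later timepoint", {
  half <- list(list(position = 11L, base = "T", count = 2500L))
  pre <- mkSample("pre", TRUE, alt1 = half)
  p1 <- mkSample("post1", FALSE, alt1 = half)
  p2 <- mkSample("post2", FALSE, alt1 = half)
  snps <- classifySNPs(list(pre, p1, p2))
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$site, "s1")
  expect_equal(snps$position, 11L)
  expect_equal(snps$base, "T")

  # 5% pre-treatment fails the >10% requirement
  low <- list(list(position = 11L, base = "T", count = 250L))
  expect_equal(nrow(classifySNPs(list(mkSample("pre", TRUE, alt1 = low),
                                      p1, p2))), 0L)

  # 15% pre but absent at one post timepoint fails presence
  some <- list(list(position = 11L, base = "T", count = 750L))
  pAbsent <- mkSample("post2", FALSE)
  expect_equal(nrow(classifySNPs(list(mkSample("pre", TRUE, alt1 = some),
                                      mkSample("post1", FALSE, alt1 = some),
                                      pAbsent))), 0L)

  expect_error(classifySNPs(list(p1, p2)), "pre-treatment")
})

test_that("background pooling matches hand arithmetic and excludes SNPs", {
  # construct a pre-treatment sample with known error rates
  alt1 <- list(list(position = 1L, base = "G", count = 10L),   # 0.002
               list(position = 2L, base = "G", count = 15L))   # 0.003
  pre <- mkSample("pre", TRUE, alt1 = alt1, total = 5000L)
  bg <- estimateBackground(pre)
  pool <- c(0.002, 0.003, rep(0, 38))
  expect_equal(bg@meanError, mean(pool))
  expect_equal(bg@sdError, sd(pool))
  expect_equal(bg@nPositions, 40L)

  # a 50% SNP position is excluded and leaves the rest untouched
  withSnp <- mkSample("pre", TRUE, alt1 = c(alt1, list(
    list(position = 11L, base = "T", count = 2500L))))
  snps <- data.frame(site = "s1", position = 11L, base = "T")
  bg2 <- estimateBackground(withSnp, snps)
  expect_equal(bg2@nPositions, 39L)
  expect_equal(bg2@meanError, mean(c(0.002, 0.003, rep(0, 37))))
})

test_that("candidate nomination needs both the 2-SD and 0.5% thresholds", {
  alt1 <- list(list(position = 1L, base = "G", count = 10L),
               list(position = 2L, base = "G", count = 15L))
  pre <- mkSample("pre", TRUE, alt1 = alt1)
  bg <- estimateBackground(pre)   # mean 1.25e-4, threshold well below 0.5%
  # 0.6% exceeds both thresholds
  post1 <- mkSample("post1", FALSE,
                    alt2 = list(list(position = 6L, base = "G",
                                     count = 30L)))
  cand <- callCandidatePositions(list(post1), bg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$site, "s2"); expect_equal(cand$position, 6L)
  # 0.4% passes 2 SD but fails the floor
  post2 <- mkSample("post1", FALSE,
                    alt2 = list(list(position = 6L, base = "G",
                                     count = 20L)))
  expect_equal(nrow(callCandidatePositions(list(post2), bg)), 0L)
  # a SNP position is never a candidate
  bgSnp <- estimateBackground(pre, data.frame(site = "s2", position = 6L,
                                              base = "G"))
  expect_equal(nrow(callCandidatePositions(list(post1), bgSnp)), 0L)
})

test_that("the longitudinal t-test matches closed-form values", {
  x <- c(0.010, 0.011, 0.009, 0.010)
  mu <- 0.001
  tt <- (mean(x) - mu) / (sd(x) / 2)
  samples <- c(list(mkSample("pre", TRUE,
                             alt2 = list(list(position = 6L, base = "G",
                                              count = 5L)))),
               lapply(seq_along(x), function(i)
                 mkSample(paste0("post", i), FALSE,
                          alt2 = list(list(position = 6L, base = "G",
                                           count = as.integer(5000 * x[i]))))))
  cand <- data.frame(site = "s2", position = 6L, ref = "C", alt = "G",
                     maxFrequency = max(x))
  call <- testCandidates(cand, samples)
  expect_equal(call$t, tt, tolerance = 1e-12)
  expect_equal(call$p, pt(tt, df = 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(call$significant)

  # all post values equal to pre: the null identity convention
  flat <- c(list(samples[[1]]),
            lapply(1:3, function(i)
              mkSample(paste0("post", i), FALSE,
                       alt2 = list(list(position = 6L, base = "G",
                                        count = 5L)))))
  c2 <- testCandidates(cand, flat)
  expect_equal(c2$t, 0); expect_equal(c2$p, 0.5)
  expect_false(c2$significant)

  # one usable post observation is indeterminate
  c3 <- testCandidates(cand, samples[1:2])
  expect_true(is.na(c3$significant))
  expect_match(c3$reason, "insufficient")
})

test_that("depth failures propagate as missing, not zero", {
  alt <- list(list(position = 6L, base = "G", count = 50L))
  pre <- mkSample("pre", TRUE, alt2 = alt)
  lowDepth <- mkSample("post1", FALSE)
  lowDepth@reads[] <- c(5000, 100)        # s2 fails depth
  post2 <- mkSample("post2", FALSE, alt2 = alt)
  post3 <- mkSample("post3", FALSE, alt2 = alt)
  cand <- data.frame(site = "s2", position = 6L, ref = "C", alt = "G",
                     maxFrequency = 0.01)
  call <- testCandidates(cand, list(pre, lowDepth, post2, post3))
  expect_equal(call$nPost, 2L)            # the failed-depth sample dropped
})

# Simulated panels -------------------------------------------------------

test_that("simulated panel frequencies track error, SNP and edit structure", {
  base <- panelSimConfig(sites = 10L, depth = 20000L, seed = 71L)
  aPos <- which(strsplit(base$sites[[3]], "")[[1]] == "A")[1]
  cfg <- panelSimConfig(
    sites = base$sites, depth = 20000L, errorRate = 1e-3,
    snpSpecs = data.frame(site = "site007", position = 11L, base = "T",
                          frequency = 0.5),
    editSpecs = data.frame(site = "site003", position = aPos,
                           frequency = 0.01, onset = "post1"),
    seed = 71L)
  stopifnot(substr(base$sites[["site007"]], 11, 11) != "T")
  panel <- simulatePanel(cfg)
  fr <- function(sm, site, pos, b)
    baseFrequencies(siteTable(sm, site))[pos, b]
  # germline SNP near 0.5 both pre and post
  expect_lt(abs(fr(panel$pre, "site007", 11L, "T") - 0.5), 0.02)
  expect_lt(abs(fr(panel$post3, "site007", 11L, "T") - 0.5), 0.02)
  # edit absent pre, near 1% post
  expect_lt(fr(panel$pre, "site003", aPos, "G"), 0.005)
  expect_lt(abs(fr(panel$post1, "site003", aPos, "G") - 0.01 - 1e-3 / 3),
            3 * sqrt(0.01 * 0.99 / 20000))
  # null positions sit at error / 3 per alternative base
  nullF <- fr(panel$pre, "site001", 5L, setdiff(BASES, substr(
    base$sites[["site001"]], 5, 5))[1])
  expect_lt(abs(nullF - 1e-3 / 3), 3 * sqrt(1e-3 / 3 / 20000))
})

test_that("edits cannot be configured to precede the pre-treatment sample", {
  base <- panelSimConfig(sites = 5L, seed = 72L)
  aPos <- which(strsplit(base$sites[[1]], "")[[1]] == "A")[1]
  expect_error(panelSimConfig(
    sites = base$sites,
    editSpecs = data.frame(site = "site001", position = aPos,
                           frequency = 0.01, onset = "pre"),
    seed = 72L), "onset")
})

test_that("an injected persistent edit is called at exactly its position", {
  base <- panelSimConfig(sites = 30L, depth = 5000L,
                         timepoints = c("pre", paste0("post", 1:5)),
                         seed = 73L)
  aPos <- which(strsplit(base$sites[[5]], "")[[1]] == "A")[1]
  cfg <- panelSimConfig(
    sites = base$sites, depth = 5000L,
    timepoints = base$timepoints,
    editSpecs = data.frame(site = "site005", position = aPos,
                           frequency = 0.01, onset = "post1"),
    seed = 73L)
  res <- callOfftargets(simulatePanel(cfg))
  sig <- res$calls[which(res$calls$significant), ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$site, "site005")
  expect_equal(sig$position, aPos)
  expect_equal(sig$alt, "G")
  long <- summarizePanel(res$calls, simulatePanel(cfg))
  expect_equal(nrow(long), 6L)   # one row per timepoint
  postF <- long$frequency[long$timepoint != "pre"]
  expect_true(all(abs(postF - 0.01) < 0.01))
})

test_that("nearest-gene annotation is a plain interval query", {
  ann <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1000, 9000, 500), c(2000, 9500, 800)),
    name = c("geneA", "geneB", "geneC"),
    type = c("gene", "gene", "gene"))
  pos <- data.frame(contig = c("chr1", "chr1", "chr2"),
                    position = c(1500, 7000, 790))
  out <- annotateNearestGene(pos, ann)
  expect_equal(out$feature, c("geneA", "geneB", "geneC"))
  expect_equal(out$distance, c(0, 2000, 0))
  expect_equal(out$region[1], "intronic")
  expect_equal(out$region[2], "intergenic")
  # equidistant tie reported deterministically and flagged
  tiePos <- data.frame(contig = "chr1", position = 5500)
  tie <- annotateNearestGene(tiePos, ann)
  expect_equal(tie$feature, "geneA")
  expect_true(tie$tie)
  # empty annotation set
  empty <- annotateNearestGene(pos, GenomicRanges::GRanges())
  expect_true(all(empty$region == "intergenic"))
  expect_true(all(is.na(empty$distance)))
})

test_that("annotations load from a BED file", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgeneA\t0\t+\nchr1\t8999\t9500\tgeneB\t0\t+",
             bed)
  out <- annotateNearestGene(
    data.frame(contig = "chr1", position = 4000), bed)
  expect_equal(out$feature, "geneA")
  expect_equal(out$distance, 2000)
})
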
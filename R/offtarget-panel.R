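#' Assemble a PanelSample from per-site count tables
#'
#' Computes per-position base frequencies for each site of a panel
#' sample. This is the entry point when counts were produced outside the
#' package; FASTQ input is handled by running [processReads()] and
#' [tabulatePositions()] per site and passing the resulting count
#' matrices here.
#'
#' @param countTables named list (by site) of positions x bases count
#'   matrices (columns `A,C,G,T`).
#' @param siteSeqs named character vector of 20-mer site sequences; must
#'   cover every site in `countTables`.
#' @param subject,timepoint sample labels.
#' @param isPretreatment `TRUE` for the pre-treatment sample.
#' @return a [PanelSample-class].
#' @export
computeSiteFrequencies <- function(countTables, siteSeqs, subject,
                                   timepoint, isPretreatment = FALSE) {
  missing <- setdiff(names(countTables), names(siteSeqs))
  if (length(missing))
    stop("site sequence not found in panel definition: ",
         paste(missing, collapse = ", "))
  refs <- lapply(names(countTables),
                 function(s) strsplit(siteSeqs[[s]], "")[[1]])
  names(refs) <- names(countTables)
  panelSample(subject, timepoint, isPretreatment, countTables, refs)
}

#' Depth-filter the sites of a panel sample
#'
#' A site is retained only if it has strictly more than `minReads` reads.
#'
#' @param sample a [PanelSample-class].
#' @param minReads read-count threshold (strict).
#' @return character vector of retained site names.
#' @export
filterByDepth <- function(sample, minReads = 1000L) {
  r <- siteReads(sample)
  names(r)[r > minReads]
}

# frequencies as [position, base, site]; sites failing depth are NA
.freqArray <- function(sample, minReads = 1000L) {
  cov <- apply(sample@counts, c(1, 3), sum)
  f <- sweep(sample@counts, c(1, 3), pmax(cov, 1L), "/")
  drop <- !(siteNames(sample) %in% filterByDepth(sample, minReads))
  if (any(drop)) f[, , drop] <- NA_real_
  f
}

#' Classify germline SNPs from a subject timecourse
#'
#' A (site, position, base) is a SNP when its frequency in the
#' pre-treatment sample exceeds `minPreFrequency` and it is present
#' (frequency at least `presenceFloor`) at every other timepoint where
#' the site passes the depth filter. Timepoints where the site fails the
#' depth filter are treated as missing, not as absence.
#'
#' @param samples list of [PanelSample-class] for one subject, containing
#'   exactly one pre-treatment sample.
#' @param minPreFrequency pre-treatment frequency a SNP must exceed
#'   (strict).
#' @param presenceFloor frequency required at every other timepoint.
#' @param minReads depth-filter threshold.
#' @return data.frame with `site`, `position`, `base`, `preFrequency`.
#' @export
classifySNPs <- function(samples, minPreFrequency = 0.10,
                         presenceFloor = 0.10, minReads = 1000L) {
  pre <- Filter(isPretreatment, samples)
  if (length(pre) != 1L)
    stop("exactly one pre-treatment sample is required for the SNP rule")
  pre <- pre[[1]]
  post <- Filter(Negate(isPretreatment), samples)
  fPre <- .freqArray(pre, minReads)
  sites <- siteNames(pre)
  out <- list()
  cand <- which(fPre > minPreFrequency, arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, 1L]; b <- cand[r, 2L]; s <- cand[r, 3L]
    base <- .BASES[b]
    if (base == pre@ref[p, s]) next
    present <- vapply(post, function(sm) {
      f <- .freqArray(sm, minReads)[p, b, s]
      if (is.na(f)) NA else f >= presenceFloor
    }, logical(1))
    if (all(present, na.rm = TRUE)) {
      out[[length(out) + 1L]] <- data.frame(
        site = sites[s], position = p, base = base,
        preFrequency = fPre[p, b, s], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(site = character(), position = integer(),
                      base = character(), preFrequency = numeric()))
  do.call(rbind, out)
}

#' Estimate the pre-treatment background error model
#'
#' Pools the per-position base error rates (1 minus the reference-base
#' frequency) across all protospacer positions of all depth-passing sites
#' of the pre-treatment sample, excluding SNP positions, and returns
#' their mean and sample standard deviation.
#'
#' @param preSample the pre-treatment [PanelSample-class].
#' @param snps SNP table from [classifySNPs()].
#' @param minReads depth-filter threshold.
#' @return a [BackgroundModel-class].
#' @export
estimateBackground <- function(preSample, snps = NULL, minReads = 1000L) {
  retained <- filterByDepth(preSample, minReads)
  if (!length(retained))
    stop("no site passes the depth filter in the pre-treatment sample")
  f <- .freqArray(preSample, minReads)
  sites <- siteNames(preSample)
  refIdx <- match(preSample@ref, .BASES)     # positions x sites, col-major
  nP <- dim(f)[1]
  err <- matrix(NA_real_, nP, length(sites))
  for (s in seq_along(sites))
    err[, s] <- 1 - f[cbind(seq_len(nP), refIdx[(s - 1L) * nP + seq_len(nP)],
                            s)]
  if (!is.null(snps) && nrow(snps))
    err[cbind(snps$position, match(snps$site, sites))] <- NA_real_
  pool <- err[!is.na(err)]
  if (length(pool) < 2L)
    stop("fewer than 2 positions in the background pool: SD undefined")
  new("BackgroundModel", subject = preSample@subject,
      meanError = mean(pool), sdError = stats::sd(pool),
      nPositions = length(pool),
      snpPositions = if (is.null(snps)) data.frame(site = character(),
                                                   position = integer(),
                                                   base = character())
                     else snps[, c("site", "position", "base")])
}

#' Nominate candidate off-target positions
#'
#' A (site, position, substitution) is a candidate when, in at least one
#' post-treatment sample, its frequency exceeds both the background
#' threshold `mean + 2 * sd` and the absolute floor (0.5% by default).
#' SNP positions are never candidates.
#'
#' @param postSamples list of post-treatment [PanelSample-class] objects.
#' @param bg a [BackgroundModel-class].
#' @param floor absolute frequency floor (strict).
#' @param minReads depth-filter threshold.
#' @return data.frame with `site`, `position`, `ref`, `alt`,
#'   `maxFrequency`.
#' @export
callCandidatePositions <- function(postSamples, bg, floor = 0.005,
                                   minReads = 1000L) {
  threshold <- bg@meanError + 2 * bg@sdError
  snpKey <- with(bg@snpPositions, paste(site, position, base))
  agg <- NULL
  for (sm in postSamples) {
    f <- .freqArray(sm, minReads)
    if (is.null(agg)) agg <- f
    else agg <- pmax(agg, f, na.rm = TRUE)
  }
  sites <- siteNames(postSamples[[1]])
  hits <- which(agg > pmax(threshold, floor), arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    p <- hits[r, 1L]; b <- hits[r, 2L]; s <- hits[r, 3L]
    ref <- postSamples[[1]]@ref[p, s]
    alt <- .BASES[b]
    if (alt == ref) next
    if (paste(sites[s], p, alt) %in% snpKey) next
    out[[length(out) + 1L]] <- data.frame(
      site = sites[s], position = p, ref = ref, alt = alt,
      maxFrequency = agg[p, b, s], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site = character(), position = integer(),
                      ref = character(), alt = character(),
                      maxFrequency = numeric()))
  df <- do.call(rbind, out)
  df[order(df$site, df$position, df$alt), , drop = FALSE]
}

#' Test candidate positions against the pre-treatment frequency
#'
#' One-sample, one-sided t-test of the post-treatment frequencies of each
#' candidate against the subject's pre-treatment frequency at the same
#' (site, position, substitution); the alternative is `greater`, since
#' editing can only add the alternative allele. With all post values
#' exactly equal to the pre value the test is the null identity
#' (`t = 0`, `p = 0.5`); zero variance away from the pre value gives the
#' limiting p of 0 (above) or 1 (below). Fewer than 2 usable post
#' observations yields an indeterminate call.
#'
#' @param candidates data.frame from [callCandidatePositions()].
#' @param samples full list of [PanelSample-class] for the subject
#'   (pre and post).
#' @param alpha significance level.
#' @param minReads depth-filter threshold.
#' @param pooled if `TRUE`, `samples` may span subjects and all post
#'   frequencies are pooled into one test per candidate.
#' @return data.frame with one row per candidate: `site`, `position`,
#'   `ref`, `alt`, `preFrequency`, `nPost`, `t`, `p`, `significant`,
#'   `reason`.
#' @export
testCandidates <- function(candidates, samples, alpha = 0.05,
                           minReads = 1000L, pooled = FALSE) {
  pre <- Filter(isPretreatment, samples)
  if (!length(pre)) stop("no pre-treatment sample")
  post <- Filter(Negate(isPretreatment), samples)
  preF <- lapply(pre, .freqArray, minReads = minReads)
  postF <- lapply(post, .freqArray, minReads = minReads)
  sites <- siteNames(samples[[1]])

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    s <- match(candidates$site[i], sites)
    p <- candidates$position[i]
    b <- match(candidates$alt[i], .BASES)
    preVals <- vapply(preF, function(f) f[p, b, s], numeric(1))
    mu <- mean(preVals, na.rm = TRUE)
    x <- vapply(postF, function(f) f[p, b, s], numeric(1))
    x <- x[!is.na(x)]
    base <- candidates[i, c("site", "position", "ref", "alt")]
    if (is.nan(mu) || length(x) < 2L) {
      return(cbind(base, data.frame(
        preFrequency = ifelse(is.nan(mu), NA_real_, mu),
        nPost = length(x), t = NA_real_, p = NA_real_,
        significant = NA, reason = "insufficient observations")))
    }
    if (stats::sd(x) == 0) {
      if (all(x == mu)) { tt <- 0; pv <- 0.5 }
      else if (mean(x) > mu) { tt <- Inf; pv <- 0 }
      else { tt <- -Inf; pv <- 1 }
    } else {
      ht <- stats::t.test(x, mu = mu, alternative = "greater")
      tt <- unname(ht$statistic); pv <- ht$p.value
    }
    cbind(base, data.frame(preFrequency = mu, nPost = length(x), t = tt,
                           p = pv, significant = pv < alpha, reason = ""))
  })
  if (!length(rows))
    return(data.frame(site = character(), position = integer(),
                      ref = character(), alt = character(),
                      preFrequency = numeric(), nPost = integer(),
                      t = numeric(), p = numeric(), significant = logical(),
                      reason = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full off-target calling for one subject
#'
#' SNP classification, background estimation, candidate nomination and
#' longitudinal testing in one call.
#'
#' @param samples list of [PanelSample-class] for one subject (exactly
#'   one pre-treatment).
#' @param alpha significance level.
#' @param floor candidate frequency floor.
#' @param minReads depth-filter threshold.
#' @param minPreFrequency,presenceFloor SNP-rule thresholds.
#' @return list with `snps`, `background`, `candidates`, `calls`.
#' @export
callOfftargets <- function(samples, alpha = 0.05, floor = 0.005,
                           minReads = 1000L, minPreFrequency = 0.10,
                           presenceFloor = 0.10) {
  snps <- classifySNPs(samples, minPreFrequency, presenceFloor, minReads)
  pre <- Filter(isPretreatment, samples)[[1]]
  bg <- estimateBackground(pre, snps, minReads)
  post <- Filter(Negate(isPretreatment), samples)
  cand <- callCandidatePositions(post, bg, floor, minReads)
  calls <- testCandidates(cand, samples, alpha, minReads)
  list(snps = snps, background = bg, candidates = cand, calls = calls)
}

#' Longitudinal frequencies of significant off-target calls
#'
#' @param calls data.frame from [testCandidates()].
#' @param samples list of [PanelSample-class] (pre and post) in temporal
#'   order.
#' @param minReads depth-filter threshold.
#' @return long-format data.frame with `site`, `position`, `alt`,
#'   `timepoint`, `frequency` for every significant call (empty when
#'   there is none).
#' @export
summarizePanel <- function(calls, samples, minReads = 1000L) {
  sig <- calls[!is.na(calls$significant) & calls$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(site = character(), position = integer(),
                      alt = character(), timepoint = character(),
                      frequency = numeric()))
  sites <- siteNames(samples[[1]])
  rows <- list()
  for (sm in samples) {
    f <- .freqArray(sm, minReads)
    for (i in seq_len(nrow(sig))) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = sig$site[i], position = sig$position[i], alt = sig$alt[i],
        timepoint = sm@timepoint,
        frequency = f[sig$position[i], match(sig$alt[i], .BASES),
                      match(sig$site[i], sites)],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Annotate positions with their nearest gene
#'
#' Replaces peak-annotation tooling with a plain interval query: for each
#' position, the nearest feature (distance 0 when overlapping), the
#' distance in bp, and a region class derived from the feature types
#' (`exonic` when overlapping an exon feature, `intronic` when inside a
#' gene but not an exon, `intergenic` otherwise). Ties on distance are
#' broken by lexicographically first feature name and flagged.
#'
#' @param positions data.frame with `contig` and `position` (1-based)
#'   columns, or a `GRanges`.
#' @param annotations a `GRanges` with metadata columns `name` and
#'   optionally `type`, or the path to a BED/GFF file (imported with
#'   rtracklayer).
#' @return data.frame with `contig`, `position`, `feature`, `distance`,
#'   `region`, `tie`.
#' @export
annotateNearestGene <- function(positions, annotations) {
  if (is.character(annotations)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read annotation files")
    annotations <- rtracklayer::import(annotations)
    if (is.null(annotations$name) && !is.null(annotations$ID))
      annotations$name <- annotations$ID
  }
  if (methods::is(positions, "GRanges")) {
    positions <- data.frame(
      contig = as.character(GenomicRanges::seqnames(positions)),
      position = BiocGenerics::start(positions))
  }
  n <- nrow(positions)
  out <- data.frame(contig = positions$contig,
                    position = positions$position,
                    feature = NA_character_, distance = NA_real_,
                    region = "intergenic", tie = FALSE,
                    stringsAsFactors = FALSE)
  if (!length(annotations)) return(out)
  aContig <- as.character(GenomicRanges::seqnames(annotations))
  aStart <- BiocGenerics::start(annotations)
  aEnd <- BiocGenerics::end(annotations)
  aName <- annotations$name
  if (is.null(aName)) aName <- sprintf("feature%04d", seq_along(annotations))
  aType <- annotations$type
  if (is.null(aType)) aType <- rep("gene", length(annotations))
  aType <- as.character(aType)

  for (i in seq_len(n)) {
    onContig <- which(aContig == positions$contig[i])
    if (!length(onContig)) next
    x <- positions$position[i]
    d <- ifelse(x >= aStart[onContig] & x <= aEnd[onContig], 0,
                pmin(abs(x - aStart[onContig]), abs(x - aEnd[onContig])))
    dmin <- min(d)
    nearest <- onContig[d == dmin]
    nm <- sort(aName[nearest])
    out$feature[i] <- nm[1]
    out$distance[i] <- dmin
    out$tie[i] <- length(unique(aName[nearest])) > 1L
    if (dmin == 0) {
      types <- aType[nearest]
      out$region[i] <- if (any(types == "exon")) "exonic" else "intronic"
    } else {
      out$region[i] <- "intergenic"
    }
  }
  out
}
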
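#' Construct a PositionFrequencyTable
#'
#' @param sample sample identifier.
#' @param counts positions x bases count matrix (columns `A,C,G,T`).
#' @param ref reference base per position (protospacer strand).
#' @return a [PositionFrequencyTable-class].
#' @export
positionFrequencyTable <- function(sample, counts, ref) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("PositionFrequencyTable", sample = as.character(sample),
      counts = counts, ref = as.character(ref))
}

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("sampleId", "PositionFrequencyTable", function(x) x@sample)

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("baseCounts", "PositionFrequencyTable", function(x) x@counts)

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("baseFrequencies", "PositionFrequencyTable", function(x) {
  cov <- rowSums(x@counts)
  f <- x@counts / ifelse(cov > 0, cov, 1)
  f[cov == 0, ] <- NA_real_
  f
})

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("positionCoverage", "PositionFrequencyTable",
          function(x) rowSums(x@counts))

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("refBases", "PositionFrequencyTable", function(x) x@ref)

#' @rdname PositionFrequencyTable-class
#' @export
setMethod("errorRates", "PositionFrequencyTable", function(x) {
  f <- baseFrequencies(x)
  1 - f[cbind(seq_len(nrow(f)), match(x@ref, colnames(f)))]
})

#' @rdname PositionFrequencyTable-class
#' @param object a `PositionFrequencyTable`.
#' @export
setMethod("show", "PositionFrequencyTable", function(object) {
  cat("PositionFrequencyTable for sample '", object@sample, "': ",
      nrow(object@counts), " positions, coverage ",
      paste(range(positionCoverage(object)), collapse = "-"), "\n", sep = "")
})

#' Construct a PanelSample from per-site count tables
#'
#' @param subject,timepoint sample labels.
#' @param isPretreatment `TRUE` for the pre-treatment sample.
#' @param counts positions x bases x sites array, or a named list of
#'   positions x bases matrices (one per site).
#' @param ref positions x sites matrix of reference bases, or a named list
#'   of per-site reference base vectors.
#' @param reads named total read count per site; defaults to the column
#'   sums of `counts`.
#' @return a [PanelSample-class].
#' @export
panelSample <- function(subject, timepoint, isPretreatment, counts, ref,
                        reads = NULL) {
  if (is.list(counts)) {
    sites <- names(counts)
    arr <- array(0, dim = c(nrow(counts[[1]]), 4L, length(counts)),
                 dimnames = list(NULL, .BASES, sites))
    for (i in seq_along(counts)) arr[, , i] <- as.matrix(counts[[i]])[, .BASES]
    counts <- arr
  }
  if (is.list(ref)) ref <- do.call(cbind, ref)
  if (is.null(reads)) reads <- apply(counts[, , , drop = FALSE], 3, function(m) max(rowSums(m)))
  names(reads) <- dimnames(counts)[[3]]
  new("PanelSample", subject = as.character(subject),
      timepoint = as.character(timepoint),
      isPretreatment = isPretreatment, counts = counts,
      ref = ref, reads = reads)
}

#' @rdname PanelSample-class
#' @export
setMethod("siteNames", "PanelSample", function(x) dimnames(x@counts)[[3]])

#' @rdname PanelSample-class
#' @export
setMethod("siteReads", "PanelSample", function(x) x@reads)

#' @rdname PanelSample-class
#' @export
setMethod("isPretreatment", "PanelSample", function(x) x@isPretreatment)

#' @rdname PanelSample-class
#' @export
setMethod("siteTable", "PanelSample", function(x, site) {
  positionFrequencyTable(
    sample = paste(x@subject, x@timepoint, site, sep = "/"),
    counts = x@counts[, , site],
    ref = x@ref[, if (is.character(site)) match(site, siteNames(x)) else site])
})

#' @rdname PanelSample-class
#' @param object a `PanelSample`.
#' @export
setMethod("show", "PanelSample", function(object) {
  cat("PanelSample ", object@subject, "/", object@timepoint,
      if (object@isPretreatment) " (pre-treatment)" else "",
      ": ", length(object@reads), " sites, ",
      sum(object@reads), " reads\n", sep = "")
})

#' Construct a TraceProportions object
#'
#' @param id colony identifier.
#' @param proportions positions x bases matrix (columns `A,C,G,T`, rows
#'   summing to 1).
#' @param protospacerStart row index where the protospacer begins.
#' @return a [TraceProportions-class].
#' @export
traceProportions <- function(id, proportions, protospacerStart) {
  new("TraceProportions", id = as.character(id),
      proportions = as.matrix(proportions),
      protospacerStart = as.integer(protospacerStart))
}

#' @rdname TraceProportions-class
#' @param object a `TraceProportions`.
#' @export
setMethod("show", "TraceProportions", function(object) {
  cat("TraceProportions '", object@id, "': ", nrow(object@proportions),
      " positions (protospacer at ", object@protospacerStart, ")\n", sep = "")
})

#' @rdname BackgroundModel-class
#' @param object a `BackgroundModel`.
#' @export
setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel for subject '", object@subject, "': mean ",
      signif(object@meanError, 4), ", SD ", signif(object@sdError, 4),
      " over ", object@nPositions, " positions (",
      nrow(object@snpPositions), " SNP positions excluded)\n", sep = "")
})

#' @rdname FilterReport-class
#' @param object a `FilterReport`.
#' @export
setMethod("show", "FilterReport", function(object) {
  cat("FilterReport: ", object@total, " pairs; merged ", object@merged,
      "; failed merge ", object@failedMerge, ", quality ",
      object@failedQuality, ", primer ", object@failedPrimer,
      "; retained ", object@retained, "\n", sep = "")
})

#' Convert a FilterReport to a one-row data.frame
#'
#' @param report a [FilterReport-class].
#' @return data.frame with one column per counter.
#' @export
filterReportAsData <- function(report) {
  data.frame(total = report@total, merged = report@merged,
             failed_merge = report@failedMerge,
             failed_quality = report@failedQuality,
             failed_primer = report@failedPrimer,
             retained = report@retained)
}
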
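#' Estimate the edited fraction at an adenine from a trace
#'
#' For an A-to-G edit, the edited-signal fraction at a position is
#' `G / (A + G)`. When less than half of the total signal at the position
#' is A or G, the trace is likely indel-bearing or mixed and the estimate
#' is indeterminate (`NA`).
#'
#' @param trace a [TraceProportions-class].
#' @param position protospacer position (1-20) of the adenine.
#' @return edited fraction in `[0, 1]`, or `NA` if indeterminate.
#' @examples
#' m <- matrix(0, 25, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
#' m[, "A"] <- 1; m[3 + 9 - 1, ] <- c(0.5, 0, 0.5, 0)
#' estimateSiteFraction(traceProportions("c1", m, 3L), 9L)
#' @export
estimateSiteFraction <- function(trace, position = 9L) {
  row <- trace@protospacerStart + position - 1L
  p <- trace@proportions[row, ]
  ag <- p[["A"]] + p[["G"]]
  if (ag < 0.5) return(NA_real_)
  p[["G"]] / ag
}

#' Call a colony genotype from its trace
#'
#' Diploid genotype bands around the expected edited-signal fractions 0,
#' 0.5 and 1: below `lo` is unedited, between `lo` and `hi` (inclusive)
#' monoallelic, above `hi` biallelic. An indeterminate edited fraction
#' (see [estimateSiteFraction()]) propagates as `indeterminate`.
#'
#' @param trace a [TraceProportions-class].
#' @param position protospacer position of the tracked adenine.
#' @param lo,hi genotype thresholds on the edited fraction.
#' @param purityThreshold,runLength parameters of the indel degradation
#'   flag (see [flagTraceIndel()]).
#' @return data.frame with `id`, `call` (`unedited`, `monoallelic`,
#'   `biallelic` or `indeterminate`), `editedFraction` and `indelFlag`.
#' @export
callColonyGenotype <- function(trace, position = 9L, lo = 0.2, hi = 0.8,
                               purityThreshold = 0.7, runLength = 5L) {
  f <- estimateSiteFraction(trace, position)
  call <- if (is.na(f)) "indeterminate"
          else if (f < lo) "unedited"
          else if (f <= hi) "monoallelic"
          else "biallelic"
  data.frame(id = trace@id, call = call, editedFraction = f,
             indelFlag = flagTraceIndel(trace, purityThreshold, runLength),
             stringsAsFactors = FALSE)
}

#' Flag a trace as indel-bearing from signal degradation
#'
#' An indel in one allele desynchronises the Sanger trace downstream of
#' the lesion, so the per-position signal becomes mixed. The flag fires
#' when, at or after the protospacer start, at least `runLength`
#' consecutive positions have a maximum base proportion below
#' `purityThreshold`.
#'
#' @param trace a [TraceProportions-class].
#' @param purityThreshold maximum-base proportion below which a position
#'   counts as degraded.
#' @param runLength required run of consecutive degraded positions.
#' @return logical flag.
#' @export
flagTraceIndel <- function(trace, purityThreshold = 0.7, runLength = 5L) {
  m <- trace@proportions
  rows <- trace@protospacerStart:nrow(m)
  degraded <- apply(m[rows, , drop = FALSE], 1L, max) < purityThreshold
  r <- rle(degraded)
  any(r$values & r$lengths >= runLength)
}

#' Call genotypes for a set of colonies
#'
#' @param traces list of [TraceProportions-class] objects.
#' @inheritParams callColonyGenotype
#' @return data.frame with one row per colony (see
#'   [callColonyGenotype()]).
#' @export
callColonyGenotypes <- function(traces, position = 9L, lo = 0.2, hi = 0.8,
                                purityThreshold = 0.7, runLength = 5L) {
  do.call(rbind, lapply(traces, callColonyGenotype, position = position,
                        lo = lo, hi = hi,
                        purityThreshold = purityThreshold,
                        runLength = runLength))
}

#' Summarize colony genotype calls
#'
#' @param calls data.frame from [callColonyGenotypes()].
#' @return data.frame of counts and fractions per genotype class, plus
#'   the fraction of edited colonies (mono- or biallelic) among
#'   determinate calls.
#' @export
summarizeColonyGenotypes <- function(calls) {
  lev <- c("unedited", "monoallelic", "biallelic", "indeterminate")
  n <- table(factor(calls$call, levels = lev))
  det <- sum(n[c("unedited", "monoallelic", "biallelic")])
  data.frame(class = lev, count = as.integer(n),
             fraction = as.integer(n) / nrow(calls),
             stringsAsFactors = FALSE)
}
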
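#' Simulate clonal-colony Sanger traces
#'
#' Generates base-proportion traces for clonal colonies drawn from a
#' mixture of unedited, monoallelic and biallelic genotypes at the
#' tracked adenine. A diploid colony's edited-signal fraction at that
#' position is 0, 0.5 or 1; trace noise mixes each position's one-hot
#' proportions with a random Dirichlet(1,1,1,1) component at weight
#' `noise`, so noise-free traces are exact.
#'
#' @param n number of colonies.
#' @param genotypeMix fractions of unedited / monoallelic / biallelic
#'   colonies (must sum to 1).
#' @param noise mixing weight of the random component in `[0, 1)`.
#' @param locus an [AmpliconLocus-class]; the trace covers its inner
#'   reference.
#' @param position tracked protospacer position.
#' @param seed integer seed.
#' @return list with `traces` (list of [TraceProportions-class]) and
#'   `truth` (data.frame with `id` and true `genotype`).
#' @examples
#' sim <- simulateColonies(12, c(0.1, 0.7, 0.2), noise = 0, seed = 2L)
#' table(sim$truth$genotype)
#' @export
simulateColonies <- function(n, genotypeMix = c(0.1, 0.7, 0.2),
                             noise = 0.03, locus = hbbLocus(),
                             position = 9L, seed = 1L) {
  if (length(genotypeMix) != 3L || abs(sum(genotypeMix) - 1) > 1e-9)
    stop("genotypeMix must be three fractions summing to 1")
  if (noise < 0) stop("noise must be non-negative")
  if (noise >= 1) stop("noise must be below 1")
  if (!is.null(seed)) set.seed(seed)

  genotypes <- sample(c("unedited", "monoallelic", "biallelic"), n,
                      replace = TRUE, prob = genotypeMix)
  editedFraction <- c(unedited = 0, monoallelic = 0.5, biallelic = 1)

  # traces are oriented to the protospacer strand, so an A-to-G edit is
  # always an A/G signal mixture
  innerSeq <- .innerReference(locus)
  if (locus@protospacerStrand == "-") {
    innerSeq <- revComp(innerSeq)
    psStart <- nchar(innerSeq) - (.innerProtospacerStart(locus) + 19L) + 1L
  } else {
    psStart <- .innerProtospacerStart(locus)
  }
  inner <- strsplit(innerSeq, "")[[1]]
  editRow <- psStart + position - 1L
  base <- matrix(0, length(inner), 4L,
                 dimnames = list(NULL, .BASES))
  base[cbind(seq_along(inner), match(inner, .BASES))] <- 1

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    m <- base
    f <- editedFraction[[genotypes[i]]]
    m[editRow, ] <- 0
    m[editRow, "A"] <- 1 - f
    m[editRow, "G"] <- f
    if (noise > 0) {
      w <- matrix(stats::rexp(length(m)), nrow(m), 4L)
      w <- w / rowSums(w)
      m <- (1 - noise) * m + noise * w
    }
    colnames(m) <- .BASES
    traces[[i]] <- traceProportions(sprintf("colony%04d", i), m, psStart)
  }
  list(traces = traces,
       truth = data.frame(id = sprintf("colony%04d", seq_len(n)),
                          genotype = genotypes, stringsAsFactors = FALSE))
}
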
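#' Simulation configuration for a multiplexed off-target panel
#'
#' Defines a longitudinal amplicon panel for one subject: a set of
#' candidate sites (20-bp protospacer-binding sequences), an ordered set
#' of timepoints with exactly one pre-treatment sample, per-base
#' sequencing/PCR error, germline SNPs (present at every timepoint) and
#' true edits (absent before their onset timepoint). Per-position counts
#' are exact multinomial draws.
#'
#' @param sites named character vector of 20-mer site sequences, or an
#'   integer: that many sites are generated by mutating `spacer` at 1-4
#'   random positions.
#' @param spacer spacer used to generate sites when `sites` is a count.
#' @param timepoints ordered timepoint labels.
#' @param preTimepoint the label of the single pre-treatment timepoint.
#' @param depth reads per site per timepoint; scalar, or a matrix
#'   (sites x timepoints).
#' @param errorRate per-base substitution error (each alternative base
#'   appears at `errorRate / 3`).
#' @param snpSpecs data.frame with `site`, `position`, `base`,
#'   `frequency`: germline variants present at all timepoints.
#' @param editSpecs data.frame with `site`, `position`, `frequency`,
#'   `onset`: A-to-G edits present from `onset` (a post-treatment label)
#'   onwards.
#' @param subject subject label.
#' @param seed integer seed.
#' @return a validated configuration list of class
#'   `abequant_panel_config`.
#' @seealso [simulatePanel()]
#' @export
panelSimConfig <- function(sites = 50L,
                           spacer = "TTCTCCTCAGGAGTCAGATG",
                           timepoints = c("pre", paste0("post", 1:5)),
                           preTimepoint = "pre",
                           depth = 5000L,
                           errorRate = 1e-3,
                           snpSpecs = NULL,
                           editSpecs = NULL,
                           subject = "subject1",
                           seed = 1L) {
  if (is.numeric(sites) && length(sites) == 1L) {
    n <- as.integer(sites)
    set.seed(seed)  # site construction is part of the deterministic config
    sp <- strsplit(spacer, "")[[1]]
    sites <- vapply(seq_len(n), function(i) {
      s <- sp
      k <- sample(1:4, 1L)
      pos <- sample(20L, k)
      for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
      paste(s, collapse = "")
    }, character(1))
    names(sites) <- sprintf("site%03d", seq_len(n))
  }
  if (is.null(names(sites))) names(sites) <- sprintf("site%03d", seq_along(sites))
  if (!(preTimepoint %in% timepoints))
    stop("preTimepoint must be one of timepoints")
  if (sum(timepoints == preTimepoint) != 1L)
    stop("exactly one pre-treatment timepoint is required")
  if (is.null(snpSpecs))
    snpSpecs <- data.frame(site = character(), position = integer(),
                           base = character(), frequency = numeric())
  if (is.null(editSpecs))
    editSpecs <- data.frame(site = character(), position = integer(),
                            frequency = numeric(), onset = character())
  if (length(depth) == 1L)
    depth <- matrix(depth, length(sites), length(timepoints),
                    dimnames = list(names(sites), timepoints))
  if (any(depth < 0)) stop("depths must be >= 0")
  if (any(snpSpecs$frequency < 0 | snpSpecs$frequency > 1) ||
      any(editSpecs$frequency < 0 | editSpecs$frequency > 1) ||
      errorRate < 0 || errorRate > 1)
    stop("frequencies must lie in [0, 1]")
  preIdx <- match(preTimepoint, timepoints)
  if (nrow(editSpecs)) {
    onsetIdx <- match(editSpecs$onset, timepoints)
    if (anyNA(onsetIdx)) stop("edit onset must be a timepoint label")
    if (any(onsetIdx <= preIdx))
      stop("edit onset before (or at) the pre-treatment timepoint")
    bad <- substr(sites[editSpecs$site], editSpecs$position,
                  editSpecs$position) != "A"
    if (any(bad)) stop("editSpecs positions must be adenines in the site")
  }
  cfg <- list(sites = sites, timepoints = timepoints,
              preTimepoint = preTimepoint, depth = depth,
              errorRate = errorRate, snpSpecs = snpSpecs,
              editSpecs = editSpecs, subject = subject, seed = seed)
  class(cfg) <- "abequant_panel_config"
  cfg
}

# exact multinomial draws via sequential binomials, vectorised over cells
.rmultinomVec <- function(n, probs) {
  # n: integer vector of trials; probs: matrix cells x 4 summing to 1
  k <- length(n)
  out <- matrix(0L, k, 4L)
  remaining <- n
  pLeft <- rep(1, k)
  for (b in 1:3) {
    p <- ifelse(pLeft > 0, pmin(1, probs[, b] / pLeft), 0)
    out[, b] <- stats::rbinom(k, remaining, p)
    remaining <- remaining - out[, b]
    pLeft <- pLeft - probs[, b]
  }
  out[, 4L] <- remaining
  out
}

#' Simulate a longitudinal off-target panel
#'
#' Draws per-site, per-position base counts for every timepoint of a
#' [panelSimConfig()]. Pre-treatment samples carry SNPs and sequencing
#' error but no edits; edits appear from their onset timepoint onwards.
#'
#' @param config a [panelSimConfig()].
#' @return list of [PanelSample-class] objects, one per timepoint, in
#'   temporal order.
#' @examples
#' cfg <- panelSimConfig(sites = 5L, depth = 2000L, seed = 11L)
#' panel <- simulatePanel(cfg)
#' panel[[1]]
#' @export
simulatePanel <- function(config) {
  if (!inherits(config, "abequant_panel_config"))
    stop("config must come from panelSimConfig()")
  set.seed(config$seed)
  sites <- config$sites
  nS <- length(sites); nP <- 20L
  tps <- config$timepoints
  preIdx <- match(config$preTimepoint, tps)
  refMat <- vapply(sites, function(s) strsplit(s, "")[[1]],
                   character(nP))        # positions x sites
  e <- config$errorRate

  samples <- vector("list", length(tps))
  for (ti in seq_along(tps)) {
    # probability array: cells = (position, site) x 4 bases
    probs <- matrix(e / 3, nS * nP, 4L)
    colnames(probs) <- .BASES
    refIdx <- match(as.vector(refMat), .BASES)
    probs[cbind(seq_len(nS * nP), refIdx)] <- 1 - e
    addAlt <- function(site, position, base, frequency) {
      cell <- (match(site, names(sites)) - 1L) * nP + position
      probs[cell, base] <<- probs[cell, base] + frequency
      probs[cell, refMat[position, site]] <<-
        probs[cell, refMat[position, site]] - frequency
    }
    sn <- config$snpSpecs
    for (i in seq_len(nrow(sn)))
      addAlt(sn$site[i], sn$position[i], sn$base[i], sn$frequency[i])
    ed <- config$editSpecs
    for (i in seq_len(nrow(ed))) {
      if (ti >= match(ed$onset[i], tps) && ti != preIdx)
        addAlt(ed$site[i], ed$position[i], "G", ed$frequency[i])
    }
    nTrials <- rep(config$depth[, ti], each = nP)
    counts <- .rmultinomVec(as.integer(nTrials), probs)
    arr <- array(0L, dim = c(nP, 4L, nS),
                 dimnames = list(1:20, .BASES, names(sites)))
    for (b in 1:4) arr[, b, ] <- matrix(counts[, b], nP, nS)
    samples[[ti]] <- panelSample(
      subject = config$subject, timepoint = tps[ti],
      isPretreatment = ti == preIdx, counts = arr, ref = refMat,
      reads = config$depth[, ti])
  }
  names(samples) <- tps
  samples
}
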
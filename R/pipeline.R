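.writeManifest <- function(outDir, step, config, seed) {
  manifest <- list(
    package = "abequant",
    version = as.character(utils::packageVersion("abequant")),
    step = step,
    seed = seed,
    config = config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}

#' Run the full amplicon quantification pipeline
#'
#' FASTQ in, summaries out: merges pairs, applies the quality filter and
#' primer anchoring, aligns to the wild-type amplicon, and writes the
#' filter report, position table, combination table, indel catalog and a
#' JSON summary. Outputs are deterministic for a given input, so reruns
#' are byte-identical.
#'
#' @param fastq1,fastq2 FASTQ paths (`fastq2 = NULL` for pre-merged
#'   reads).
#' @param locus an [AmpliconLocus-class] or the path to a locus YAML.
#' @param outDir output directory (created).
#' @param sample sample identifier.
#' @param seed recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @param ... thresholds forwarded to [processReads()] and
#'   [quantifyAmplicon()].
#' @return invisibly, the quantification list (see
#'   [quantifyAmplicon()]), with the filter report attached.
#' @export
runQuantify <- function(fastq1, fastq2 = NULL, locus, outDir,
                        sample = "sample", seed = NA_integer_, ...) {
  if (is.character(locus)) locus <- readLocusYaml(locus)
  if (!file.exists(fastq1)) stop("FASTQ not found: ", fastq1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dots <- list(...)
  prArgs <- dots[names(dots) %in% names(formals(processReads))]
  qArgs <- dots[names(dots) %in% names(formals(quantifyAmplicon))]

  r1 <- readFastq(fastq1)
  if (!length(r1$seq)) stop("empty FASTQ: ", fastq1)
  if (!is.null(fastq2)) {
    r2 <- readFastq(fastq2)
    pr <- do.call(processReads, c(list(r1$seq, r1$qual, r2$seq, r2$qual,
                                       locus = locus, id = r1$id), prArgs))
  } else {
    pr <- do.call(processReads, c(list(r1$seq, r1$qual, locus = locus,
                                       id = r1$id), prArgs))
  }
  if (!length(pr$seq)) stop("no reads survived filtering")
  q <- do.call(quantifyAmplicon, c(list(pr$seq, locus, sample = sample),
                                   qArgs))

  writeTsv(filterReportAsData(pr$report), file.path(outDir, "filter_report.tsv"))
  f <- baseFrequencies(q$positions)
  posDf <- data.frame(position = 1:20, ref = refBases(q$positions),
                      baseCounts(q$positions),
                      freq_A = f[, "A"], freq_C = f[, "C"],
                      freq_G = f[, "G"], freq_T = f[, "T"])
  writeTsv(posDf, file.path(outDir, "position_table.tsv"))
  writeTsv(q$combinations, file.path(outDir, "combination_table.tsv"))
  writeTsv(q$indels, file.path(outDir, "indel_catalog.tsv"))
  writeTsv(q$cytosine, file.path(outDir, "cytosine_table.tsv"))

  np <- locus@namedPositions
  aPos <- np[startsWith(names(np), "A")]
  er <- errorRates(q$positions)
  summary <- list(
    sample = sample,
    retained_reads = q$nRetained,
    class_counts = as.list(q$classCounts),
    editing_frequency = as.list(stats::setNames(er[aPos], names(aPos))),
    indel_cumulative_frequency = attr(q$indels, "cumulativeFrequency"))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .writeManifest(outDir, "quantify",
                 list(fastq1 = fastq1, fastq2 = fastq2,
                      locus = locus@name, sample = sample, options = dots),
                 seed)
  q$report <- pr$report
  invisible(q)
}

#' Run the off-target panel caller
#'
#' Reads per-sample per-site count tables (TSV, see
#' [readPanelCountsTsv()]) described by a panel YAML, runs SNP
#' classification, background estimation, candidate nomination and the
#' longitudinal t-test, and writes the background model JSON, the calls
#' TSV, a BED of significant sites and the longitudinal summary TSV.
#'
#' The panel YAML must contain `subject`, and `samples`: a list of
#' entries with `timepoint`, `counts` (TSV path, relative to the YAML)
#' and `pretreatment: true` on exactly one entry. Optional keys `sites`
#' (site name to genomic `contig:position` map) and `annotations`
#' (BED/GFF path) enable nearest-gene annotation of significant calls.
#'
#' @param panelYaml path to the panel definition YAML.
#' @param outDir output directory (created).
#' @param seed recorded in the manifest.
#' @param alpha,floor,minReads,minPreFrequency,presenceFloor caller
#'   thresholds (see [callOfftargets()]).
#' @return invisibly, the [callOfftargets()] result.
#' @export
runPanel <- function(panelYaml, outDir, seed = NA_integer_, alpha = 0.05,
                     floor = 0.005, minReads = 1000L,
                     minPreFrequency = 0.10, presenceFloor = 0.10) {
  if (!file.exists(panelYaml)) stop("panel YAML not found: ", panelYaml)
  y <- yaml::read_yaml(panelYaml)
  base <- dirname(panelYaml)
  if (is.null(y$samples) || !length(y$samples))
    stop("panel YAML lists no samples")
  pretreat <- vapply(y$samples, function(s) isTRUE(s$pretreatment),
                     logical(1))
  if (sum(pretreat) != 1L)
    stop("exactly one pre-treatment sample is required ",
         "(the SNP and background rules need it)")
  samples <- lapply(y$samples, function(s) {
    readPanelCountsTsv(file.path(base, s$counts),
                       subject = y$subject %||% "subject",
                       timepoint = s$timepoint,
                       isPretreatment = isTRUE(s$pretreatment))
  })
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  res <- callOfftargets(samples, alpha = alpha, floor = floor,
                        minReads = minReads,
                        minPreFrequency = minPreFrequency,
                        presenceFloor = presenceFloor)
  bg <- res$background
  jsonlite::write_json(
    list(subject = bg@subject, mean_error = bg@meanError,
         sd_error = bg@sdError, threshold = bg@meanError + 2 * bg@sdError,
         n_positions = bg@nPositions,
         snp_positions = bg@snpPositions),
    file.path(outDir, "background.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeTsv(res$calls, file.path(outDir, "calls.tsv"))
  long <- summarizePanel(res$calls, samples, minReads)
  writeTsv(long, file.path(outDir, "longitudinal.tsv"))

  sig <- res$calls[!is.na(res$calls$significant) & res$calls$significant, ,
                   drop = FALSE]
  siteMap <- y$sites
  bed <- if (nrow(sig) && !is.null(siteMap)) {
    coords <- strsplit(unlist(siteMap[sig$site]), ":")
    data.frame(contig = vapply(coords, `[`, "", 1L),
               start = as.integer(vapply(coords, `[`, "", 2L)) - 1L +
                 sig$position - 1L,
               end = as.integer(vapply(coords, `[`, "", 2L)) +
                 sig$position - 1L,
               name = paste0(sig$site, "_p", sig$position),
               score = 0L, strand = ".")
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  }
  utils::write.table(bed, file.path(outDir, "significant.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (nrow(sig) && !is.null(siteMap) && !is.null(y$annotations)) {
    ann <- annotateNearestGene(
      data.frame(contig = bed$contig, position = bed$end),
      file.path(base, y$annotations))
    writeTsv(cbind(sig[, c("site", "position", "alt")], ann),
             file.path(outDir, "nearest_gene.tsv"))
  }
  .writeManifest(outDir, "panel",
                 list(panel = panelYaml, alpha = alpha, floor = floor,
                      min_reads = minReads), seed)
  invisible(res)
}

#' Simulate reads / a panel / colonies to disk
#'
#' Thin wrappers pairing the simulators with their writers, used by the
#' command-line interface.
#'
#' @param outDir output directory.
#' @param seed integer seed overriding the config's.
#' @param config a [simConfig()], [panelSimConfig()], or colony
#'   parameters.
#' @return invisibly, the paths written.
#' @export
runSimulateReads <- function(config = simConfig(), outDir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulateAmpliconReads(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeSimulatedFastq(sim, outDir)
  writeLocusYaml(config$locus, file.path(outDir, "locus.yaml"))
  .writeManifest(outDir, "simulate-reads",
                 config[setdiff(names(config), "locus")], config$seed)
  invisible(paths)
}

#' @rdname runSimulateReads
#' @export
runSimulatePanel <- function(config = panelSimConfig(), outDir,
                             seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  panel <- simulatePanel(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(panel, function(sm) {
    f <- paste0("counts_", sm@timepoint, ".tsv")
    writePanelCountsTsv(sm, file.path(outDir, f))
    list(timepoint = sm@timepoint, counts = f,
         pretreatment = isPretreatment(sm))
  })
  yaml::write_yaml(list(subject = config$subject,
                        samples = unname(entries)),
                   file.path(outDir, "panel.yaml"))
  .writeManifest(outDir, "simulate-panel",
                 config[setdiff(names(config), c("sites", "depth"))],
                 config$seed)
  invisible(file.path(outDir, "panel.yaml"))
}

#' Genotype colony trace CSVs
#'
#' @param traceDir directory of trace CSVs (see [readTraceCsv()]).
#' @param protospacerStart row index where the protospacer begins in the
#'   traces.
#' @param outDir output directory.
#' @param position tracked protospacer position.
#' @param lo,hi genotype thresholds.
#' @return invisibly, the genotype call data.frame.
#' @export
runColonies <- function(traceDir, protospacerStart, outDir, position = 9L,
                        lo = 0.2, hi = 0.8) {
  files <- sort(list.files(traceDir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trace CSVs found in ", traceDir)
  traces <- lapply(files, readTraceCsv, protospacerStart = protospacerStart)
  calls <- callColonyGenotypes(traces, position = position, lo = lo,
                               hi = hi)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(calls, file.path(outDir, "genotypes.tsv"))
  writeTsv(summarizeColonyGenotypes(calls),
           file.path(outDir, "genotype_summary.tsv"))
  .writeManifest(outDir, "colonies",
                 list(trace_dir = traceDir, position = position,
                      lo = lo, hi = hi), NA_integer_)
  invisible(calls)
}

#' Enumerate and rank candidate sites from a FASTA
#'
#' @param fasta reference FASTA path.
#' @param spacer 20-mer spacer.
#' @param outDir output directory.
#' @param pamPattern,maxMismatches see [enumerateCandidateSites()].
#' @param k panel size for [rankAndSelect()]; `NULL` keeps all sites.
#' @return invisibly, the selected `GRanges`.
#' @export
runDiscover <- function(fasta, spacer, outDir, pamPattern = "NNN",
                        maxMismatches = 4L, k = NULL) {
  sites <- enumerateCandidateSites(fasta, spacer, pamPattern,
                                   maxMismatches)
  if (!is.null(k)) sites <- rankAndSelect(sites, k)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  exportCandidateSites(sites, bedPath = file.path(outDir, "sites.bed"),
                       tsvPath = file.path(outDir, "sites.tsv"))
  .writeManifest(outDir, "discover",
                 list(fasta = fasta, spacer = spacer, pam = pamPattern,
                      max_mismatches = maxMismatches, k = k), NA_integer_)
  invisible(sites)
}
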
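#' Read a FASTQ file
#'
#' Gzip-aware (via Biostrings). Returns plain character vectors, the
#' representation the processing kernels work on.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return list with `id`, `seq`, `qual` character vectors.
#' @export
readFastq <- function(path) {
  # Biostrings warns about dropping the (empty) metadata columns it
  # attaches itself while pairing sequences with qualities; muffle it
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  S4Vectors::mcols(x) <- NULL
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

#' Write a FASTQ file (Sanger Phred+33)
#'
#' @param id,seq,qual read names, sequences and quality strings.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq),
    Biostrings::PhredQuality(qual))
  names(x) <- id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' Deterministic plain-text writer used for all tabular outputs.
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a Sanger trace base-proportion CSV
#'
#' Expected columns: `position`, `A`, `C`, `G`, `T`; proportions per row
#' are renormalised to sum to 1.
#'
#' @param path CSV file.
#' @param id colony identifier (defaults to the file name).
#' @param protospacerStart row index where the protospacer begins.
#' @return a [TraceProportions-class].
#' @export
readTraceCsv <- function(path, protospacerStart,
                         id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$position), ]
  m <- as.matrix(df[, .BASES])
  m <- m / rowSums(m)
  rownames(m) <- df$position
  traceProportions(id, m, protospacerStart)
}

#' Read a per-site position-by-base count TSV
#'
#' Expected columns: `site`, `position`, `ref`, `A`, `C`, `G`, `T`. Used
#' to assemble [PanelSample-class] objects from precomputed count tables.
#'
#' @param path TSV file.
#' @param subject,timepoint sample labels.
#' @param isPretreatment `TRUE` for the pre-treatment sample.
#' @return a [PanelSample-class].
#' @export
readPanelCountsTsv <- function(path, subject, timepoint, isPretreatment) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("site", "position", "ref", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("panel counts TSV must have columns: ", paste(need, collapse = ", "))
  sites <- unique(df$site)
  counts <- lapply(sites, function(s) {
    d <- df[df$site == s, ]
    d <- d[order(d$position), ]
    m <- as.matrix(d[, .BASES])
    rownames(m) <- d$position
    m
  })
  names(counts) <- sites
  refs <- lapply(sites, function(s) {
    d <- df[df$site == s, ]
    d$ref[order(d$position)]
  })
  names(refs) <- sites
  panelSample(subject, timepoint, isPretreatment, counts, refs)
}

#' Write a PanelSample as a per-site count TSV
#'
#' @param sample a [PanelSample-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePanelCountsTsv <- function(sample, path) {
  sites <- siteNames(sample)
  rows <- lapply(sites, function(s) {
    m <- sample@counts[, , s]
    data.frame(site = s, position = seq_len(nrow(m)),
               ref = sample@ref[, match(s, sites)],
               A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"])
  })
  writeTsv(do.call(rbind, rows), path)
}
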
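#' Per-base depth from an indexed BAM file
#'
#' Piles up one chromosome of a coordinate-sorted, indexed BAM into a
#' [depth_track]. Reads with mapping quality below `mapq_min`, duplicates
#' (when `drop_duplicates`), secondary/supplementary alignments and unmapped
#' records are excluded. Depth is counted along the aligned reference span:
#' CIGAR deletions (`D`) advance the span and are covered, reference skips
#' (`N`) advance it without coverage, insertions and clips do not consume
#' reference — conventional pileup semantics.
#'
#' @param alignment_file Path to a coordinate-sorted BAM with a `.bai`
#'   index.
#' @param chrom Chromosome name; must be present in the BAM header.
#' @param mapq_min Minimum mapping quality (default 1, excluding
#'   multi-mapped MAPQ-0 reads).
#' @param drop_duplicates Exclude reads flagged as duplicates.
#' @return A [depth_track] covering `[0, chromosome length)`.
#' @export
read_depth <- function(alignment_file, chrom, mapq_min = 1L,
                       drop_duplicates = TRUE) {
  if (!file.exists(alignment_file))
    stop("alignment file not found: ", alignment_file)
  bf <- tryCatch(Rsamtools::BamFile(alignment_file),
                 error = function(e) stop("cannot open BAM: ",
                                          conditionMessage(e)))
  if (is.na(Rsamtools::index(bf)) || !file.exists(Rsamtools::index(bf)))
    stop("BAM index (.bai) not found for ", alignment_file)
  sq <- Rsamtools::scanBamHeader(bf)$targets
  if (!chrom %in% names(sq))
    stop("chromosome ", chrom, " is absent from the BAM header")
  L <- unname(sq[[chrom]])
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flags, mapqFilter = as.integer(mapq_min),
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, L)))
  aln <- GenomicAlignments::readGAlignments(bf, param = param)
  cov <- GenomicAlignments::coverage(aln)[[chrom]]
  depth <- as.numeric(cov)
  if (length(depth) < L) depth <- c(depth, numeric(L - length(depth)))
  depth_track(chrom, depth[seq_len(L)], 0L)
}

#' Write / read a reference baseline archive
#'
#' The archive is a compressed keyed container (R serialization, gzip): one
#' entry per chromosome holding the expected per-position depth `p`, its
#' mask and the smoothed series `p_bar`, plus a metadata entry recording the
#' format version, smoothing window, stride, number of controls, pooling
#' method, scale factors and genome build. `read_baseline(write_baseline(a))`
#' reproduces the archive bit-exactly and refuses archives from an
#' incompatible format version.
#'
#' @param archive A `baseline_archive` (from [build_baseline] or
#'   [simulate_baseline]).
#' @param path File path.
#' @return `write_baseline`: invisibly, `path`. `read_baseline`: the
#'   `baseline_archive`.
#' @export
write_baseline <- function(archive, path) {
  if (!inherits(archive, "baseline_archive"))
    stop("archive must be a baseline_archive")
  if (is.null(archive$metadata))
    stop("archive is missing its metadata block")
  saveRDS(unclass(archive), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  if (!file.exists(path)) stop("baseline archive not found: ", path)
  raw <- readRDS(path)
  md <- raw$metadata
  if (is.null(md) || is.null(md$format) || md$format != "shallowcnv-baseline")
    stop("not a shallowcnv baseline archive (metadata block missing)")
  if (is.null(md$format_version) || md$format_version != 1L)
    stop("incompatible baseline archive format version: ",
         md$format_version)
  structure(raw, class = "baseline_archive")
}

#' Write CNV calls to BED or TSV
#'
#' BED dialect: 0-based half-open `chrom`, `start`, `end`, `name` (the call
#' type) and `score` (`round(logR * 1000)`). TSV dialect: a header row
#' `chrom, start, end, type, logR, size` preceded by optional `#` comment
#' lines (used to record the resolved configuration). Calls must be sorted
#' by (chrom, start).
#'
#' @param calls data.frame with columns `chrom`, `start`, `end`, `type`,
#'   `logR` (and `size` for TSV; recomputed if absent), or a `cnv_scan`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param header_lines Character vector written as `#`-prefixed comment
#'   lines (TSV and BED).
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed"),
                        header_lines = NULL) {
  format <- match.arg(format)
  if (inherits(calls, "cnv_scan")) calls <- calls$calls
  need <- c("chrom", "start", "end", "type", "logR")
  if (!all(need %in% names(calls)))
    stop("calls must have columns ", paste(need, collapse = ", "))
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$start)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, start)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  if (format == "bed") {
    if (nrow(calls))
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d", calls$chrom,
                         as.integer(calls$start), as.integer(calls$end),
                         calls$type, as.integer(round(calls$logR * 1000))),
                 con)
  } else {
    if (is.null(calls$size)) calls$size <- calls$end - calls$start
    writeLines("chrom\tstart\tend\ttype\tlogR\tsize", con)
    if (nrow(calls))
      writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g\t%d", calls$chrom,
                         as.integer(calls$start), as.integer(calls$end),
                         calls$type, calls$logR, as.integer(calls$size)),
                 con)
  }
  invisible(path)
}

#' Read a TSV call report written by [write_calls]
#'
#' @param path Path to a TSV call report (comment lines allowed).
#' @return data.frame with columns `chrom`, `start`, `end`, `type`, `logR`,
#'   `size`.
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "logR", "size")
  if (!all(need %in% names(df)))
    stop("not a shallowcnv TSV call report: ", path)
  df
}

#' Write / read a depth track as a compressed text array
#'
#' One gzipped TSV per chromosome: `#`-prefixed metadata lines
#' (`chrom`, `start_offset`) followed by `depth` and `mask` columns. Used by
#' the command-line front end to pass per-base tracks between subcommands.
#'
#' @param track A [depth_track].
#' @param path Output path (conventionally `.depth.tsv.gz`).
#' @return `write_depth_track`: invisibly, `path`; `read_depth_track`: the
#'   [depth_track].
#' @export
write_depth_track <- function(track, path) {
  stop_if_not_track(track)
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# chrom = %s", track$chrom),
               sprintf("# start_offset = %d", track$start_offset),
               "depth\tmask"), con)
  writeLines(sprintf("%.10g\t%d", track$depth, as.integer(track$mask)), con)
  invisible(path)
}

#' @rdname write_depth_track
#' @export
read_depth_track <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  meta <- c(readLines(con, n = 1L), readLines(con, n = 1L))
  chrom <- sub("^# chrom = ", "", meta[1L])
  off <- as.integer(sub("^# start_offset = ", "", meta[2L]))
  if (is.na(off) || !startsWith(meta[1L], "# chrom"))
    stop("not a shallowcnv depth track file: ", path)
  df <- utils::read.table(con, header = TRUE, sep = "\t")
  depth_track(chrom, df$depth, off, as.logical(df$mask))
}
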
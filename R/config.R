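#' Caller configuration
#'
#' Collects every tunable of the detection pipeline in one place. Defaults
#' reproduce the method's published operating point: smoothing window
#' `n = 3000` bp with per-base monitoring (`stride = 1`), CUSUM reference
#' value `K = 0.3`, control-limit factors `a = 3/2` and `b = 1/2`
#' (the expected depth change of a single-copy gain/loss in a diploid
#' genome), calling threshold `logr_threshold = 0.3`, and a 1000 bp minimum
#' CNV size.
#'
#' @param K CUSUM reference value (allowance); deviations of the logR target
#'   smaller than `K` never accumulate. Smaller values increase sensitivity.
#' @param a,b Control-limit factors: `UCL = n*log2(a)`, `LCL = n*log2(b)`.
#'   Require `a > 1`, `0 < b < 1`.
#' @param n Segment sliding-window size in bp (`n >= 3000` recommended at
#'   shallow coverage; smaller values are accepted for small test genomes).
#' @param stride Spacing of monitoring points in bp; 1 = per-base monitoring.
#' @param epsilon Pseudocount added to numerator and denominator of every
#'   log2 ratio; `NULL` means `1/n`.
#' @param logr_threshold Per-region calling threshold; gain iff
#'   `logR > logr_threshold`, loss iff `logR < -logr_threshold` (strict).
#' @param min_cnv_size Minimum reported CNV size in bp.
#' @param min_span Minimum CUSUM alarm span in bp; shorter alarms are
#'   discarded as transient alerts.
#' @param merge_gap Alarms of the same direction closer than this many bp are
#'   merged; `NULL` means `n` (gaps shorter than one smoothing window are
#'   artifacts of the smoother).
#' @param end_rule How the end of an alarm region is estimated: `"peak"`
#'   (position of the extreme CUSUM statistic within the excursion, the
#'   standard CUSUM changepoint estimate) or `"zero"` (first return of the
#'   statistic to zero; overshoots the true end by roughly peak/K positions
#'   and is provided for diagnostics).
#' @param mapq_min Minimum mapping quality for reads entering the pileup.
#' @param drop_duplicates Drop reads flagged as PCR/optical duplicates.
#' @param all_regions If `TRUE`, `call_cnvs()` also scores and reports
#'   non-candidate regions whose region logR exceeds the threshold
#'   (diagnostic mode); default reports candidate-derived calls only.
#' @param merge_calls If `TRUE`, adjacent same-type calls separated by less
#'   than `n` bp are merged after classification.
#' @param keep_chart If `TRUE`, `call_cnvs()` retains the per-position
#'   monitoring series (x-bar, p-bar, R, C+, C-) for control-chart plots.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(K = 0.3, a = 1.5, b = 0.5, n = 3000L, stride = 1L,
                          epsilon = NULL, logr_threshold = 0.3,
                          min_cnv_size = 1000L, min_span = 1000L,
                          merge_gap = NULL, end_rule = c("peak", "zero"),
                          mapq_min = 1L, drop_duplicates = TRUE,
                          all_regions = FALSE, merge_calls = FALSE,
                          keep_chart = FALSE) {
  end_rule <- match.arg(end_rule)
  stopifnot(K > 0, a > 1, b > 0, b < 1, n >= 1, stride >= 1,
            logr_threshold > 0, min_cnv_size >= 1)
  if (is.null(epsilon)) epsilon <- 1 / n
  if (is.null(merge_gap)) merge_gap <- n
  structure(
    list(K = K, a = a, b = b, n = as.integer(n), stride = as.integer(stride),
         epsilon = epsilon, logr_threshold = logr_threshold,
         min_cnv_size = as.integer(min_cnv_size),
         min_span = as.integer(min_span), merge_gap = as.integer(merge_gap),
         end_rule = end_rule, mapq_min = as.integer(mapq_min),
         drop_duplicates = drop_duplicates, all_regions = all_regions,
         merge_calls = merge_calls, keep_chart = keep_chart),
    class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat("<caller_config>\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

# One "key = value" line per tunable, for reproducible output headers.
config_header_lines <- function(config, version = NULL) {
  if (is.null(version))
    version <- as.character(utils::packageVersion("shallowcnv"))
  vals <- vapply(config, function(v) paste(format(v), collapse = ","),
                 character(1))
  c(sprintf("shallowcnv_version = %s", version),
    sprintf("%s = %s", names(vals), vals))
}

# Parse a flat "key = value" config file; used by the command-line front end.
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[[2L]], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}
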
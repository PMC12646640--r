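#' log2 depth-ratio monitoring series
#'
#' Computes the CUSUM target value at every monitoring point: the log2 ratio
#' of the sample's smoothed depth to the baseline's smoothed expected depth,
#' `R_t = log2((xbar_t + eps) / (pbar_t + eps))`. A pseudocount `epsilon`
#' (default `1/n`) keeps the ratio finite when a smoothed value is zero;
#' positions where the baseline expectation is exactly zero are masked
#' rather than reported as infinite.
#'
#' @param sample A `segment_series` for the test sample (from
#'   [segment_means]).
#' @param baseline Either a `baseline_archive` (the matching chromosome's
#'   smoothed series is used) or a `segment_series` of expected depth.
#' @param epsilon Pseudocount; `NULL` means `1/n`.
#' @return An object of class `logr_series` with fields `chrom`,
#'   `positions`, `values`, `mask`, `n`, `stride`.
#' @export
log_ratio <- function(sample, baseline, epsilon = NULL) {
  if (!inherits(sample, "segment_series"))
    stop("sample must be a segment_series")
  pb <- baseline_series_for(baseline, sample$chrom)
  if (pb$n != sample$n || pb$stride != sample$stride)
    stop("sample and baseline were smoothed with different n or stride")
  if (length(pb$values) != length(sample$values) ||
      pb$positions[1L] != sample$positions[1L])
    stop("sample and baseline monitoring positions do not match")
  if (is.null(epsilon)) epsilon <- 1 / sample$n
  mask <- sample$mask | pb$mask | !is.finite(pb$values) | pb$values == 0 |
    !is.finite(sample$values)
  vals <- rep(NA_real_, length(sample$values))
  ok <- !mask
  vals[ok] <- log2((sample$values[ok] + epsilon) / (pb$values[ok] + epsilon))
  structure(
    list(chrom = sample$chrom, positions = sample$positions, values = vals,
         mask = mask, n = sample$n, stride = sample$stride),
    class = "logr_series")
}

baseline_series_for <- function(baseline, chrom) {
  if (inherits(baseline, "segment_series")) return(baseline)
  if (inherits(baseline, "baseline_archive")) {
    entry <- baseline$chromosomes[[chrom]]
    if (is.null(entry)) stop("baseline does not cover chromosome ", chrom)
    return(entry$p_bar)
  }
  stop("baseline must be a baseline_archive or segment_series")
}

#' Two-sided CUSUM statistics
#'
#' Runs the tabular CUSUM recursions on a logR target series:
#' `C+_t = max(0, R_t - K + C+_{t-1})` accumulates persistent upward shifts
#' (copy-number gain) and `C-_t = min(0, R_t + K + C-_{t-1})` persistent
#' downward shifts (loss), both started at zero. The reference value `K` is
#' the per-step allowance: deviations of `R_t` within `±K` never accumulate,
#' so short noise excursions decay while a sustained shift grows linearly.
#' The two statistics are accumulated independently and do not interfere.
#' Masked monitoring points carry the previous statistics forward unchanged.
#'
#' @param r A `logr_series`, or a bare numeric vector of target values.
#' @param K Reference value (> 0); default 0.3, matching the usual logR
#'   alert threshold.
#' @return An object of class `cusum_series` with fields `chrom`,
#'   `positions`, `Cplus` (>= 0), `Cminus` (<= 0), `mask`, `K`, `n`,
#'   `stride`.
#' @export
cusum_series <- function(r, K = 0.3) {
  if (K <= 0) stop("K must be > 0")
  if (is.numeric(r))
    r <- structure(list(chrom = NA_character_,
                        positions = seq_along(r) - 1L,
                        values = as.numeric(r), mask = logical(length(r)),
                        n = NA_integer_, stride = 1L),
                   class = "logr_series")
  if (!inherits(r, "logr_series")) stop("r must be a logr_series or numeric")
  cs <- .cusum_recursion(r$values, K, r$mask)
  structure(
    list(chrom = r$chrom, positions = r$positions, Cplus = cs$Cplus,
         Cminus = cs$Cminus, mask = r$mask, K = K, n = r$n,
         stride = r$stride),
    class = "cusum_series")
}

#' @export
print.cusum_series <- function(x, ...) {
  cat(sprintf("<cusum_series> %s: %d points, K=%g, max C+=%.3g, min C-=%.3g\n",
              x$chrom, length(x$Cplus), x$K, max(x$Cplus), min(x$Cminus)))
  invisible(x)
}

#' Control limits for the CUSUM chart
#'
#' `UCL = n * log2(a)` and `LCL = n * log2(b)`, with center line 0. The
#' defaults `a = 3/2`, `b = 1/2` are the expected depth ratios of a
#' single-copy gain and loss in a diploid genome, so the limits equal the
#' cumulative deviation a single-copy event sustained over one smoothing
#' window would produce. Larger `a` / smaller `b` increase specificity;
#' smaller `a` / larger `b` increase sensitivity.
#'
#' @param n Smoothing-window size in bp (>= 1).
#' @param a Upper factor, > 1.
#' @param b Lower factor, in (0, 1).
#' @return An object of class `control_limits` with fields `a`, `b`, `n`,
#'   `UCL` (> 0), `LCL` (< 0).
#' @export
control_limits <- function(n = 3000L, a = 1.5, b = 0.5) {
  if (!(a > 1)) stop("a must be > 1")
  if (!(b > 0 && b < 1)) stop("b must lie in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(list(a = a, b = b, n = as.integer(n),
                 UCL = n * log2(a), LCL = n * log2(b)),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("<control_limits> n=%d a=%g b=%g UCL=%.4g LCL=%.4g\n",
              x$n, x$a, x$b, x$UCL, x$LCL))
  invisible(x)
}

#' Partition a chromosome into candidate and non-candidate CNV regions
#'
#' Scans the CUSUM statistics for alarms. An excursion of `C+` is a maximal
#' run of positive values bounded by zeros; it raises a gain alarm when it
#' crosses the upper control limit (symmetrically for `C-` and the lower
#' limit). The alarm region starts at the last monitoring point where the
#' triggering statistic was zero before the crossing. Its end is estimated
#' by `end_rule`: `"peak"` (default) takes the position of the statistic's
#' extreme within the excursion — the standard CUSUM estimate of where the
#' shift ends, since after the shifted stretch the statistic drifts back at
#' rate `K`; `"zero"` extends to the first return to zero.
#'
#' Alarms of the same direction separated by less than `merge_gap` bp are
#' merged; alarms spanning fewer than `min_span` bp are discarded as
#' transient alerts. If a gain and a loss alarm overlap (possible on
#' oscillating data) they are trimmed at the midpoint of the overlap. The
#' complement of the surviving alarms is returned as `direction = "none"`
#' regions, so the regions tile the monitored span without overlap.
#'
#' @param C A `cusum_series`.
#' @param limits A `control_limits` built with the same `n`.
#' @param min_span Minimum alarm span in bp (default 1000, the conventional
#'   minimum CNV size).
#' @param merge_gap Merge distance in bp; `NULL` means `n`.
#' @param end_rule `"peak"` or `"zero"` (see Details).
#' @return A data.frame of class `candidate_regions` with columns `chrom`,
#'   `start`, `end` (0-based half-open bp), `direction`
#'   (`gain-candidate`/`loss-candidate`/`none`), `peak_stat`.
#' @export
extract_candidates <- function(C, limits, min_span = 1000L,
                               merge_gap = NULL, end_rule = c("peak", "zero")) {
  end_rule <- match.arg(end_rule)
  if (!inherits(C, "cusum_series")) stop("C must be a cusum_series")
  if (!inherits(limits, "control_limits"))
    stop("limits must be a control_limits object")
  if (!is.na(C$n) && C$n != limits$n)
    stop("cusum series and control limits use different n")
  if (is.null(merge_gap)) merge_gap <- if (is.na(C$n)) 0L else C$n
  stride <- C$stride
  span_lo <- C$positions[1L]
  span_hi <- C$positions[length(C$positions)] + stride

  gains <- alarm_intervals(C$Cplus, limits$UCL, upper = TRUE, C$positions,
                           stride, end_rule)
  losses <- alarm_intervals(-C$Cminus, -limits$LCL, upper = TRUE,
                            C$positions, stride, end_rule)
  losses$peak_stat <- -losses$peak_stat
  gains <- merge_alarms(gains, merge_gap, upper = TRUE)
  losses <- merge_alarms(losses, merge_gap, upper = FALSE)
  gains <- gains[gains$end - gains$start >= min_span, , drop = FALSE]
  losses <- losses[losses$end - losses$start >= min_span, , drop = FALSE]
  alarms <- trim_opposite_overlaps(gains, losses)
  alarms <- alarms[alarms$end - alarms$start >= min_span, , drop = FALSE]
  alarms <- alarms[order(alarms$start), , drop = FALSE]

  out <- tile_with_none(alarms, span_lo, span_hi)
  out$chrom <- C$chrom
  out <- out[, c("chrom", "start", "end", "direction", "peak_stat")]
  class(out) <- c("candidate_regions", "data.frame")
  out
}

# Alarm excursions of a statistic that must exceed `limit` (> 0); the series
# is oriented so that excursions are positive.
alarm_intervals <- function(stat, limit, upper, positions, stride, end_rule) {
  cross <- which(stat > limit)
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_stat = numeric(0))
  if (length(cross) == 0L) return(empty)
  pos_run <- stat > 0
  r <- rle(pos_run)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  run_start <- run_start[keep]; run_end <- run_end[keep]
  # runs containing at least one crossing (a crossing always lies inside a
  # positive run, so the last run starting at or before it is its run)
  hit <- unique(findInterval(cross, run_start))
  res <- lapply(hit, function(j) {
    i0 <- run_start[j]; i1 <- run_end[j]
    if (!any(stat[i0:i1] > limit)) return(NULL)
    i_end <- if (end_rule == "peak") i0 - 1L + which.max(stat[i0:i1]) else i1
    # start at the last zero before the excursion (excursion start - 1)
    i_begin <- max(i0 - 1L, 1L)
    data.frame(start = positions[i_begin],
               end = positions[i_end] + stride,
               peak_stat = max(stat[i0:i1]))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

merge_alarms <- function(a, merge_gap, upper) {
  if (nrow(a) < 2L) {
    a$direction <- if (nrow(a)) alarm_dir(upper) else character(0)
    return(a)
  }
  a <- a[order(a$start), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(a$start[-1L] - a$end[-nrow(a)] >= merge_gap)))
  merged <- do.call(rbind, lapply(split(a, grp), function(g)
    data.frame(start = min(g$start), end = max(g$end),
               peak_stat = g$peak_stat[which.max(abs(g$peak_stat))])))
  merged$direction <- alarm_dir(upper)
  merged
}

alarm_dir <- function(upper) if (upper) "gain-candidate" else "loss-candidate"

trim_opposite_overlaps <- function(gains, losses) {
  if (nrow(gains) == 0L && nrow(losses) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      peak_stat = numeric(0), direction = character(0)))
  if (nrow(gains)) gains$direction <- "gain-candidate"
  if (nrow(losses)) losses$direction <- "loss-candidate"
  for (i in seq_len(nrow(gains))) {
    for (j in seq_len(nrow(losses))) {
      lo <- max(gains$start[i], losses$start[j])
      hi <- min(gains$end[i], losses$end[j])
      if (lo < hi) {              # overlap: trim both at the midpoint
        mid <- (lo + hi) %/% 2L
        if (gains$start[i] < losses$start[j]) {
          gains$end[i] <- mid; losses$start[j] <- mid
        } else {
          losses$end[j] <- mid; gains$start[i] <- mid
        }
      }
    }
  }
  rbind(gains, losses)
}

tile_with_none <- function(alarms, span_lo, span_hi) {
  if (nrow(alarms) == 0L)
    return(data.frame(start = span_lo, end = span_hi, direction = "none",
                      peak_stat = NA_real_))
  alarms$start <- pmax(alarms$start, span_lo)
  alarms$end <- pmin(alarms$end, span_hi)
  rows <- list()
  cursor <- span_lo
  for (i in seq_len(nrow(alarms))) {
    if (alarms$start[i] > cursor)
      rows[[length(rows) + 1L]] <- data.frame(
        start = cursor, end = alarms$start[i], direction = "none",
        peak_stat = NA_real_)
    rows[[length(rows) + 1L]] <- alarms[i, c("start", "end", "direction",
                                             "peak_stat")]
    cursor <- alarms$end[i]
  }
  if (cursor < span_hi)
    rows[[length(rows) + 1L]] <- data.frame(
      start = cursor, end = span_hi, direction = "none",
      peak_stat = NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
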
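#' Region-level log2 copy ratio with a dynamic window
#'
#' Scores one region with a single window sized to the region itself: the
#' log2 ratio of summed sample depth to summed expected depth over
#' `[start, end)`, restricted to unmasked positions,
#' `logR = log2((sum x_i + eps) / (sum p_i + eps))`. Because the window
#' matches the region delimited by the control chart, small events are not
#' diluted by flanking normal sequence and large events are not split.
#'
#' @param region A list or one-row data.frame with `start` and `end`
#'   (0-based half-open bp).
#' @param sample A [depth_track] (corrected, normalized).
#' @param baseline A `baseline_archive` covering the sample's chromosome, or
#'   a [depth_track] of expected depth.
#' @param epsilon Pseudocount added to both sums (default `1/(end-start)`).
#' @return The region logR (scalar), or `NA` with attribute
#'   `uncallable = TRUE` when every position in the region is masked or the
#'   expected-depth sum is zero.
#' @export
region_logr <- function(region, sample, baseline, epsilon = NULL) {
  stop_if_not_track(sample)
  p_track <- baseline_track_for(baseline, sample$chrom)
  s <- max(as.integer(region$start), sample$start_offset)
  e <- min(as.integer(region$end), sample$start_offset + length(sample$depth))
  if (e <= s) stop("region lies outside the track")
  if (is.null(epsilon)) epsilon <- 1 / (e - s)
  idx <- (s - sample$start_offset + 1L):(e - sample$start_offset)
  ok <- !(sample$mask[idx] | p_track$mask[idx])
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "uncallable") <- TRUE
    return(out)
  }
  sx <- sum(sample$depth[idx][ok])
  sp <- sum(p_track$depth[idx][ok])
  if (sp == 0) {
    out <- NA_real_
    attr(out, "uncallable") <- TRUE
    return(out)
  }
  log2((sx + epsilon) / (sp + epsilon))
}

baseline_track_for <- function(baseline, chrom) {
  if (is_depth_track(baseline)) return(baseline)
  if (inherits(baseline, "baseline_archive")) {
    entry <- baseline$chromosomes[[chrom]]
    if (is.null(entry)) stop("baseline does not cover chromosome ", chrom)
    return(entry$p)
  }
  stop("baseline must be a baseline_archive or depth_track")
}

#' Classify a region logR as gain, loss or none
#'
#' Fixed-threshold classification with strict inequalities: `"gain"` iff
#' `logr > threshold`, `"loss"` iff `logr < -threshold`, otherwise
#' `"none"`. The default threshold 0.3 is the conventional logR alert level
#' (a single-copy gain in a pure diploid sample sits at +0.585, a
#' single-copy loss at -1).
#'
#' @param logr Numeric vector of region logR values (NA allowed: returns
#'   `"none"`).
#' @param threshold Positive threshold; default 0.3.
#' @return Character vector: `"gain"`, `"loss"` or `"none"`.
#' @export
classify_logr <- function(logr, threshold = 0.3) {
  if (threshold <= 0) stop("threshold must be > 0")
  out <- rep("none", length(logr))
  out[!is.na(logr) & logr > threshold] <- "gain"
  out[!is.na(logr) & logr < -threshold] <- "loss"
  out
}

#' Call CNVs from a sample against a reference baseline
#'
#' The full detection pipeline: per-base depth (read from a BAM file or
#' supplied as a [depth_track]) is optionally GC-corrected, normalized to
#' unit mean, smoothed with the segment sliding window, converted to a log2
#' depth-ratio series against the baseline, monitored with the two-sided
#' CUSUM chart, partitioned into candidate and non-candidate regions, and
#' finally each candidate region is re-scored with one dynamic, region-sized
#' window and classified as gain or loss. Regions whose region-level logR
#' does not exceed the threshold are dropped; surviving calls shorter than
#' `min_cnv_size` are discarded.
#'
#' @param sample A [depth_track], a list of depth_tracks (one per
#'   chromosome), or the path to a coordinate-sorted, indexed BAM file (all
#'   baseline chromosomes are then processed).
#' @param baseline A `baseline_archive` (see [build_baseline]); its `n` and
#'   `stride` must match `config`.
#' @param config A [caller_config].
#' @param gc Optional named list (per chromosome) with elements
#'   `gc_fraction` and `bin_size` for GC correction; `NULL` skips it.
#' @return An object of class `cnv_scan`: list with `calls` (data.frame
#'   `chrom`, `start`, `end`, `type`, `logR`, `size`, sorted), `regions`
#'   (the candidate/non-candidate partition with per-region logR), `config`,
#'   `limits`, and (when `config$keep_chart`) `chart`, a per-chromosome list
#'   of monitoring series for control-chart plots.
#' @export
call_cnvs <- function(sample, baseline, config = caller_config(), gc = NULL) {
  if (!inherits(baseline, "baseline_archive"))
    stop("baseline must be a baseline_archive")
  if (!inherits(config, "caller_config"))
    stop("config must be a caller_config")
  md <- baseline$metadata
  if (md$n != config$n)
    stop("baseline was built with n=", md$n, " but config has n=", config$n)
  if (md$stride != config$stride)
    stop("baseline was built with stride=", md$stride,
         " but config has stride=", config$stride)

  tracks <- resolve_sample_tracks(sample, baseline, config)
  limits <- control_limits(config$n, config$a, config$b)
  per_chrom <- lapply(tracks, call_one_chrom, baseline = baseline,
                      config = config, limits = limits, gc = gc)

  calls <- do.call(rbind, lapply(per_chrom, `[[`, "calls"))
  regions <- do.call(rbind, lapply(per_chrom, `[[`, "regions"))
  rownames(calls) <- rownames(regions) <- NULL
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  out <- list(calls = calls, regions = regions, config = config,
              limits = limits)
  if (config$keep_chart)
    out$chart <- lapply(per_chrom, `[[`, "chart")
  class(out) <- "cnv_scan"
  out
}

resolve_sample_tracks <- function(sample, baseline, config) {
  if (is_depth_track(sample)) return(stats::setNames(list(sample),
                                                     sample$chrom))
  if (is.list(sample) && all(vapply(sample, is_depth_track, logical(1))))
    return(stats::setNames(sample,
                           vapply(sample, `[[`, character(1), "chrom")))
  if (is.character(sample) && length(sample) == 1L) {
    chroms <- names(baseline$chromosomes)
    return(stats::setNames(
      lapply(chroms, function(ch)
        read_depth(sample, ch, mapq_min = config$mapq_min,
                   drop_duplicates = config$drop_duplicates)),
      chroms))
  }
  stop("sample must be a depth_track, a list of depth_tracks, or a BAM path")
}

call_one_chrom <- function(track, baseline, config, limits, gc) {
  entry <- baseline$chromosomes[[track$chrom]]
  if (is.null(entry))
    stop("baseline does not cover chromosome ", track$chrom)
  if (length(entry$p$depth) != length(track$depth) ||
      entry$p$start_offset != track$start_offset)
    stop("sample and baseline coordinates differ on ", track$chrom)
  if (!is.null(gc) && !is.null(gc[[track$chrom]]))
    track <- gc_correct(track, gc[[track$chrom]]$gc_fraction,
                        gc[[track$chrom]]$bin_size)
  # compare like with like: exclude baseline-masked positions from the sample
  track <- depth_track(track$chrom, track$depth, track$start_offset,
                       track$mask | entry$p$mask)
  track <- normalize_depth(track)
  xbar <- segment_means(track, n = config$n, stride = config$stride)
  r <- log_ratio(xbar, baseline, epsilon = config$epsilon)
  cu <- cusum_series(r, K = config$K)
  regions <- extract_candidates(cu, limits, min_span = config$min_span,
                                merge_gap = config$merge_gap,
                                end_rule = config$end_rule)
  regions$logR <- vapply(seq_len(nrow(regions)), function(i)
    as.numeric(region_logr(regions[i, ], track, baseline,
                           epsilon = config$epsilon)), numeric(1))
  regions$type <- classify_logr(regions$logR, config$logr_threshold)

  keep <- regions$type != "none" &
    (regions$end - regions$start) >= config$min_cnv_size
  if (!config$all_regions)
    keep <- keep & regions$direction != "none"
  calls <- regions[keep, c("chrom", "start", "end", "type", "logR")]
  if (config$merge_calls) calls <- merge_adjacent_calls(calls, config$n)
  calls$size <- calls$end - calls$start
  list(calls = calls, regions = regions,
       chart = if (config$keep_chart)
         data.frame(position = xbar$positions, xbar = xbar$values,
                    pbar = entry$p_bar$values, R = r$values,
                    Cplus = cu$Cplus, Cminus = cu$Cminus))
}

merge_adjacent_calls <- function(calls, gap) {
  if (nrow(calls) < 2L) return(calls)
  calls <- calls[order(calls$start), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(
    calls$start[-1L] - calls$end[-nrow(calls)] >= gap |
      calls$type[-1L] != calls$type[-nrow(calls)])))
  do.call(rbind, lapply(split(calls, grp), function(g)
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               type = g$type[1L],
               logR = stats::weighted.mean(g$logR, g$end - g$start))))
}

#' Fixed-window reference caller
#'
#' A deliberately simple fixed-bin caller kept as an internal point of
#' comparison for the dynamic-window strategy: the chromosome is tiled with
#' fixed `bin_size` bins, each bin's logR against the baseline is computed
#' and thresholded, and adjacent same-type bins are merged. Events much
#' smaller than the bin are diluted below the threshold and missed — the
#' failure mode the dynamic window avoids.
#'
#' @param sample A [depth_track] (it is normalized internally).
#' @param baseline A `baseline_archive`.
#' @param bin_size Fixed bin width in bp (default 100 kb).
#' @param threshold logR calling threshold (default 0.3).
#' @return A data.frame of calls (`chrom`, `start`, `end`, `type`, `logR`,
#'   `size`).
#' @export
fixed_window_calls <- function(sample, baseline, bin_size = 1e5,
                               threshold = 0.3) {
  stop_if_not_track(sample)
  entry <- baseline$chromosomes[[sample$chrom]]
  if (is.null(entry)) stop("baseline does not cover ", sample$chrom)
  sample <- depth_track(sample$chrom, sample$depth, sample$start_offset,
                        sample$mask | entry$p$mask)
  sample <- normalize_depth(sample)
  L <- length(sample$depth)
  starts <- seq(sample$start_offset, sample$start_offset + L - 1L,
                by = bin_size)
  ends <- pmin(starts + bin_size, sample$start_offset + L)
  logr <- vapply(seq_along(starts), function(i)
    as.numeric(region_logr(list(start = starts[i], end = ends[i]),
                           sample, baseline)), numeric(1))
  type <- classify_logr(logr, threshold)
  calls <- data.frame(chrom = sample$chrom, start = starts, end = ends,
                      type = type, logR = logr)
  calls <- calls[calls$type != "none", , drop = FALSE]
  calls <- merge_adjacent_calls(calls, gap = 1L)
  calls$size <- calls$end - calls$start
  rownames(calls) <- NULL
  calls
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat(sprintf("<cnv_scan> %d call(s) on %d chromosome(s)\n",
              nrow(x$calls), length(unique(x$regions$chrom))))
  if (nrow(x$calls)) print(x$calls, row.names = FALSE)
  invisible(x)
}

#' @method summary cnv_scan
#' @export
summary.cnv_scan <- function(object, ...) {
  calls <- object$calls
  cat("CNV scan summary\n")
  cat(sprintf("  smoothing window n = %d bp, stride = %d, K = %g\n",
              object$config$n, object$config$stride, object$config$K))
  cat(sprintf("  control limits: UCL = %.4g, LCL = %.4g\n",
              object$limits$UCL, object$limits$LCL))
  cand <- object$regions[object$regions$direction != "none", , drop = FALSE]
  cat(sprintf("  candidate regions: %d (%d gain, %d loss)\n", nrow(cand),
              sum(cand$direction == "gain-candidate"),
              sum(cand$direction == "loss-candidate")))
  cat(sprintf("  calls: %d (%d gain, %d loss)", nrow(calls),
              sum(calls$type == "gain"), sum(calls$type == "loss")))
  if (nrow(calls))
    cat(sprintf("; sizes %s-%s bp", format(min(calls$size), big.mark = ","),
                format(max(calls$size), big.mark = ",")))
  cat("\n")
  invisible(object)
}

#' @method as.data.frame cnv_scan
#' @export
as.data.frame.cnv_scan <- function(x, ...) x$calls

#' Control-chart plot of a CNV scan
#'
#' Plots the logR monitoring series and the two CUSUM statistics with their
#' control limits for one chromosome, marking called CNVs. Requires the scan
#' to have been run with `keep_chart = TRUE`.
#'
#' @param x A `cnv_scan`.
#' @param chrom Chromosome to plot (default: first).
#' @param ... Passed to [graphics::plot].
#' @method plot cnv_scan
#' @export
plot.cnv_scan <- function(x, chrom = NULL, ...) {
  if (is.null(x$chart))
    stop("scan was run without keep_chart = TRUE; no chart data retained")
  if (is.null(chrom)) chrom <- names(x$chart)[1L]
  ch <- x$chart[[chrom]]
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(ch$position, ch$R, type = "l", col = "grey40",
                 xlab = "", ylab = "logR", main = chrom, ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(ch$position, ch$Cplus, type = "l", col = "firebrick",
                 ylim = range(c(ch$Cplus, ch$Cminus, x$limits$UCL,
                                x$limits$LCL), na.rm = TRUE),
                 xlab = "position", ylab = "CUSUM")
  graphics::lines(ch$position, ch$Cminus, col = "navy")
  graphics::abline(h = c(x$limits$UCL, x$limits$LCL), lty = 3)
  calls <- x$calls[x$calls$chrom == chrom, , drop = FALSE]
  if (nrow(calls))
    graphics::rect(calls$start, x$limits$LCL, calls$end, x$limits$UCL,
                   col = grDevices::adjustcolor("gold", 0.25), border = NA)
  invisible(x)
}
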
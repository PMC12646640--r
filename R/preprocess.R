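#' Segment sliding-window means
#'
#' Smooths a per-base depth track with a fixed segment sliding window: the
#' mean depth of the `n` bases starting at position `t` is assigned to the
#' monitoring point at `t`, for `t = 0, stride, 2*stride, ...`. At shallow
#' coverage per-base depth is zero-inflated; by the central limit theorem the
#' window mean of `n` positions is approximately normal once `n` is a few
#' thousand, which is what makes a normal-theory control chart applicable
#' downstream.
#'
#' Masked positions are excluded from the window mean (the mean is taken over
#' unmasked positions only); a monitoring point is itself masked when more
#' than `max_masked_frac` of its window is masked.
#'
#' @param track A [depth_track].
#' @param n Window size in bp; must not exceed the track length.
#' @param stride Spacing between monitoring points in bp (1 = per-base).
#' @param max_masked_frac Monitoring points whose window has more than this
#'   fraction of masked positions are masked.
#' @return An object of class `segment_series` with fields `chrom`,
#'   `positions` (0-based genomic position of each monitoring point),
#'   `values` (window means), `mask`, `n`, `stride`.
#' @export
segment_means <- function(track, n = 3000L, stride = 1L,
                          max_masked_frac = 0.5) {
  stop_if_not_track(track)
  L <- length(track$depth)
  if (n > L) stop("window size n exceeds track length")
  rw <- .rolling_window_sums(track$depth, !track$mask, as.integer(n),
                             as.integer(stride))
  m <- length(rw$sum)
  vals <- ifelse(rw$count > 0L, rw$sum / rw$count, NA_real_)
  msk <- rw$count < (1 - max_masked_frac) * n
  structure(
    list(chrom = track$chrom,
         positions = track$start_offset + seq(0L, by = as.integer(stride),
                                              length.out = m),
         values = as.numeric(vals), mask = as.logical(msk),
         n = as.integer(n), stride = as.integer(stride)),
    class = "segment_series")
}

#' @export
print.segment_series <- function(x, ...) {
  cat(sprintf("<segment_series> %s: %d monitoring points (n=%d, stride=%d), %d masked\n",
              x$chrom, length(x$values), x$n, x$stride, sum(x$mask)))
  invisible(x)
}

#' Normalize a depth track to unit mean
#'
#' Divides depth by the mean over unmasked positions, so that samples
#' sequenced at different total coverage are on a common scale before being
#' compared with the reference baseline.
#'
#' @param track A [depth_track] with at least one unmasked, non-zero
#'   position.
#' @return A [depth_track] whose unmasked mean is 1 (to within 1e-12), with
#'   a `scale_factor` attribute recording the divisor.
#' @export
normalize_depth <- function(track) {
  stop_if_not_track(track)
  d <- track$depth[!track$mask]
  if (length(d) == 0L) stop("cannot normalize: all positions are masked")
  mu <- mean(d)
  if (mu == 0) stop("cannot normalize: all unmasked depths are zero")
  out <- depth_track(track$chrom, track$depth / mu, track$start_offset,
                     track$mask)
  attr(out, "scale_factor") <- mu
  out
}

#' GC-bias correction of a depth track
#'
#' Per-bin GC-content correction by median ratio: each bin is assigned to a
#' GC decile; every position's depth is divided by the median depth of all
#' bins in the same decile, and the track is rescaled so the overall
#' (unmasked) mean is unchanged. With no GC bias the correction is the
#' identity up to floating point.
#'
#' @param track A [depth_track].
#' @param gc_fraction Numeric vector in \[0,1\]: GC fraction of each
#'   consecutive `bin_size`-bp bin tiling the track (the last bin may be
#'   partial).
#' @param bin_size Bin width in bp, >= 100.
#' @return A corrected [depth_track] (mask preserved).
#' @export
gc_correct <- function(track, gc_fraction, bin_size = 1000L) {
  stop_if_not_track(track)
  if (bin_size < 100) stop("bin_size must be >= 100")
  L <- length(track$depth)
  n_bins <- ceiling(L / bin_size)
  if (length(gc_fraction) != n_bins)
    stop("gc_fraction must have one value per ", bin_size, "-bp bin (",
         n_bins, " bins expected)")
  if (anyNA(gc_fraction) || any(gc_fraction < 0 | gc_fraction > 1))
    stop("gc_fraction values must lie in [0, 1]")
  keep <- !track$mask
  if (!any(keep & track$depth > 0)) {
    warning("all-zero track: GC correction skipped")
    return(track)
  }
  bin_of_pos <- rep(seq_len(n_bins), each = bin_size, length.out = L)
  bin_depth <- vapply(split(track$depth[keep], bin_of_pos[keep]), mean,
                      numeric(1))
  bins_present <- as.integer(names(bin_depth))
  qs <- unique(stats::quantile(gc_fraction, probs = seq(0, 1, 0.1),
                               names = FALSE, type = 7))
  decile <- if (length(qs) < 2L) rep(1L, length(gc_fraction)) else
    cut(gc_fraction, breaks = qs, include.lowest = TRUE, labels = FALSE)
  med_by_decile <- tapply(bin_depth, decile[bins_present], stats::median)
  factor_of_bin <- med_by_decile[as.character(decile)]
  factor_of_bin[is.na(factor_of_bin) | factor_of_bin <= 0] <- NA_real_
  fac <- as.numeric(factor_of_bin[bin_of_pos])
  fac[is.na(fac)] <- stats::median(bin_depth)   # decile with no usable bins
  corrected <- track$depth / fac
  mu_before <- mean(track$depth[keep])
  mu_after <- mean(corrected[keep])
  corrected <- corrected * (mu_before / mu_after)
  depth_track(track$chrom, corrected, track$start_offset, track$mask)
}

#' Build a reference baseline from control samples
#'
#' Pools corrected, normalized control depth tracks into a panel-of-normals
#' baseline: the expected per-position depth `p` (cross-control mean by
#' default), a mask flagging positions with zero depth in every control, and
#' the smoothed expected depth `p_bar` obtained by [segment_means] with the
#' same window used for test samples. After pooling, `p` is rescaled to unit
#' mean over unmasked positions so that the baseline sits on the same scale
#' as a normalized test sample.
#'
#' The pooling statistic defaults to the mean. The cross-control median is
#' available (`method = "median"`) but degenerates at shallow coverage:
#' when most per-base depths are zero the per-position median collapses to
#' zero nearly everywhere, leaving no usable baseline.
#'
#' @param controls List of [depth_track]s on identical coordinates
#'   (already GC-corrected and normalized).
#' @param n,stride Smoothing window and monitoring stride used for `p_bar`;
#'   recorded in the archive and required to match the caller configuration.
#' @param method Pooling statistic across controls: `"mean"` (default) or
#'   `"median"`.
#' @param genome_build Free-text genome build label stored in the metadata.
#' @return An object of class `baseline_archive`: a list with `chromosomes`
#'   (per-chromosome list of `p`, `mask`, `p_bar` segment_series,
#'   `start_offset`) and `metadata` (format version, `n`, `stride`,
#'   `n_controls`, `method`, scale factors, genome build).
#' @export
build_baseline <- function(controls, n = 3000L, stride = 1L,
                           method = c("mean", "median"),
                           genome_build = "unspecified") {
  method <- match.arg(method)
  if (length(controls) < 1L) stop("at least one control is required")
  lapply(controls, stop_if_not_track)
  chroms <- vapply(controls, `[[`, character(1), "chrom")
  by_chrom <- split(controls, chroms)
  chrom_entries <- lapply(by_chrom, function(trks) {
    L <- length(trks[[1L]]$depth)
    off <- trks[[1L]]$start_offset
    same <- vapply(trks, function(t)
      length(t$depth) == L && t$start_offset == off, logical(1))
    if (!all(same))
      stop("controls cover mismatched coordinates on ", trks[[1L]]$chrom)
    mat_sum <- Reduce(`+`, lapply(trks, `[[`, "depth"))
    any_nonzero <- Reduce(`|`, lapply(trks, function(t) t$depth > 0))
    p <- if (method == "mean") {
      mat_sum / length(trks)
    } else {
      .row_medians(do.call(cbind, lapply(trks, `[[`, "depth")))
    }
    pooled_mask <- Reduce(`|`, lapply(trks, `[[`, "mask")) | !any_nonzero
    finalize_baseline_chrom(trks[[1L]]$chrom, p, pooled_mask, off, n, stride)
  })
  new_baseline_archive(chrom_entries, n, stride, length(controls), method,
                       genome_build)
}

# Rescale pooled expected depth to unit unmasked mean and smooth it.
finalize_baseline_chrom <- function(chrom, p, mask, start_offset, n, stride) {
  usable <- !mask
  if (!any(usable) || mean(p[usable]) == 0)
    stop("baseline for ", chrom, " has no usable positions")
  scale <- mean(p[usable])
  p <- p / scale
  trk <- depth_track(chrom, p, start_offset, mask)
  list(p = trk, p_bar = segment_means(trk, n = n, stride = stride),
       scale_factor = scale)
}

new_baseline_archive <- function(chrom_entries, n, stride, n_controls,
                                 method, genome_build) {
  structure(
    list(chromosomes = chrom_entries,
         metadata = list(
           format = "shallowcnv-baseline", format_version = 1L,
           n = as.integer(n), stride = as.integer(stride),
           n_controls = as.integer(n_controls), method = method,
           scale_factors = vapply(chrom_entries, `[[`, numeric(1),
                                  "scale_factor"),
           genome_build = genome_build,
           tool_version = as.character(utils::packageVersion("shallowcnv")))),
    class = "baseline_archive")
}

#' @export
print.baseline_archive <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<baseline_archive> %d chromosome(s), %d control(s), pooled by %s, n=%d, stride=%d\n",
    length(x$chromosomes), md$n_controls, md$method, md$n, md$stride))
  invisible(x)
}
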
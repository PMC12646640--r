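#' Per-base read-depth track
#'
#' A `depth_track` holds the (possibly corrected and rescaled) read depth of
#' one chromosome at single-base resolution, together with a per-position
#' exclusion mask. Depth values are non-negative reals: raw pileup depths are
#' integers, but GC correction and normalization rescale them.
#'
#' @param chrom Chromosome name.
#' @param depth Numeric vector of non-negative, finite depth values; element
#'   `i` is the depth at genomic position `start_offset + i - 1` (0-based).
#' @param start_offset 0-based genomic position of the first element.
#' @param mask Logical vector, same length as `depth`; `TRUE` marks positions
#'   excluded from analysis. Defaults to all `FALSE`.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(chrom, depth, start_offset = 0L, mask = NULL) {
  if (is.null(mask)) mask <- logical(length(depth))
  stopifnot(is.character(chrom), length(chrom) == 1L, is.numeric(depth))
  if (length(mask) != length(depth))
    stop("depth and mask must have identical length")
  if (anyNA(depth) || any(!is.finite(depth)) || any(depth < 0))
    stop("all depth values must be finite and >= 0")
  if (start_offset < 0) stop("start_offset must be >= 0")
  structure(
    list(chrom = chrom, start_offset = as.integer(start_offset),
         depth = as.numeric(depth), mask = as.logical(mask)),
    class = "depth_track")
}

#' @export
length.depth_track <- function(x) length(x$depth)

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %s:%d-%d (%s bp), %d masked, mean depth %.4g\n",
              x$chrom, x$start_offset, x$start_offset + length(x$depth),
              format(length(x$depth), big.mark = ","), sum(x$mask),
              mean(x$depth[!x$mask])))
  invisible(x)
}

is_depth_track <- function(x) inherits(x, "depth_track")

stop_if_not_track <- function(x) {
  if (!is_depth_track(x)) stop("expected a depth_track object")
  invisible(x)
}
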
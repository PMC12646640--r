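#' Zero-inflated Poisson parameters
#'
#' Per-base read depth of shallow WGS is modelled as a zero-inflated Poisson
#' (ZIP) mixture: with probability `pi` a position is a structural zero
#' (never sampled by sequencing), otherwise the depth is Poisson with rate
#' `lambda`.
#'
#' @param pi Structural-zero fraction in \[0, 1\].
#' @param lambda Poisson rate, > 0.
#' @return A list of class `zip_params`.
#' @export
zip_params <- function(pi = 0.9, lambda = 1) {
  if (is.na(pi) || pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (is.na(lambda) || lambda <= 0) stop("lambda must be > 0")
  structure(list(pi = pi, lambda = lambda), class = "zip_params")
}

#' ZIP probability mass function
#'
#' `P(X = 0) = pi + (1 - pi) exp(-lambda)`;
#' `P(X = x) = (1 - pi) exp(-lambda) lambda^x / x!` for `x > 0`.
#'
#' @param x Non-negative integer vector.
#' @param params A [zip_params].
#' @return Probabilities, same length as `x`.
#' @export
zip_pmf <- function(x, params) {
  if (!inherits(params, "zip_params")) params <- do.call(zip_params, params)
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integers")
  p <- (1 - params$pi) * stats::dpois(x, params$lambda)
  p[x == 0] <- params$pi + p[x == 0]
  p
}

#' Mean and variance of a ZIP segment mean
#'
#' The sliding-window mean of `n` independent ZIP depths has mean
#' `(1 - pi) lambda` and variance `(1 - pi) lambda (1 + pi lambda) / n`; by
#' the central limit theorem its distribution approaches a normal with these
#' moments as `n` grows, which underwrites the normal-theory control chart.
#'
#' @param params A [zip_params].
#' @param n Segment size (number of pooled positions), >= 1.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
zip_segment_moments <- function(params, n = 1L) {
  if (!inherits(params, "zip_params")) params <- do.call(zip_params, params)
  if (n < 1) stop("n must be >= 1")
  mu <- (1 - params$pi) * params$lambda
  v <- mu * (1 + params$pi * params$lambda) / n
  c(mean = mu, variance = v)
}

#' Map target mean coverage to the ZIP rate
#'
#' Coverage presets are expressed as the genome-wide mean depth; with a
#' structural-zero fraction `pi` the Poisson rate that realizes a mean depth
#' `coverage` is `lambda = coverage / (1 - pi)`. This mapping is a
#' convention of this package.
#'
#' @param coverage Target mean depth (e.g. 0.1, 1, 3).
#' @param pi Structural-zero fraction.
#' @return A [zip_params].
#' @export
coverage_params <- function(coverage, pi = 0.9) {
  if (pi >= 1) stop("pi must be < 1 to realize a positive coverage")
  zip_params(pi = pi, lambda = coverage / (1 - pi))
}

#' Simulation truth set
#'
#' Describes a synthetic chromosome: its length, base ZIP parameters, the
#' implanted CNV intervals with their copy ratios, and the seed controlling
#' the realization.
#'
#' @param length Chromosome length in bp.
#' @param params Base [zip_params] of diploid background.
#' @param cnvs data.frame with columns `start`, `end` (0-based half-open)
#'   and `copy_ratio` (> 0; > 1 is a gain, < 1 a loss; 1.5 and 0.5
#'   correspond to single-copy gain/loss in a diploid genome). May be empty.
#' @param seed Integer seed; all randomness of the realization flows from it.
#' @param chrom Chromosome name.
#' @return A list of class `sim_truth`; `cnvs` gains a `type` column
#'   (`gain`/`loss`).
#' @export
sim_truth <- function(length, params = zip_params(), cnvs = NULL, seed = 1L,
                      chrom = "chr1") {
  if (!inherits(params, "zip_params")) params <- do.call(zip_params, params)
  if (is.null(cnvs))
    cnvs <- data.frame(start = integer(0), end = integer(0),
                       copy_ratio = numeric(0))
  stopifnot(all(c("start", "end", "copy_ratio") %in% names(cnvs)))
  if (nrow(cnvs)) {
    if (any(cnvs$end <= cnvs$start) || any(cnvs$start < 0) ||
        any(cnvs$end > length))
      stop("implants must be non-empty intervals within genome bounds")
    if (any(cnvs$copy_ratio <= 0)) stop("copy_ratio must be > 0")
    if (any(cnvs$copy_ratio == 1))
      stop("copy_ratio 1 is not a CNV")
    o <- order(cnvs$start)
    cnvs <- cnvs[o, , drop = FALSE]
    if (nrow(cnvs) > 1L && any(cnvs$start[-1L] < cnvs$end[-nrow(cnvs)]))
      stop("implants must not overlap")
    cnvs$type <- ifelse(cnvs$copy_ratio > 1, "gain", "loss")
  } else {
    cnvs$type <- character(0)
  }
  structure(list(chrom = chrom, length = as.integer(length),
                 params = params, cnvs = cnvs, seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate a zero-inflated Poisson depth track
#'
#' Draws per-base depth under the ZIP model: each position is a structural
#' zero with probability `pi`, otherwise Poisson with rate
#' `lambda * copy_ratio` of the covering implant (ratio 1 outside implants).
#' The structural-zero fraction is not scaled by copy ratio — a deletion
#' reduces the sampling rate, not the fraction of unsampleable genome.
#' Identical truth (including seed) yields a bit-identical track.
#'
#' @param truth A [sim_truth].
#' @return The simulated [depth_track]. The truth is attached as attribute
#'   `truth`.
#' @export
simulate_track <- function(truth) {
  if (!inherits(truth, "sim_truth")) stop("truth must be a sim_truth")
  L <- truth$length
  rate <- rep(truth$params$lambda, L)
  for (i in seq_len(nrow(truth$cnvs))) {
    idx <- (truth$cnvs$start[i] + 1L):truth$cnvs$end[i]
    rate[idx] <- rate[idx] * truth$cnvs$copy_ratio[i]
  }
  set.seed(truth$seed)
  structural <- stats::runif(L) < truth$params$pi
  depth <- numeric(L)
  depth[!structural] <- stats::rpois(sum(!structural), rate[!structural])
  trk <- depth_track(truth$chrom, depth, 0L)
  attr(trk, "truth") <- truth
  trk
}

#' Simulate a panel-of-normals baseline
#'
#' Generates `n_controls` null ZIP tracks (no implants), normalizes each to
#' unit mean, and pools them into a [build_baseline]-equivalent archive
#' using the cross-control mean. Controls are generated one at a time and
#' pooled incrementally, so memory stays at a few track-lengths regardless
#' of panel size.
#'
#' @param n_controls Number of control samples in the panel.
#' @param length Chromosome length in bp.
#' @param params Base [zip_params].
#' @param seed Integer seed; control `i` uses `seed + i`.
#' @param n,stride Smoothing window and monitoring stride (see
#'   [build_baseline]).
#' @param chrom Chromosome name.
#' @return A `baseline_archive`.
#' @export
simulate_baseline <- function(n_controls, length, params = zip_params(),
                              seed = 1L, n = 3000L, stride = 1L,
                              chrom = "chr1") {
  stopifnot(n_controls >= 1)
  acc <- numeric(length)
  any_nonzero <- logical(length)
  for (i in seq_len(n_controls)) {
    trk <- simulate_track(sim_truth(length, params = params,
                                    seed = seed + i, chrom = chrom))
    trk <- normalize_depth(trk)
    acc <- acc + trk$depth
    any_nonzero <- any_nonzero | trk$depth > 0
  }
  entry <- finalize_baseline_chrom(chrom, acc / n_controls, !any_nonzero,
                                   0L, n, stride)
  new_baseline_archive(stats::setNames(list(entry), chrom), n, stride,
                       n_controls, "mean", "synthetic")
}

#' Write a small alignment fixture matching a simulation truth
#'
#' Emits a coordinate-sorted, indexed BAM whose pileup matches the ZIP model
#' of the truth in expectation: the number of reads starting at each
#' position is ZIP with rate `lambda * copy_ratio / read_length`, so the
#' expected per-base depth equals `(1 - pi) * lambda * copy_ratio`. All
#' reads are `read_length` bp, forward strand, MAPQ 60, CIGAR `<len>M`.
#' Intended for integration-testing the BAM reader, not for benchmarking
#' realism.
#'
#' @param truth A [sim_truth] (genome at most 10 Mb).
#' @param path Output path; `.bam` extension added if absent.
#' @param read_length Read length in bp (default 35, typical of NIPT data).
#' @return Invisibly, the path to the indexed BAM.
#' @export
make_alignment_fixture <- function(truth, path, read_length = 35L) {
  if (!inherits(truth, "sim_truth")) stop("truth must be a sim_truth")
  if (truth$length > 1e7) stop("fixture genomes are limited to 10 Mb")
  L <- truth$length
  n_start <- max(L - read_length + 1L, 1L)
  rate <- rep(truth$params$lambda / read_length, n_start)
  for (i in seq_len(nrow(truth$cnvs))) {
    idx <- intersect((truth$cnvs$start[i] + 1L):truth$cnvs$end[i],
                     seq_len(n_start))
    rate[idx] <- rate[idx] * truth$cnvs$copy_ratio[i]
  }
  set.seed(truth$seed)
  structural <- stats::runif(n_start) < truth$params$pi
  counts <- integer(n_start)
  counts[!structural] <- stats::rpois(sum(!structural), rate[!structural])
  starts <- rep(seq_len(n_start), counts)   # 1-based, already sorted

  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", truth$chrom, L)), con)
  if (length(starts)) {
    recs <- sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                    seq_along(starts), truth$chrom, starts, read_length,
                    strrep("A", read_length))
    writeLines(recs, con)
  }
  close(con)
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}
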
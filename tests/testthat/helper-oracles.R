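# Independent reference implementations used as oracles. These deliberately
# use the most literal formulation (per-window loops, per-step recursions,
# per-read increments) rather than anything shared with the package.

naive_segment_means <- function(depth, mask, n, stride) {
  L <- length(depth)
  starts <- seq(1L, L - n + 1L, by = stride)
  vals <- numeric(length(starts))
  msk <- logical(length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + n - 1L)
    ok <- !mask[idx]
    vals[j] <- if (any(ok)) mean(depth[idx][ok]) else NA_real_
    msk[j] <- sum(!ok) > 0.5 * n
  }
  list(values = vals, mask = msk)
}

cusum_loop <- function(r, K, mask = rep(FALSE, length(r))) {
  cp <- cm <- numeric(length(r))
  prev_p <- prev_m <- 0
  for (t in seq_along(r)) {
    if (mask[t]) {
      cp[t] <- prev_p; cm[t] <- prev_m
      next
    }
    prev_p <- max(0, r[t] - K + prev_p)
    prev_m <- min(0, r[t] + K + prev_m)
    cp[t] <- prev_p; cm[t] <- prev_m
  }
  list(Cplus = cp, Cminus = cm)
}

# per-read interval-increment pileup (1-based read starts, reference widths)
pileup_oracle <- function(starts, widths, L) {
  depth <- numeric(L)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + widths[k] - 1L, L)
    depth[idx] <- depth[idx] + 1
  }
  depth
}

# exhaustive one-to-one matching: maximum number of call/truth pairs subject
# to the same eligibility rule as match_calls (used on tiny instances only)
max_matching_oracle <- function(calls, truth, min_overlap = 0.5,
                                require_type = TRUE) {
  eligible <- matrix(FALSE, nrow(calls), nrow(truth))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (calls$chrom[i] != truth$chrom[j]) next
      if (require_type && calls$type[i] != truth$type[j]) next
      ov <- min(calls$end[i], truth$end[j]) - max(calls$start[i],
                                                  truth$start[j])
      if (ov <= 0) next
      if (ov / (calls$end[i] - calls$start[i]) >= min_overlap &&
          ov / (truth$end[j] - truth$start[j]) >= min_overlap)
        eligible[i, j] <- TRUE
    }
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > nrow(calls)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(i + 1L, used)                    # leave call i unmatched
    for (j in which(eligible[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used)
      used[j] <- FALSE
    }
  }
  if (nrow(calls)) recurse(1L, rep(FALSE, nrow(truth))) else best <- 0L
  best
}

# write a SAM file from a record data.frame and convert to indexed BAM
sam_fixture <- function(records, chrom = "chr1", chrom_len = 1000L,
                        index = TRUE) {
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  if (nrow(records)) {
    o <- order(records$pos)
    records <- records[o, , drop = FALSE]
    lines <- c(lines, sprintf(
      "r%03d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
      seq_len(nrow(records)), records$flag, chrom, records$pos,
      records$mapq, records$cigar,
      vapply(records$cigar, function(cg) {
        w <- sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=[MIS=X])",
                                                    cg, perl = TRUE))[[1]]))
        strrep("A", w)
      }, character(1))))
  }
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                          indexDestination = index)
  unlink(sam)
  bam
}

# small synthetic baseline on an explicit expected-depth vector: k identical
# normalized controls so that p equals the (normalized) template
baseline_from_template <- function(p, n, stride = 1L, chrom = "chr1") {
  trk <- normalize_depth(depth_track(chrom, p))
  build_baseline(list(trk, trk, trk), n = n, stride = stride)
}
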
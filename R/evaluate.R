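#' Score CNV calls against a truth set
#'
#' Matches calls to truth intervals by the 50%-overlap convention of
#' structural-variant benchmarking: a call matches a truth interval when
#' their shared span is at least `min_overlap` of *both* interval lengths
#' (reciprocal overlap; set `reciprocal = FALSE` to require the fraction of
#' the truth interval only) and, when `require_type` is set, the types
#' agree. Matching is one-to-one and greedy by descending overlap length.
#' `TP` is the number of matched truth intervals, `FN` the unmatched truth,
#' `FP` the unmatched calls; sensitivity = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 = 2*sens*prec/(sens+prec). An undefined ratio
#' (zero denominator) is reported as 0 and flagged.
#'
#' @param calls data.frame (or `cnv_scan`) with columns `chrom`, `start`,
#'   `end`, `type`; 0-based half-open.
#' @param truth data.frame with the same columns (a [sim_truth]'s `cnvs`
#'   with a `chrom` column also works).
#' @param min_overlap Required overlap fraction (default 0.5).
#' @param require_type Types must agree for a match (default `TRUE`).
#' @param reciprocal If `TRUE` (default) the fraction applies to both
#'   intervals; if `FALSE`, to the truth interval only.
#' @param size_breaks Boundaries (bp) of the per-size strata reported in
#'   addition to the overall metrics; default `c(1e4, 1e6)` gives strata
#'   `<10k`, `10k-1M`, `>1M`.
#' @return A list of class `cnv_eval`: `TP`, `FP`, `FN`, `sensitivity`,
#'   `precision`, `f1`, `undefined` (character vector of ratios reported as
#'   0 for lack of a denominator), `by_size` (per-stratum data.frame) and
#'   `matches` (matched index pairs with overlap lengths).
#' @export
match_calls <- function(calls, truth, min_overlap = 0.5,
                        require_type = TRUE, reciprocal = TRUE,
                        size_breaks = c(1e4, 1e6)) {
  if (inherits(calls, "cnv_scan")) calls <- calls$calls
  if (inherits(truth, "sim_truth")) {
    truth <- cbind(chrom = truth$chrom, truth$cnvs)
  }
  calls <- check_intervals(calls, "calls")
  truth <- check_intervals(truth, "truth")
  if (min_overlap <= 0 || min_overlap > 1)
    stop("min_overlap must lie in (0, 1]")

  pairs <- eligible_pairs(calls, truth, min_overlap, require_type,
                          reciprocal)
  used_call <- logical(nrow(calls))
  used_truth <- logical(nrow(truth))
  matches <- pairs[0, , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- pairs[order(-pairs$overlap, pairs$call, pairs$truth), ,
                   drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$call[k]; j <- pairs$truth[k]
      if (!used_call[i] && !used_truth[j]) {
        used_call[i] <- TRUE
        used_truth[j] <- TRUE
        matches <- rbind(matches, pairs[k, ])
      }
    }
  }
  res <- eval_counts(sum(used_truth), sum(!used_call), sum(!used_truth))
  res$by_size <- by_size_strata(calls, truth, used_call, used_truth,
                                size_breaks)
  res$matches <- matches
  class(res) <- "cnv_eval"
  res
}

check_intervals <- function(x, what) {
  need <- c("chrom", "start", "end", "type")
  if (!all(need %in% names(x)))
    stop(what, " must have columns ", paste(need, collapse = ", "))
  if (nrow(x) && (anyNA(x$start) || anyNA(x$end) || any(x$end <= x$start)))
    stop(what, " contains malformed intervals (end must exceed start)")
  x
}

eligible_pairs <- function(calls, truth, min_overlap, require_type,
                           reciprocal) {
  out <- data.frame(call = integer(0), truth = integer(0),
                    overlap = numeric(0))
  if (!nrow(calls) || !nrow(truth)) return(out)
  for (i in seq_len(nrow(calls))) {
    same <- which(truth$chrom == calls$chrom[i] &
                    (!require_type | truth$type == calls$type[i]))
    if (!length(same)) next
    ov <- pmin(truth$end[same], calls$end[i]) -
      pmax(truth$start[same], calls$start[i])
    frac_truth <- ov / (truth$end[same] - truth$start[same])
    frac_call <- ov / (calls$end[i] - calls$start[i])
    keep <- ov > 0 & frac_truth >= min_overlap &
      (!reciprocal | frac_call >= min_overlap)
    if (any(keep))
      out <- rbind(out, data.frame(call = i, truth = same[keep],
                                   overlap = ov[keep]))
  }
  out
}

eval_counts <- function(TP, FP, FN) {
  undefined <- character(0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined <- c(undefined, "sensitivity"); 0 }
  prec <- if (TP + FP > 0) TP / (TP + FP) else {
    undefined <- c(undefined, "precision"); 0 }
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else {
    undefined <- c(undefined, "f1"); 0 }
  list(TP = TP, FP = FP, FN = FN, sensitivity = sens, precision = prec,
       f1 = f1, undefined = undefined)
}

by_size_strata <- function(calls, truth, used_call, used_truth,
                           size_breaks) {
  breaks <- c(0, sort(size_breaks), Inf)
  labels <- stratum_labels(breaks)
  strat_of <- function(x) cut(x$end - x$start, breaks = breaks,
                              labels = labels, right = FALSE)
  sc <- strat_of(calls)
  st <- strat_of(truth)
  do.call(rbind, lapply(labels, function(lab) {
    tp <- sum(used_truth & st == lab)
    fn <- sum(!used_truth & st == lab)
    fp <- sum(!used_call & sc == lab)
    m <- eval_counts(tp, fp, fn)
    data.frame(stratum = lab, TP = tp, FP = fp, FN = fn,
               sensitivity = m$sensitivity, precision = m$precision,
               f1 = m$f1)
  }))
}

stratum_labels <- function(breaks) {
  fmt <- function(b) {
    if (!is.finite(b)) return("Inf")
    if (b >= 1e6 && b %% 1e6 == 0) return(paste0(b / 1e6, "M"))
    if (b >= 1e3 && b %% 1e3 == 0) return(paste0(b / 1e3, "k"))
    as.character(b)
  }
  n <- length(breaks)
  labs <- character(n - 1)
  for (i in seq_len(n - 1)) {
    labs[i] <- if (i == 1) paste0("<", fmt(breaks[2])) else
      if (i == n - 1) paste0(">", fmt(breaks[n - 1])) else
        paste0(fmt(breaks[i]), "-", fmt(breaks[i + 1]))
  }
  labs
}

#' @export
print.cnv_eval <- function(x, ...) {
  cat(sprintf("<cnv_eval> TP=%d FP=%d FN=%d  sens=%.3f prec=%.3f F1=%.3f\n",
              x$TP, x$FP, x$FN, x$sensitivity, x$precision, x$f1))
  if (length(x$undefined))
    cat("  reported as 0 (no denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  print(x$by_size, row.names = FALSE)
  invisible(x)
}
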
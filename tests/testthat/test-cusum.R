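make_series <- function(values, n = 3000L, stride = 1L, chrom = "chr1",
                        mask = NULL, positions = NULL) {
  if (is.null(mask)) mask <- logical(length(values))
  if (is.null(positions)) positions <- seq(0L, by = stride,
                                           length.out = length(values))
  structure(list(chrom = chrom, positions = positions, values = values,
                 mask = mask, n = as.integer(n), stride = as.integer(stride)),
            class = "segment_series")
}

test_that("log_ratio computes log2(xbar/pbar) and masks zero baselines", {
  x <- make_series(c(1, 2, 3, 0.5))
  p <- make_series(c(1, 2, 3, 0.5))
  r <- log_ratio(x, p, epsilon = 0)
  expect_equal(r$values, rep(0, 4))
  r2 <- log_ratio(make_series(3), make_series(2), epsilon = 0)
  expect_equal(r2$values, log2(1.5))
  r3 <- log_ratio(make_series(c(1, 1)), make_series(c(1, 0)), epsilon = 0)
  expect_true(r3$mask[2])
  expect_true(is.na(r3$values[2]))
  expect_false(any(is.infinite(r3$values), na.rm = TRUE))
  expect_error(log_ratio(make_series(1, n = 100), make_series(1, n = 200)),
               "different n")
})

test_that("the CUSUM recursion reproduces the worked two-sided example", {
  R <- c(0.2, 0, 0.3, 0.7, 0.5, 0.2, 0.1, -0.2, -0.8, -0.7, -0.2, -0.8, -0.6)
  cu <- cusum_series(R, K = 0.3)
  expect_equal(cu$Cplus,
               c(0, 0, 0, 0.4, 0.6, 0.5, 0.3, 0, 0, 0, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(cu$Cminus,
               c(0, 0, 0, 0, 0, 0, 0, 0, -0.5, -0.9, -0.8, -1.3, -1.6),
               tolerance = 1e-12)
})

test_that("CUSUM closed forms and sign separation hold", {
  cu0 <- cusum_series(rep(0, 50), K = 0.1)
  expect_true(all(cu0$Cplus == 0) && all(cu0$Cminus == 0))
  cu <- cusum_series(rep(0.5, 40), K = 0.3)
  expect_equal(cu$Cplus, 0.2 * (1:40), tolerance = 1e-12)
  expect_true(all(cu$Cminus == 0))   # a pure upward shift never touches C-
  set.seed(601)
  for (i in 1:5) {
    r <- rnorm(500, sd = 0.5)
    cu <- cusum_series(r, K = 0.3)
    expect_gte(min(cu$Cplus), 0)
    expect_lte(max(cu$Cminus), 0)
  }
  expect_error(cusum_series(rep(0, 5), K = 0), "K must be")
})

test_that("vectorized recursion equals the literal per-step loop", {
  set.seed(602)
  for (i in 1:5) {
    m <- 10000L
    r <- rnorm(m, sd = 0.6)
    mask <- runif(m) < 0.05
    series <- structure(list(chrom = "c", positions = 0:(m - 1),
                             values = r, mask = mask, n = 100L, stride = 1L),
                        class = "logr_series")
    cu <- cusum_series(series, K = 0.3)
    ref <- cusum_loop(r, 0.3, mask)
    expect_equal(cu$Cplus, ref$Cplus, tolerance = 1e-12)
    expect_equal(cu$Cminus, ref$Cminus, tolerance = 1e-12)
  }
})

test_that("masked monitoring points carry the statistics forward", {
  r <- c(1, 1, NA, 1)
  series <- structure(list(chrom = "c", positions = 0:3, values = r,
                           mask = c(FALSE, FALSE, TRUE, FALSE), n = 10L,
                           stride = 1L), class = "logr_series")
  cu <- cusum_series(series, K = 0.3)
  expect_equal(cu$Cplus, c(0.7, 1.4, 1.4, 2.1), tolerance = 1e-12)
})

test_that("control limits follow n*log2(a) and n*log2(b)", {
  lim <- control_limits(3000, a = 1.5, b = 0.5)
  expect_equal(lim$UCL, 3000 * log2(1.5))
  expect_equal(lim$UCL, 1754.8875, tolerance = 1e-4)
  expect_equal(lim$LCL, -3000)
  expect_equal(control_limits(1, a = 2, b = 0.5)$UCL, 1)
  expect_error(control_limits(3000, a = 1, b = 0.5), "a must be")
  expect_error(control_limits(3000, a = 2, b = 1.2), "b must")
})

test_that("a sustained single-copy-gain shift crosses the UCL on schedule", {
  K <- 0.3
  n <- 3000L
  shift <- log2(1.5)
  lim <- control_limits(n)
  cu <- cusum_series(rep(shift, 8000), K = K)
  first <- which(cu$Cplus > lim$UCL)[1]
  expect_equal(first, ceiling(lim$UCL / (shift - K)))
  expect_true(first >= 6150 && first <= 6170)
})

test_that("candidate extraction partitions the chromosome and filters alarms", {
  n <- 10L
  lim <- control_limits(n, a = 1.5, b = 0.5)   # UCL ~ 5.85
  # quiet series: single none-region spanning the monitored span
  quiet <- cusum_series(rep(0, 5000), K = 0.3)
  quiet$n <- n
  reg <- extract_candidates(quiet, lim)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$direction, "none")
  expect_equal(c(reg$start, reg$end), c(0L, 5000L))

  # constructed excursion: rise over 5000 points, bounded by zeros, with the
  # peak at the end of the run so both end rules agree
  r <- c(rep(0, 1000), rep(0.31, 5000), rep(-10, 1), rep(0, 1000))
  cu <- cusum_series(r, K = 0.3)
  cu$n <- n
  for (rule in c("peak", "zero")) {
    reg <- extract_candidates(cu, lim, merge_gap = 10L, end_rule = rule)
    gain <- reg[reg$direction == "gain-candidate", ]
    expect_equal(nrow(gain), 1L)
    expect_lte(gain$start, 1000)
    expect_gte(gain$end, 5990)
    # the output tiles the span without overlap
    expect_equal(reg$start[-1], reg$end[-nrow(reg)])
    expect_equal(reg$start[1], 0L)
    expect_equal(reg$end[nrow(reg)], length(r))
  }

  # an 800-point excursion is a transient alert and is filtered out
  r2 <- c(rep(0, 500), rep(1, 800), rep(-10, 1), rep(0, 500))
  cu2 <- cusum_series(r2, K = 0.3)
  cu2$n <- n
  reg2 <- extract_candidates(cu2, lim, min_span = 1000L, merge_gap = 10L)
  expect_true(all(reg2$direction == "none"))
})

test_that("nearby same-direction alarms merge; loss alarms mirror gains", {
  n <- 10L
  lim <- control_limits(n)
  # two loss stretches separated by a positive stretch long enough to pull
  # C- back to zero (0.7/step down for 1500 steps, 10.3/step up for 150)
  burst <- c(rep(-1, 1500), rep(10, 150), rep(-1, 1500))
  r <- c(rep(0, 200), burst, rep(0, 200))
  cu <- cusum_series(r, K = 0.3)
  cu$n <- n
  merged <- extract_candidates(cu, lim, merge_gap = 200L, end_rule = "peak")
  expect_equal(sum(merged$direction == "loss-candidate"), 1L)
  split <- extract_candidates(cu, lim, merge_gap = 10L, end_rule = "peak")
  expect_equal(sum(split$direction == "loss-candidate"), 2L)
  # regions always tile [0, L)
  for (reg in list(merged, split)) {
    expect_equal(reg$start[1], 0L)
    expect_equal(reg$end[nrow(reg)], length(r))
    expect_true(all(reg$start[-1] == reg$end[-nrow(reg)]))
  }
})

test_that("region tiling holds on random CUSUM inputs", {
  set.seed(603)
  n <- 20L
  lim <- control_limits(n)
  for (i in 1:10) {
    r <- rnorm(4000, mean = sample(c(-0.4, 0, 0.4), 1), sd = 1)
    cu <- cusum_series(r, K = 0.3)
    cu$n <- n
    reg <- extract_candidates(cu, lim, min_span = 100L, merge_gap = 20L)
    expect_equal(reg$start[1], 0L)
    expect_equal(reg$end[nrow(reg)], 4000L)
    expect_true(all(reg$start[-1] == reg$end[-nrow(reg)]))
    expect_true(all(reg$end > reg$start))
  }
})
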
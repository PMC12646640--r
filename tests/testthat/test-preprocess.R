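test_that("normalize_depth rescales to unit mean and rejects degenerate input", {
  expect_equal(normalize_depth(depth_track("c", rep(4, 10)))$depth,
               rep(1, 10))
  out <- normalize_depth(depth_track("c", c(2, 4, 6)))
  expect_equal(out$depth, c(0.5, 1, 1.5))
  expect_equal(attr(out, "scale_factor"), 4)
  expect_lt(abs(mean(out$depth[!out$mask]) - 1), 1e-12)
  expect_error(normalize_depth(depth_track("c", rep(0, 5))), "zero")
  expect_error(normalize_depth(depth_track("c", 1:5, mask = rep(TRUE, 5))),
               "masked")
  # masked positions are excluded from the scaling mean
  msk <- depth_track("c", c(2, 4, 100), mask = c(FALSE, FALSE, TRUE))
  expect_equal(normalize_depth(msk)$depth[1:2], c(2, 4) / 3)
})

test_that("segment_means matches hand-computed window means", {
  sm <- segment_means(depth_track("c", c(0, 0, 3, 0, 0, 3)), n = 3, stride = 3)
  expect_equal(sm$values, c(1, 1))
  expect_equal(sm$positions, c(0L, 3L))
  sm2 <- segment_means(depth_track("c", c(1, 2, 3, 4)), n = 2, stride = 1)
  expect_equal(sm2$values, c(1.5, 2.5, 3.5))
  # constant depth: every window mean is the constant, any n and stride
  for (n in c(2, 5)) for (s in c(1, 3)) {
    smc <- segment_means(depth_track("c", rep(2.5, 20)), n = n, stride = s)
    expect_true(all(smc$values == 2.5))
    expect_equal(length(smc$values), (20 - n) %/% s + 1)
  }
  expect_error(segment_means(depth_track("c", 1:5), n = 10), "exceeds")
})

test_that("rolling segment means agree with the naive per-window oracle", {
  set.seed(501)
  for (rep in 1:4) {
    L <- sample(2000:5000, 1)
    depth <- rpois(L, 2) * rbinom(L, 1, 0.3)
    mask <- runif(L) < 0.2
    n <- sample(c(50, 301, 1000), 1)
    stride <- sample(c(1, 7, n), 1)
    sm <- segment_means(depth_track("c", depth, mask = mask), n = n,
                        stride = stride)
    ref <- naive_segment_means(depth, mask, n, stride)
    expect_equal(sm$values, ref$values, tolerance = 1e-9)
    expect_equal(sm$mask, ref$mask)
  }
})

test_that("monitoring points with mostly-masked windows are masked", {
  mask <- c(rep(TRUE, 8), rep(FALSE, 12))
  sm <- segment_means(depth_track("c", rep(1, 20), mask = mask), n = 10,
                      stride = 10)
  expect_true(sm$mask[1])    # 8/10 masked
  expect_false(sm$mask[2])
  expect_equal(sm$values[1], 1)  # mean over the unmasked positions only
})

test_that("gc_correct is the identity without bias and removes imposed bias", {
  set.seed(502)
  L <- 50000L
  bin <- 500L
  n_bins <- L / bin
  # uniform GC: correction must be a no-op up to a global rescale
  trk <- depth_track("c", rpois(L, 10))
  same <- gc_correct(trk, rep(0.45, n_bins), bin)
  expect_equal(same$depth, trk$depth, tolerance = 1e-12)
  # single populated decile behaves the same way
  same2 <- gc_correct(trk, rep(0.8, n_bins), bin)
  expect_equal(same2$depth, trk$depth, tolerance = 1e-12)

  # imposed linear GC bias: depth ~ (1 + 0.5*(gc - 0.5))
  gc <- runif(n_bins, 0.3, 0.7)
  lambda <- 10 * (1 + 0.5 * (gc[rep(seq_len(n_bins), each = bin)] - 0.5))
  biased <- depth_track("c", rpois(L, lambda))
  fixed <- gc_correct(biased, gc, bin)
  bin_mean <- function(d) tapply(d, rep(seq_len(n_bins), each = bin), mean)
  slope_pre <- coef(lm(bin_mean(biased$depth) ~ gc))[2]
  slope_post <- coef(lm(bin_mean(fixed$depth) ~ gc))[2]
  expect_lt(abs(slope_post), 0.1 * abs(slope_pre))
  # overall mean is preserved
  expect_equal(mean(fixed$depth), mean(biased$depth), tolerance = 1e-12)
})

test_that("gc_correct validates input and warns on all-zero tracks", {
  trk <- depth_track("c", rep(0, 1000))
  expect_warning(out <- gc_correct(trk, rep(0.5, 2), 500), "all-zero")
  expect_equal(out$depth, trk$depth)
  expect_error(gc_correct(depth_track("c", 1:1000), rep(0.5, 3), 500),
               "one value per")
  expect_error(gc_correct(depth_track("c", 1:1000), rep(0.5, 10), 50),
               ">= 100")
})

test_that("build_baseline pools controls and masks all-zero positions", {
  # identical normalized controls: p equals any one of them where unmasked
  tpl <- c(2, 4, 6, 0, 8)
  ctrl <- normalize_depth(depth_track("chr1", tpl))
  archive <- build_baseline(list(ctrl, ctrl, ctrl), n = 2L)
  entry <- archive$chromosomes$chr1
  expect_equal(entry$p$depth[!entry$p$mask] * entry$scale_factor,
               ctrl$depth[!entry$p$mask])
  # a position zero in every control is masked
  expect_true(entry$p$mask[4])
  expect_false(any(entry$p$mask[-4]))
  # baseline is on the unit-mean scale of a normalized sample
  expect_equal(mean(entry$p$depth[!entry$p$mask]), 1, tolerance = 1e-12)
  # recorded smoothing window matches the one used for p_bar
  expect_equal(archive$metadata$n, entry$p_bar$n)
})

test_that("median pooling recovers the per-position median of controls", {
  mk <- function(v) depth_track("chr1", v)
  archive <- build_baseline(list(mk(c(1, 2)), mk(c(3, 2)), mk(c(5, 2))),
                            n = 1L, method = "median")
  entry <- archive$chromosomes$chr1
  # undo the unit-mean rescale to read the raw pooled statistic
  expect_equal(entry$p$depth * entry$scale_factor, c(3, 2))
})

test_that("build_baseline rejects controls on mismatched coordinates", {
  a <- depth_track("chr1", 1:10)
  b <- depth_track("chr1", 1:12)
  expect_error(build_baseline(list(a, b), n = 2L), "mismatched")
  expect_error(build_baseline(list(), n = 2L), "at least one")
})

test_that("disjoint segment means match the ZIP limit moments within 3 SE", {
  p <- zip_params(0.9, 1)
  n <- 1000L
  n_seg <- 600L
  trk <- simulate_track(sim_truth(n * n_seg, p, seed = 515))
  sm <- segment_means(trk, n = n, stride = n)
  mo <- zip_segment_moments(p, n)
  se_mean <- sqrt(mo[["variance"]] / n_seg)
  expect_lt(abs(mean(sm$values) - mo[["mean"]]), 3 * se_mean)
  v <- var(sm$values)
  m4 <- mean((sm$values - mean(sm$values))^4)
  se_var <- sqrt((m4 - v^2) / n_seg)
  expect_lt(abs(v - mo[["variance"]]), 3 * se_var)
})
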
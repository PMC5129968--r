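# Depth ratios, GC correction, segmentation, calling, oscillation.

flat_bins <- function(n, tumor, normal, gc = NULL, chrom = "chr1") {
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 1000L,
             end = seq_len(n) * 1000L,
             gc = gc %||% rep(0.5, n),
             tumor_depth = tumor, normal_depth = normal)
}

test_that("log ratios are library-size normalized and median-centered", {
  b <- compute_log_ratio(flat_bins(100, 200L, 200L))
  expect_true(all(abs(b$log2_ratio) < 1e-12))
  # one doubled bin on an otherwise flat background
  tum <- rep(200L, 101); tum[51] <- 400L
  b <- compute_log_ratio(flat_bins(101, tum, 200L))
  expect_equal(b$log2_ratio[51] - median(b$log2_ratio[-51]), 1,
               tolerance = 0.02)
  # tumor library twice as deep, identical proportions: ratios are zero
  b <- compute_log_ratio(flat_bins(100, 400L, 200L))
  expect_true(all(abs(b$log2_ratio) < 1e-12))
  # masked bins: normal below threshold
  nrm <- rep(200L, 100); nrm[10] <- 3L
  b <- compute_log_ratio(flat_bins(100, 200L, nrm))
  expect_true(b$masked[10])
  expect_true(is.na(b$log2_ratio[10]))
  expect_error(compute_log_ratio(flat_bins(10, 100L, 1L)), "masked")
})

test_that("GC correction removes a sinusoidal bias without eating steps", {
  set.seed(71)
  cfg <- sim_config(n_bins = 3000L, mean_depth = 300, gc_bias_amp = 0.3,
                    segment_spec = list())
  bins <- simulate_depth_profile(cfg)
  b <- gc_correct(compute_log_ratio(bins))
  stratum <- cut(b$gc, seq(0.3, 0.7, by = 0.05))
  med <- tapply(b$log2_ratio, stratum, median)
  expect_lt(max(abs(med), na.rm = TRUE), 0.05)
  # raw ratios do vary with GC before correction
  med_raw <- tapply(b$log2_ratio_raw, stratum, median)
  expect_gt(max(abs(med_raw), na.rm = TRUE), 0.1)
  # a planted step survives correction within 0.05
  cfg2 <- sim_config(n_bins = 3000L, mean_depth = 300, gc_bias_amp = 0.3,
                     segment_spec = list(list(start = 1001L, end = 2000L,
                                              log2 = 1)))
  bins2 <- simulate_depth_profile(cfg2)
  b2 <- gc_correct(compute_log_ratio(bins2))
  step <- mean(b2$log2_ratio[bins2$true_log2 == 1]) -
    mean(b2$log2_ratio[bins2$true_log2 == 0])
  expect_equal(step, 1, tolerance = 0.05)
  # constant GC: correction reduces to a constant shift (zero after centering)
  b3 <- compute_log_ratio(flat_bins(200, 150L, 150L))
  b3c <- gc_correct(b3)
  expect_equal(b3c$log2_ratio, b3$log2_ratio, tolerance = 1e-12)
})

test_that("segmentation finds noise-free steps exactly and is deterministic", {
  x <- c(rep(0, 50), rep(1, 50))
  b <- flat_bins(100, 100L, 100L)
  b$log2_ratio <- x; b$masked <- FALSE
  segs <- segment_bins(b, seed = 1)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_bins, c(50L, 50L))
  expect_equal(segs$mean_log2, c(0, 1))
  # constant signal: a single segment
  b$log2_ratio <- rep(0.25, 100)
  expect_equal(nrow(segment_bins(b, seed = 1)), 1L)
  # determinism under a fixed seed
  set.seed(72)
  b$log2_ratio <- rnorm(100, 0, 0.2)
  s1 <- segment_bins(b, seed = 7)
  s2 <- segment_bins(b, seed = 7)
  expect_identical(s1, s2)
  expect_error(segment_bins(b[c(2:1, 3:100), ]), "sorted")
})

test_that("segment means equal member-bin means and cover all unmasked bins", {
  set.seed(73)
  x <- c(rnorm(80, 0, 0.1), rnorm(60, 0.8, 0.1), rnorm(80, -0.5, 0.1))
  b <- flat_bins(220, 100L, 100L)
  b$log2_ratio <- x; b$masked <- FALSE
  segs <- segment_bins(b, seed = 3)
  expect_equal(sum(segs$n_bins), 220L)
  # per-segment mean equals the mean of its member bins
  bounds <- cumsum(c(0, segs$n_bins))
  for (k in seq_len(nrow(segs))) {
    expect_equal(segs$mean_log2[k], mean(x[(bounds[k] + 1):bounds[k + 1]]),
                 tolerance = 1e-9)
  }
  # breakpoints recovered within +/- 2 bins
  bps <- cumsum(segs$n_bins)[-nrow(segs)]
  expect_equal(length(bps), 2L)
  expect_lte(abs(bps[1] - 80), 2)
  expect_lte(abs(bps[2] - 140), 2)
})

test_that("gain/loss calls separate focal from arm-level segments", {
  arms <- read_arm_table(system.file("extdata", "adenoma_arms.tsv",
                                     package = "tumorith"))
  segs <- data.frame(
    chrom = c("chr5", "chr5", "chr5"),
    start = c(50000000, 111500000, 100000000),
    end = c(175000000, 112800000, 101000000),
    n_bins = c(1000L, 55L, 40L), mean_log2 = c(-0.5, -0.6, 0))
  out <- call_gain_loss(segs, arm_table = arms)
  expect_equal(out$call, c("loss", "loss", "neutral"))
  expect_equal(out$scope, c("arm-level", "focal", NA))
  expect_equal(out$arm[1], "5q")
  expect_warning(
    call_gain_loss(data.frame(chrom = "chrUn", start = 0, end = 1e6,
                              n_bins = 10L, mean_log2 = 0.5),
                   arm_table = arms), "arm table")
})

test_that("oscillation flag needs a long two-state alternation", {
  alt8 <- data.frame(chrom = "chr6",
                     start = seq(0, 7e6, 1e6), end = seq(1e6, 8e6, 1e6),
                     n_bins = 10L,
                     mean_log2 = rep(c(-0.5, 0.4), 4))
  res <- detect_oscillation(alt8)
  expect_true(res$flag)
  expect_equal(res$n_switches, 8L)
  # two segments are not an oscillation
  expect_false(detect_oscillation(alt8[1:2, ])$flag)
  # a monotone staircase of 8 distinct levels never alternates two states
  stair <- alt8
  stair$mean_log2 <- seq(0, 3.5, by = 0.5)
  expect_false(detect_oscillation(stair)$flag)
  # seven alternating segments stay below the default threshold
  expect_false(detect_oscillation(alt8[1:7, ])$flag)
})
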
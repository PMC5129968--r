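# KS-based microsatellite-instability calling.

test_that("KS statistic matches the pooled-support ECDF definition", {
  h <- c("9" = 10, "10" = 20, "11" = 10)
  expect_equal(ks_statistic(h, h), 0)
  expect_equal(ks_statistic(c("9" = 50), c("10" = 50)), 1)
  expect_equal(ks_statistic(c("9" = 5, "10" = 5), c("10" = 10)), 0.5)
  # symmetry and scale invariance of D (depends only on proportions)
  set.seed(61)
  for (i in 1:25) {
    p <- random_hist_pair(shifted = TRUE)
    expect_equal(ks_statistic(p$tumor, p$normal),
                 ks_statistic(p$normal, p$tumor))
    expect_equal(ks_statistic(p$tumor * 7, p$normal * 3),
                 ks_statistic(p$tumor, p$normal))
    expect_equal(ks_statistic(p$tumor, p$normal),
                 oracle_ks_D(p$tumor, p$normal))
  }
})

test_that("p-values behave at the boundaries and match ks.test asymptotics", {
  expect_equal(ks_pvalue(0, 50, 50), 1)
  expect_equal(ks_pvalue(0, 50, 50, "permutation",
                         c("9" = 25, "10" = 25), c("9" = 25, "10" = 25)),
               1, tolerance = 1e-6)
  expect_lt(ks_pvalue(1, 50, 50), 1e-10)
  # permutation floor with disjoint supports: p <= 2/(B+1) at B = 1e4
  p_perm <- ks_pvalue(1, 50, 50, "permutation", c("9" = 50), c("10" = 50),
                      B = 1e4)
  expect_lte(p_perm, 2e-4)
  # asymptotic series equals the reference implementation in stats::ks.test
  set.seed(62)
  for (i in 1:10) {
    x <- sample(1:1000, 150); y <- sample(1:1000, 120)
    D <- ks_statistic(table(x), table(y))
    expect_equal(ks_pvalue(D, 150, 120),
                 suppressWarnings(ks.test(x, y, exact = FALSE))$p.value,
                 tolerance = 1e-4)
  }
  expect_error(ks_pvalue(1.2, 10, 10), "D")
  expect_error(ks_pvalue(0.5, 10, 10, "permutation"), "requires")
})

test_that("permutation p-values agree with the expansion-shuffle oracle", {
  set.seed(63)
  for (i in 1:5) {
    p <- random_hist_pair(max_reads = 80, shifted = TRUE)
    p_pkg <- ks_pvalue(ks_statistic(p$tumor, p$normal),
                       sum(p$tumor), sum(p$normal), "permutation",
                       p$tumor, p$normal, B = 4000L)
    p_orc <- oracle_ks_perm_p(p$tumor, p$normal, B = 4000L)
    expect_lt(abs(p_pkg - p_orc), 0.025)  # two MC estimates of one p

  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.5)), c(0.08, 0.5))
  set.seed(64)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.3)), "0, 1")
})

test_that("MSI status thresholds separate MSS from MSI-H event counts", {
  expect_equal(classify_msi_status(0), "MSS")
  expect_equal(classify_msi_status(5), "MSS")
  expect_equal(classify_msi_status(46), "MSI-H")
  expect_equal(classify_msi_status(128), "MSI-H")
})

test_that("event calling flags a planted unstable locus among null loci", {
  set.seed(65)
  rows <- list()
  for (j in 1:300) {
    prof <- triangular_profile(20)
    h <- simulate_microsat_locus(prof, FALSE, n_reads = 50L)
    rows[[j]] <- rbind(
      data.frame(locus_id = sprintf("MS%03d", j), sample = "tumor",
                 length = as.integer(names(h$tumor)),
                 read_count = as.vector(h$tumor)),
      data.frame(locus_id = sprintf("MS%03d", j), sample = "normal",
                 length = as.integer(names(h$normal)),
                 read_count = as.vector(h$normal)))
  }
  # one locus with completely shifted tumor reads (D = 1)
  rows[[301]] <- rbind(
    data.frame(locus_id = "MS301", sample = "tumor", length = 14L,
               read_count = 50L),
    data.frame(locus_id = "MS301", sample = "normal", length = 20L,
               read_count = 50L))
  res <- call_msi_events(do.call(rbind, rows))
  pl <- res$per_locus
  expect_true(pl$is_event[pl$locus_id == "MS301"])
  expect_lte(sum(pl$is_event), 2L)
  # undercovered loci are excluded from the family, not tested
  shallow <- rbind(
    data.frame(locus_id = "MS900", sample = "tumor", length = 20L,
               read_count = 5L),
    data.frame(locus_id = "MS900", sample = "normal", length = 20L,
               read_count = 5L))
  res2 <- call_msi_events(shallow)
  expect_equal(res2$per_sample$n_untestable, 1L)
  expect_equal(res2$per_sample$n_testable, 0L)
  expect_true(is.na(res2$status))
})

test_that("per-region statuses combine into the case status as configured", {
  mk <- function(unstable, region) {
    rows <- list()
    for (j in 1:40) {
      prof <- triangular_profile(15)
      h <- simulate_microsat_locus(prof, j <= (if (unstable) 30 else 0),
                                   0.7, -2L, 60L)
      rows[[j]] <- rbind(
        data.frame(locus_id = sprintf("MS%03d", j),
                   sample = paste0("tumor:", region),
                   length = as.integer(names(h$tumor)),
                   read_count = as.vector(h$tumor)),
        if (region == "T1") {
          data.frame(locus_id = sprintf("MS%03d", j), sample = "normal",
                     length = as.integer(names(h$normal)),
                     read_count = as.vector(h$normal))
        })
    }
    do.call(rbind, rows)
  }
  set.seed(66)
  tab <- rbind(mk(TRUE, "T1"), mk(TRUE, "T2"), mk(FALSE, "T3"))
  expect_equal(call_msi_events(tab, combine = "majority")$status, "MSI-H")
  expect_equal(call_msi_events(tab, combine = "all")$status, "MSS")
  expect_equal(call_msi_events(tab, combine = "any")$status, "MSI-H")
})
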
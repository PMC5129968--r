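# Independent oracles and small fixture builders shared across tests.
# Every oracle is written from the definition, independently of the package
# code paths it checks.

# Brute-force two-sample KS statistic: expand histograms to raw samples and
# evaluate both ECDFs point by point over the pooled support.
oracle_ks_D <- function(tumor_hist, normal_hist) {
  xt <- rep(as.numeric(names(tumor_hist)), tumor_hist)
  xn <- rep(as.numeric(names(normal_hist)), normal_hist)
  support <- sort(unique(c(xt, xn)))
  d <- 0
  for (s in support) {
    d <- max(d, abs(mean(xt <= s) - mean(xn <= s)))
  }
  d
}

# Label-permutation p-value for the KS statistic, by explicit expansion and
# shuffling of the pooled sample (add-one corrected).
oracle_ks_perm_p <- function(tumor_hist, normal_hist, B = 10000) {
  xt <- rep(as.numeric(names(tumor_hist)), tumor_hist)
  xn <- rep(as.numeric(names(normal_hist)), normal_hist)
  n <- length(xt); m <- length(xn)
  pool <- sort(c(xt, xn))
  grp_end <- cumsum(table(pool))
  d_obs <- oracle_ks_D(tumor_hist, normal_hist)
  lab0 <- rep(c(1L, 0L), c(n, m))
  hits <- 0L
  for (b in seq_len(B)) {
    c1 <- cumsum(sample(lab0))[grp_end]
    if (max(abs(c1 / n - (grp_end - c1) / m)) >= d_obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (1 + hits) / (1 + B)
}

# Direct Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive least-squares single-split: the breakpoint b minimizing
# RSS([1..b]) + RSS([b+1..n]) over all admissible b.
oracle_ls_single_split <- function(x, min_bins = 5L) {
  n <- length(x)
  rss <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_b <- NA_integer_
  for (b in min_bins:(n - min_bins)) {
    r <- rss(x[1:b]) + rss(x[(b + 1):n])
    if (r < best) { best <- r; best_b <- b }
  }
  best_b
}

# A random stutter-like histogram pair around one reference length.
random_hist_pair <- function(max_reads = 200, shifted = FALSE) {
  prof <- triangular_profile(sample(10:30, 1))
  n <- sample(20:max_reads, 1); m <- sample(20:max_reads, 1)
  tumor_law <- prof
  if (shifted) {
    h <- simulate_microsat_locus(prof, TRUE, runif(1, 0.2, 0.8),
                                 sample(c(-2L, -1L, 1L), 1), c(n, 1))
    tumor <- h$tumor
  } else {
    tumor <- setNames(as.vector(rmultinom(1, n, prof)), names(prof))
  }
  normal <- setNames(as.vector(rmultinom(1, m, prof)), names(prof))
  list(tumor = tumor, normal = normal)
}

# Minimal three-region calls + evidence tables for genotyper tests.
toy_case <- function() {
  sites <- data.frame(
    chrom = c("chr1", "chr2", "chr3"), pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
    gene = c("G1", "G2", "G3"), protein_change = c("p.A1T", "", "p.C3F"),
    consequence = c("missense", "synonymous", "nonsense"))
  regions <- c("T1", "T2", "T3")
  calls <- rbind(
    cbind(sites[1, ], region = "T1"),
    cbind(sites[1, ], region = "T2"),
    cbind(sites[2, ], region = "T2"),
    cbind(sites[3, ], region = "T3"))
  evidence <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
               alt = sites$alt, region = r, alt_count = 0L,
               ref_count = 100L)
  }))
  # strong evidence where called, plus rescueable evidence for site 1 in T3
  for (i in seq_len(nrow(calls))) {
    sel <- evidence$chrom == calls$chrom[i] & evidence$pos == calls$pos[i] &
      evidence$region == calls$region[i]
    evidence$alt_count[sel] <- 40L
    evidence$ref_count[sel] <- 60L
  }
  sel <- evidence$chrom == "chr1" & evidence$region == "T3"
  evidence$alt_count[sel] <- 5L
  evidence$ref_count[sel] <- 95L
  list(sites = sites, calls = calls, evidence = evidence,
       regions = regions)
}
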
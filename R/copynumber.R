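# Read-depth copy-number analysis: tumor/normal log2 ratio, GC correction,
# circular-binary-segmentation-style change-point search with a seeded
# permutation test, gain/loss calling and the oscillation (chromothripsis-
# like) flag.

#' Read a binned depth table
#'
#' @param path BED-like TSV with columns chrom, start, end (0-based
#'   half-open), gc, tumor_depth, normal_depth.
#' @return validated data.frame sorted by (chrom, start).
#' @export
read_depth_bins <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "tumor_depth", "normal_depth")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  if (any(df$end <= df$start)) stop_invalid("%s: bins must have end > start", path)
  check_fraction(df$gc, "gc")
  df[order(chrom_rank(df$chrom), df$chrom, df$start), , drop = FALSE]
}

#' Raw tumor/normal log2 depth ratio
#'
#' Library-size-normalized: `log2((tumor/T) / (normal/N))` with T, N the
#' total unmasked depths, then median-centered across the genome. Bins with
#' `normal_depth < min_normal_depth` are masked (ratio NA) -- the normal
#' carries no information there.
#'
#' @param bins depth-bin data.frame (see [read_depth_bins()]).
#' @param min_normal_depth masking threshold on the matched normal.
#' @return `bins` with columns `log2_ratio` and `masked` appended.
#' @export
compute_log_ratio <- function(bins, min_normal_depth = 10L) {
  masked <- bins$normal_depth < min_normal_depth
  if (all(masked)) stop_invalid("all bins masked (normal depth too low)")
  t_tot <- sum(bins$tumor_depth[!masked])
  n_tot <- sum(bins$normal_depth[!masked])
  ratio <- rep(NA_real_, nrow(bins))
  ratio[!masked] <- log2((bins$tumor_depth[!masked] / t_tot) /
                           (bins$normal_depth[!masked] / n_tot))
  ratio[!masked & bins$tumor_depth == 0] <- min(ratio[is.finite(ratio)],
                                                -5, na.rm = TRUE)
  ratio[!masked] <- ratio[!masked] - median(ratio[!masked])
  bins$log2_ratio <- ratio
  bins$masked <- masked
  bins
}

#' GC-bias correction by per-stratum median subtraction
#'
#' Bins are stratified by GC fraction (strata of `stratum_width`); strata
#' with fewer than `min_stratum_bins` bins are merged with their nearest
#' neighbor before the per-stratum median of the raw log2 ratio is
#' subtracted. The result is re-centered at median zero.
#'
#' @param bins output of [compute_log_ratio()].
#' @param stratum_width GC stratum width (default 0.02).
#' @param min_stratum_bins minimum bins per stratum before merging.
#' @return `bins` with `log2_ratio` replaced by the corrected value (raw
#'   kept as `log2_ratio_raw`).
#' @export
gc_correct <- function(bins, stratum_width = 0.02, min_stratum_bins = 50L) {
  ok <- !bins$masked
  stratum <- floor(bins$gc / stratum_width)
  levels_occ <- sort(unique(stratum[ok]))
  # Merge undersized strata with their nearest (smaller-count) neighbor.
  group <- match(stratum, levels_occ)
  counts <- tabulate(group[ok], nbins = length(levels_occ))
  merged <- as.list(seq_along(levels_occ))
  while (length(merged) > 1L) {
    sizes <- vapply(merged, function(g) sum(counts[g]), 0)
    if (all(sizes >= min_stratum_bins)) break
    i <- which.min(sizes)
    j <- if (i == 1L) 2L
         else if (i == length(merged)) i - 1L
         else if (sizes[i - 1] <= sizes[i + 1]) i - 1L else i + 1L
    merged[[min(i, j)]] <- c(merged[[min(i, j)]], merged[[max(i, j)]])
    merged[[max(i, j)]] <- NULL
  }
  stratum_of_level <- integer(length(levels_occ))
  for (g in seq_along(merged)) stratum_of_level[merged[[g]]] <- g
  grp <- stratum_of_level[group]
  raw <- bins$log2_ratio
  corrected <- raw
  for (g in unique(grp[ok])) {
    sel <- ok & grp == g
    corrected[sel] <- raw[sel] - median(raw[sel])
  }
  corrected[ok] <- corrected[ok] - median(corrected[ok])
  bins$log2_ratio_raw <- raw
  bins$log2_ratio <- corrected
  bins
}

# Recursive change-point search on one chromosome's unmasked ratio vector.
# Returns integer breakpoints (indices after which a new segment starts).
cbs_chrom <- function(x, alpha, min_bins, n_perm) {
  n <- length(x)
  breaks <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rng[1]; hi <- rng[2]
    len <- hi - lo + 1L
    if (len < 2L * min_bins) next
    seg <- x[lo:hi]
    scan <- cpp_cbs_scan(seg, min_bins)
    if (!is.finite(scan$stat) || scan$stat <= 0) next
    count <- cpp_cbs_perm_count(seg, min_bins, n_perm, scan$stat)
    p <- (1 + count) / (1 + n_perm)
    if (p >= alpha) next
    i <- scan$start; j <- scan$end   # arc covers seg[i..j]
    new_breaks <- integer(0)
    if (i > 1L) new_breaks <- c(new_breaks, lo + i - 2L)
    if (j < len) new_breaks <- c(new_breaks, lo + j - 1L)
    breaks <- c(breaks, new_breaks)
    pieces <- unique(c(lo - 1L, sort(new_breaks), hi))
    for (k in seq_len(length(pieces) - 1L)) {
      stack[[length(stack) + 1L]] <- c(pieces[k] + 1L, pieces[k + 1L])
    }
  }
  sort(unique(breaks))
}

#' Segment log2 ratios by recursive circular binary segmentation
#'
#' Per chromosome, the (i, j) arc maximizing the two-sample arc-vs-
#' complement statistic is found; the split is accepted when its seeded
#' permutation p-value is below `alpha` and both parts hold at least
#' `min_bins` bins, then the search recurses into the resulting pieces.
#' Adjacent segments whose means differ by less than `merge_tol` are merged
#' afterwards.
#'
#' @param bins output of [compute_log_ratio()]/[gc_correct()], sorted by
#'   (chrom, start).
#' @param alpha permutation significance level per split (default 0.01).
#' @param min_bins minimum bins per arc/complement (default 5).
#' @param n_perm permutations per split test (default 1000).
#' @param merge_tol post-hoc merge tolerance on adjacent segment means.
#' @param seed integer seed for the permutation test (segmentation is then
#'   deterministic).
#' @return data.frame of class `cn_segments`: chrom, start, end, n_bins,
#'   mean_log2.
#' @export
segment_bins <- function(bins, alpha = 0.01, min_bins = 5L, n_perm = 1000L,
                         merge_tol = 0.1, seed = NULL) {
  ord <- order(chrom_rank(bins$chrom), bins$chrom, bins$start)
  if (!identical(ord, seq_len(nrow(bins)))) {
    stop_invalid("bins must be sorted by (chrom, start)")
  }
  if (is.null(bins$masked)) bins$masked <- FALSE
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (chrom in unique(bins$chrom)) {
    sub <- bins[bins$chrom == chrom & !bins$masked, , drop = FALSE]
    if (nrow(sub) == 0L) next
    x <- sub$log2_ratio
    breaks <- cbs_chrom(x, alpha, min_bins, n_perm)
    bounds <- c(0L, breaks, length(x))
    segs <- data.frame(
      chrom = chrom,
      start = sub$start[bounds[-length(bounds)] + 1L],
      end = sub$end[bounds[-1L]],
      n_bins = diff(bounds),
      mean_log2 = vapply(seq_len(length(bounds) - 1L), function(k)
        mean(x[(bounds[k] + 1L):bounds[k + 1L]]), 0))
    segs <- merge_adjacent_segments(segs, merge_tol)
    out[[chrom]] <- segs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cn_segments", "data.frame")
  res
}

merge_adjacent_segments <- function(segs, merge_tol) {
  repeat {
    if (nrow(segs) < 2L) return(segs)
    d <- abs(diff(segs$mean_log2))
    if (all(d >= merge_tol)) return(segs)
    k <- which.min(d)   # merge the most similar adjacent pair first
    w <- segs$n_bins[k] + segs$n_bins[k + 1L]
    segs$mean_log2[k] <- (segs$mean_log2[k] * segs$n_bins[k] +
                            segs$mean_log2[k + 1L] * segs$n_bins[k + 1L]) / w
    segs$end[k] <- segs$end[k + 1L]
    segs$n_bins[k] <- w
    segs <- segs[-(k + 1L), , drop = FALSE]
  }
}

#' Read a chromosome-arm table
#' @param path TSV with columns chrom, arm, start, end (0-based half-open).
#' @export
read_arm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "arm", "start", "end"), names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  df
}

#' Call gains and losses and annotate focal vs arm-level scope
#'
#' @param segments a `cn_segments` data.frame.
#' @param gain_thresh,loss_thresh mean log2 thresholds for gain/loss calls
#'   (defaults +0.3 / -0.3, separating single-copy events at purity ~0.7
#'   from noise).
#' @param arm_table chromosome-arm table (see [read_arm_table()]).
#' @param arm_cover fraction of an arm a called segment must cover to be
#'   arm-level (default 0.8).
#' @return `segments` with columns `call` (gain/loss/neutral), `scope`
#'   (focal/arm-level; NA for neutral) and `arm`.
#' @export
call_gain_loss <- function(segments, gain_thresh = 0.3, loss_thresh = -0.3,
                           arm_table = NULL, arm_cover = 0.8) {
  call <- ifelse(segments$mean_log2 >= gain_thresh, "gain",
                 ifelse(segments$mean_log2 <= loss_thresh, "loss",
                        "neutral"))
  scope <- rep(NA_character_, nrow(segments))
  arm <- rep(NA_character_, nrow(segments))
  for (i in which(call != "neutral")) {
    scope[i] <- "focal"
    if (is.null(arm_table)) next
    arms <- arm_table[arm_table$chrom == segments$chrom[i], , drop = FALSE]
    if (nrow(arms) == 0L) {
      warning(sprintf("segment on %s outside arm table; scope set to focal",
                      segments$chrom[i]), call. = FALSE)
      next
    }
    cov <- overlap_len(segments$start[i], segments$end[i],
                       arms$start, arms$end) / (arms$end - arms$start)
    best <- which.max(cov)
    arm[i] <- arms$arm[best]
    if (cov[best] >= arm_cover) scope[i] <- "arm-level"
  }
  segments$call <- call
  segments$scope <- scope
  segments$arm <- arm
  segments
}

#' Flag chromothripsis-like copy-number oscillation on one chromosome
#'
#' Segment means are collapsed into discrete states (1-D single-linkage
#' clustering: sorted means are cut where adjacent values differ by more
#' than `state_tol`); the longest run of segments alternating between
#' exactly two states is measured, and the chromosome is flagged when that
#' run reaches `min_switches` segments.
#'
#' @param segments segments of one chromosome (>= 2 rows).
#' @param min_switches minimum alternating run length in segments.
#' @param state_tol clustering tolerance on segment means.
#' @return list with `flag`, `n_switches` (longest alternating run) and
#'   `states` (state id per segment).
#' @export
detect_oscillation <- function(segments, min_switches = 8L,
                               state_tol = 0.15) {
  if (length(unique(segments$chrom)) > 1L) {
    stop_invalid("oscillation detection works on one chromosome at a time")
  }
  n <- nrow(segments)
  if (n < 2L) return(list(flag = FALSE, n_switches = n, states = rep(1L, n)))
  means <- segments$mean_log2
  o <- order(means)
  state_sorted <- cumsum(c(1, diff(means[o]) > state_tol))
  states <- integer(n)
  states[o] <- state_sorted
  best <- 1L
  for (i in seq_len(n - 1L)) {
    a <- states[i]; b <- states[i + 1L]
    if (a == b) next
    run <- 2L
    k <- i + 2L
    while (k <= n && states[k] == (if (run %% 2L == 0L) a else b)) {
      run <- run + 1L
      k <- k + 1L
    }
    best <- max(best, run)
  }
  list(flag = best >= min_switches, n_switches = best, states = states)
}

#' Write segments in SEG format
#' @param segments a `cn_segments` data.frame (optionally with calls).
#' @param path output path.
#' @param sample sample identifier for the first SEG column.
#' @export
write_seg <- function(segments, path, sample = "TUMOR") {
  out <- data.frame(sample = sample, chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    n_bins = segments$n_bins,
                    mean_log2 = segments$mean_log2)
  extra <- intersect(c("call", "scope", "arm"), names(segments))
  out <- cbind(out, segments[, extra, drop = FALSE])
  write_tsv(out, path)
}
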
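# Sequencing-based microsatellite-instability calling.
#
# Per coding microsatellite, the tumor and matched-normal repeat-length read
# distributions are compared by a two-sample Kolmogorov-Smirnov test; loci
# whose difference survives false-discovery-rate control are MSI events, and
# the per-genome event count classifies the genome as MSS or MSI-H.

as_length_hist <- function(h, name) {
  if (is.data.frame(h)) h <- setNames(h$read_count, h$length)
  if (length(h) == 0L || is.null(names(h))) {
    stop_invalid("`%s` must be a non-empty named count vector (names = repeat lengths)", name)
  }
  if (any(h < 0)) stop_invalid("`%s` has negative counts", name)
  h
}

#' Two-sample KS statistic between repeat-length histograms
#'
#' `D = max |F_tumor - F_normal|` over the pooled integer support, with
#' ECDFs formed from the read counts. Depends only on the two proportions,
#' not the absolute counts.
#'
#' @param tumor_hist,normal_hist named count vectors (names are integer
#'   repeat lengths) or data.frames with `length`/`read_count` columns.
#' @return the statistic D in \[0, 1\].
#' @export
ks_statistic <- function(tumor_hist, normal_hist) {
  t_h <- as_length_hist(tumor_hist, "tumor_hist")
  n_h <- as_length_hist(normal_hist, "normal_hist")
  n <- sum(t_h); m <- sum(n_h)
  if (n == 0 || m == 0) stop_invalid("histograms must have positive total counts")
  support <- sort(unique(c(as.numeric(names(t_h)), as.numeric(names(n_h)))))
  ft <- fu <- setNames(numeric(length(support)), support)
  ft[names(t_h)] <- t_h
  fu[names(n_h)] <- n_h
  max(abs(cumsum(ft) / n - cumsum(fu) / m))
}

#' P-value for the two-sample KS statistic
#'
#' Asymptotic: `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)` with
#' `lambda = D * sqrt(n m / (n + m))`, clipped to \[0, 1\]. With integer
#' repeat lengths the data are heavily tied and the asymptotic p-value is
#' conservative; the permutation method (label permutation of the pooled
#' reads, add-one corrected) is exact up to Monte Carlo error and is the
#' reference for small or discrete samples. The permutation method needs
#' the two histograms, not just D.
#'
#' @param D observed statistic.
#' @param n,m total read counts of the two samples.
#' @param method "asymptotic" or "permutation".
#' @param tumor_hist,normal_hist histograms (required for "permutation").
#' @param B permutation count.
#' @return p-value in \[0, 1\].
#' @export
ks_pvalue <- function(D, n, m, method = c("asymptotic", "permutation"),
                      tumor_hist = NULL, normal_hist = NULL, B = 10000L) {
  method <- match.arg(method)
  if (D < 0 || D > 1) stop_invalid("`D` must lie in [0, 1]")
  if (n < 1 || m < 1) stop_invalid("`n` and `m` must be >= 1")
  if (method == "asymptotic") {
    lambda <- D * sqrt(n * m / (n + m))
    if (lambda < 1e-12) return(1)
    k <- seq_len(101L)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    return(min(1, max(0, p)))
  }
  if (is.null(tumor_hist) || is.null(normal_hist)) {
    stop_invalid("permutation method requires `tumor_hist` and `normal_hist`")
  }
  t_h <- as_length_hist(tumor_hist, "tumor_hist")
  n_h <- as_length_hist(normal_hist, "normal_hist")
  support <- sort(unique(c(as.numeric(names(t_h)), as.numeric(names(n_h)))))
  tv <- nv <- setNames(integer(length(support)), support)
  tv[names(t_h)] <- as.integer(t_h)
  nv[names(n_h)] <- as.integer(n_h)
  cpp_ks_perm_pvalue(unname(tv), unname(nv), as.integer(B))
}

#' KS test of one microsatellite locus
#'
#' @inheritParams ks_pvalue
#' @param tumor_hist,normal_hist repeat-length read histograms.
#' @return list with D, p, n, m.
#' @export
ks_test_hist <- function(tumor_hist, normal_hist,
                         method = c("asymptotic", "permutation"),
                         B = 10000L) {
  method <- match.arg(method)
  D <- ks_statistic(tumor_hist, normal_hist)
  t_h <- as_length_hist(tumor_hist, "tumor_hist")
  n_h <- as_length_hist(normal_hist, "normal_hist")
  n <- sum(t_h); m <- sum(n_h)
  p <- ks_pvalue(D, n, m, method, tumor_hist = t_h, normal_hist = n_h, B = B)
  list(D = D, p = p, n = n, m = m)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment over one family of tests (here: the testable
#' microsatellite loci of one tumor-normal pair).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values (monotone, clipped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify a genome's MSI status from its event count
#'
#' @param n_events number of MSI events (FDR-significant loci).
#' @param msih_min_events minimum events for MSI-H (default 20; MSS genomes
#'   carry on the order of 0-5 events, MSI-H genomes tens to hundreds).
#' @return "MSS" or "MSI-H".
#' @export
classify_msi_status <- function(n_events, msih_min_events = 20L) {
  check_count(n_events, "n_events")
  if (n_events >= msih_min_events) "MSI-H" else "MSS"
}

#' Call MSI events and genome status from microsatellite histograms
#'
#' Input is the long histogram table: one row per (locus, sample, repeat
#' length) with read counts; `sample` is `"normal"` or a tumor label such
#' as `"tumor:T1"`. Each tumor sample is tested against the shared normal:
#' loci with at least `min_reads` reads in both samples enter the testing
#' family, get a KS statistic, p-value and BH q-value, and are events when
#' `q < fdr_threshold`. Undercovered loci are excluded from the family and
#' reported as untestable. The case-level status combines per-sample
#' statuses by `combine`.
#'
#' @param microsat long data.frame (locus_id, sample, length, read_count).
#' @param fdr_threshold FDR level for event calling (default 0.05).
#' @param min_reads per-sample read minimum for a locus to be testable.
#' @param method p-value method, see [ks_pvalue()].
#' @param B permutation count when `method = "permutation"`.
#' @param msih_min_events see [classify_msi_status()].
#' @param combine how per-sample statuses roll up to the case: majority,
#'   any, or all.
#' @return object of class `msi_result`: `$per_locus` (sample, locus_id,
#'   n, m, D, p, q, is_event), `$per_sample` (event and untestable counts,
#'   status), `$status` (case level), `$params`.
#' @export
call_msi_events <- function(microsat, fdr_threshold = 0.05,
                            min_reads = 20L,
                            method = c("asymptotic", "permutation"),
                            B = 2000L, msih_min_events = 20L,
                            combine = c("majority", "any", "all")) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  stopifnot(all(c("locus_id", "sample", "length", "read_count") %in%
                  names(microsat)))
  tumor_samples <- sort(setdiff(unique(microsat$sample), "normal"))
  if (length(tumor_samples) == 0L) stop_invalid("no tumor samples in table")
  normal_tab <- microsat[microsat$sample == "normal", , drop = FALSE]
  normal_by_locus <- split(normal_tab, normal_tab$locus_id)

  per_locus <- list()
  per_sample <- list()
  for (s in tumor_samples) {
    tab <- microsat[microsat$sample == s, , drop = FALSE]
    by_locus <- split(tab, tab$locus_id)
    ids <- names(by_locus)
    n_v <- m_v <- D_v <- p_v <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
      nh <- normal_by_locus[[ids[i]]]
      if (is.null(nh)) next
      t_h <- setNames(by_locus[[i]]$read_count, by_locus[[i]]$length)
      n_h <- setNames(nh$read_count, nh$length)
      n_v[i] <- sum(t_h); m_v[i] <- sum(n_h)
      if (n_v[i] < min_reads || m_v[i] < min_reads) next
      D_v[i] <- ks_statistic(t_h, n_h)
      p_v[i] <- ks_pvalue(D_v[i], n_v[i], m_v[i], method,
                          tumor_hist = t_h, normal_hist = n_h, B = B)
    }
    testable <- !is.na(p_v)
    q_v <- rep(NA_real_, length(ids))
    q_v[testable] <- bh_adjust(p_v[testable])
    is_event <- !is.na(q_v) & q_v < fdr_threshold
    per_locus[[s]] <- data.frame(sample = s, locus_id = ids,
                                 n = n_v, m = m_v, D = D_v, p = p_v,
                                 q = q_v, testable = testable,
                                 is_event = is_event)
    n_events <- sum(is_event)
    per_sample[[s]] <- data.frame(
      sample = s, n_loci = length(ids), n_testable = sum(testable),
      n_untestable = sum(!testable), n_events = n_events,
      status = if (sum(testable) > 0) {
        classify_msi_status(n_events, msih_min_events)
      } else NA_character_)
  }
  per_locus <- do.call(rbind, per_locus)
  rownames(per_locus) <- NULL
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL

  statuses <- per_sample$status[!is.na(per_sample$status)]
  status <- if (length(statuses) == 0L) {
    NA_character_
  } else {
    n_h <- sum(statuses == "MSI-H")
    switch(combine,
           majority = if (n_h > length(statuses) / 2) "MSI-H" else "MSS",
           any = if (n_h > 0) "MSI-H" else "MSS",
           all = if (n_h == length(statuses)) "MSI-H" else "MSS")
  }
  structure(list(per_locus = per_locus, per_sample = per_sample,
                 status = status,
                 params = list(fdr_threshold = fdr_threshold,
                               min_reads = min_reads, method = method,
                               B = if (method == "permutation") B else NA,
                               msih_min_events = msih_min_events,
                               combine = combine)),
            class = "msi_result")
}

#' @exportS3Method print msi_result
print.msi_result <- function(x, ...) {
  cat(sprintf("MSI calling (%s KS p-values, FDR < %g): case status %s\n",
              x$params$method, x$params$fdr_threshold,
              ifelse(is.na(x$status), "untestable", x$status)))
  for (i in seq_len(nrow(x$per_sample))) {
    r <- x$per_sample[i, ]
    cat(sprintf("  %s: %d events / %d testable loci (%d untestable) -> %s\n",
                r$sample, r$n_events, r$n_testable, r$n_untestable,
                ifelse(is.na(r$status), "untestable", r$status)))
  }
  invisible(x)
}

#' Write MSI results (per-locus TSV + case status JSON)
#' @param x an `msi_result`.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @export
write_msi_result <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "msi_result"))
  if (!is.null(tsv_path)) write_tsv(x$per_locus, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(status = x$status,
                              per_sample = x$per_sample,
                              params = x$params),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
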
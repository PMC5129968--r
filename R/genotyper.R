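# Joint genotyping by read-evidence rescue.
#
# A mutation called in any regional biopsy is re-examined in every region:
# regions with supporting read evidence above the rescue thresholds are
# marked present even if their caller missed the mutation. Without this
# step, caller dropout inflates apparent intratumoral heterogeneity.

#' Rescue thresholds for read-evidence re-examination
#'
#' A region is rescued at a site when it was not originally called there
#' but `alt_count >= min_alt_reads`, `alt/(alt+ref) >= min_vaf` and
#' `alt + ref >= min_depth`. Cells with depth below `min_depth` are flagged
#' non-evaluable.
#'
#' @param min_alt_reads minimum supporting reads (default 2, suppressing
#'   single-read sequencing errors).
#' @param min_vaf minimum variant allele fraction (default 0.02).
#' @param min_depth minimum total depth for a cell to be evaluable
#'   (default 10).
#' @return object of class `rescue_thresholds`.
#' @export
rescue_thresholds <- function(min_alt_reads = 2L, min_vaf = 0.02,
                              min_depth = 10L) {
  check_count(min_alt_reads, "min_alt_reads")
  check_fraction(min_vaf, "min_vaf")
  check_count(min_depth, "min_depth")
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_vaf = min_vaf, min_depth = as.integer(min_depth)),
            class = "rescue_thresholds")
}

#' Re-examine one candidate site across all regions
#'
#' @param called_in character vector of regions whose caller reported the
#'   site.
#' @param evidence data.frame with columns region, alt_count, ref_count
#'   covering every region of the case exactly once.
#' @param regions all region labels of the case.
#' @param thresholds a [rescue_thresholds()].
#' @return data.frame with one row per region: present, provenance
#'   (called/rescued/absent) and evaluable.
#' @export
rescue_site <- function(called_in, evidence, regions,
                        thresholds = rescue_thresholds()) {
  i <- match(regions, evidence$region)
  if (anyNA(i)) {
    stop_invalid("evidence missing region(s): %s",
                 paste(regions[is.na(i)], collapse = ", "))
  }
  alt <- evidence$alt_count[i]
  depth <- alt + evidence$ref_count[i]
  called <- regions %in% called_in
  evaluable <- called | depth >= thresholds$min_depth
  vaf <- ifelse(depth > 0, alt / depth, 0)
  rescued <- !called & evaluable & alt >= thresholds$min_alt_reads &
    vaf >= thresholds$min_vaf
  data.frame(region = regions,
             present = called | rescued,
             provenance = ifelse(called, "called",
                                 ifelse(rescued, "rescued", "absent")),
             evaluable = evaluable)
}

#' Build the sites x regions presence matrix
#'
#' Applies [rescue_site()] to every site of the candidate union. Originally
#' called cells are always present with provenance "called"; rescue never
#' introduces sites outside the union of per-region calls.
#'
#' @param sites site union from [merge_candidate_sites()] (needs a
#'   `called_in` column).
#' @param evidence long evidence table (chrom, pos, ref, alt, region,
#'   alt_count, ref_count) covering every site x region.
#' @param thresholds a [rescue_thresholds()].
#' @param regions region labels; defaults to those seen in `evidence`.
#' @return object of class `presence_matrix`: list with the `sites` table
#'   and logical/character matrices `present`, `provenance`, `evaluable`
#'   (rows = sites, columns = regions).
#' @export
build_presence_matrix <- function(sites, evidence,
                                  thresholds = rescue_thresholds(),
                                  regions = NULL) {
  if (nrow(sites) == 0L) stop_invalid("site union is empty")
  regions <- regions %||% sort(unique(evidence$region))
  keys <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  ev_key <- site_key(evidence$chrom, evidence$pos, evidence$ref,
                     evidence$alt)
  n <- length(keys); R <- length(regions)
  alt <- depth <- matrix(NA_real_, n, R, dimnames = list(keys, regions))
  idx <- cbind(match(ev_key, keys), match(evidence$region, regions))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  alt[idx[keep, , drop = FALSE]] <- evidence$alt_count[keep]
  depth[idx[keep, , drop = FALSE]] <-
    evidence$alt_count[keep] + evidence$ref_count[keep]
  if (anyNA(alt)) {
    miss <- which(is.na(alt), arr.ind = TRUE)
    stop_invalid("evidence missing for site %s in region %s (and %d more)",
                 keys[miss[1, 1]], regions[miss[1, 2]], nrow(miss) - 1L)
  }
  called <- matrix(FALSE, n, R, dimnames = list(keys, regions))
  called_sets <- strsplit(sites$called_in, ",", fixed = TRUE)
  for (j in seq_len(R)) {
    called[, j] <- vapply(called_sets, function(s) regions[j] %in% s, TRUE)
  }
  evaluable <- called | depth >= thresholds$min_depth
  vaf <- ifelse(depth > 0, alt / depth, 0)
  rescued <- !called & evaluable & alt >= thresholds$min_alt_reads &
    vaf >= thresholds$min_vaf
  present <- called | rescued
  provenance <- matrix("absent", n, R, dimnames = list(keys, regions))
  provenance[rescued] <- "rescued"
  provenance[called] <- "called"
  structure(list(sites = sites, regions = regions, present = present,
                 provenance = provenance, evaluable = evaluable,
                 thresholds = thresholds,
                 n_called = sum(called), n_rescued = sum(rescued)),
            class = "presence_matrix")
}

#' Build a presence matrix directly from known regional distributions
#'
#' For inputs that already state, per mutation, the set of carrying regions
#' (e.g. a curated mutation table), bypassing read evidence. All present
#' cells get provenance "called" and every cell is evaluable.
#'
#' @param mutations data.frame with at least chrom, pos, ref, alt and a
#'   comma-separated `regions` column.
#' @param regions all region labels of the case.
#' @return a `presence_matrix`.
#' @export
presence_from_regions <- function(mutations, regions) {
  if (nrow(mutations) == 0L) stop_invalid("mutation table is empty")
  keys <- site_key(mutations$chrom, mutations$pos, mutations$ref,
                   mutations$alt)
  sets <- strsplit(mutations$regions, ",", fixed = TRUE)
  present <- t(matrix(vapply(sets, function(s) regions %in% s,
                             logical(length(regions))),
                      nrow = length(regions)))
  dimnames(present) <- list(keys, regions)
  sites <- mutations
  sites$called_in <- vapply(sets, function(s)
    paste(sort(intersect(regions, s)), collapse = ","), "")
  provenance <- ifelse(present, "called", "absent")
  structure(list(sites = sites, regions = regions, present = present,
                 provenance = provenance,
                 evaluable = matrix(TRUE, nrow(present), ncol(present),
                                    dimnames = dimnames(present)),
                 thresholds = NULL,
                 n_called = sum(present), n_rescued = 0L),
            class = "presence_matrix")
}

#' @exportS3Method print presence_matrix
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix: %d sites x %d regions (%s)\n",
              nrow(x$present), length(x$regions),
              paste(x$regions, collapse = ", ")))
  cat(sprintf("  cells: %d called, %d rescued, %d non-evaluable\n",
              x$n_called, x$n_rescued, sum(!x$evaluable)))
  invisible(x)
}

#' Write a presence matrix as a TSV with provenance codes
#' @param pm a `presence_matrix`.
#' @param path output path.
#' @export
write_presence_matrix <- function(pm, path) {
  out <- cbind(pm$sites[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(pm$provenance, optional = TRUE))
  write_tsv(out, path)
}
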
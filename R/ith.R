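# Spatial mutation categorization and intratumoral-heterogeneity summaries.
#
# With R regional biopsies, a mutation present in all R evaluable regions is
# "public", in exactly one "private", and in between "shared" (for R = 3:
# 3, 2 and 1 observed biopsies respectively). Public fraction is the basic
# ITH statistic: the lower it is, the more heterogeneous the tumor.

#' Categorize one presence row
#'
#' Categorization is over evaluable regions only: low-coverage regions
#' cannot testify either way, and counting them as absent would manufacture
#' spurious private labels.
#'
#' @param present logical presence vector over regions.
#' @param evaluable logical vector of the same length (default: all).
#' @return list with `label` ("public", "shared", "private"),
#'   `n_regions_present`, `n_evaluable` and `partial` (TRUE when at least
#'   one region was non-evaluable).
#' @export
classify_regional <- function(present, evaluable = NULL) {
  evaluable <- evaluable %||% rep(TRUE, length(present))
  stopifnot(length(evaluable) == length(present))
  n_eval <- sum(evaluable)
  n_present <- sum(present & evaluable)
  if (n_eval == 0L || n_present == 0L) {
    stop_invalid("cannot categorize a site absent from every evaluable region")
  }
  label <- if (n_present == n_eval) "public"
           else if (n_present == 1L) "private"
           else "shared"
  list(label = label, n_regions_present = n_present,
       n_evaluable = n_eval, partial = n_eval < length(present))
}

#' Per-mutation spatial categories for a whole presence matrix
#'
#' @param pm a `presence_matrix`.
#' @return the `sites` table with appended columns `category`,
#'   `n_regions_present`, `n_evaluable`, `partial`.
#' @export
categorize_mutations <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  n <- nrow(pm$present)
  category <- character(n); npres <- integer(n); neval <- integer(n)
  partial <- logical(n)
  for (i in seq_len(n)) {
    cl <- classify_regional(pm$present[i, ], pm$evaluable[i, ])
    category[i] <- cl$label
    npres[i] <- cl$n_regions_present
    neval[i] <- cl$n_evaluable
    partial[i] <- cl$partial
  }
  out <- pm$sites
  out$category <- category
  out$n_regions_present <- npres
  out$n_evaluable <- neval
  out$partial <- partial
  out
}

#' Mutation burden in mutations per megabase
#'
#' @param n_exonic_mutations exonic mutation count.
#' @param target_size_mb capture target territory in Mb (default 50, the
#'   nominal size of a whole-exome 50 Mb capture kit).
#' @return mutations per Mb.
#' @export
mutation_burden <- function(n_exonic_mutations, target_size_mb = 50) {
  check_count(n_exonic_mutations, "n_exonic_mutations")
  if (!is.numeric(target_size_mb) || target_size_mb <= 0) {
    stop_invalid("`target_size_mb` must be > 0")
  }
  n_exonic_mutations / target_size_mb
}

#' Nonsynonymous-to-synonymous SNV ratio
#'
#' Numerator: missense + nonsense + canonical-splice single-base
#' substitutions; denominator: synonymous substitutions. Indels are
#' excluded from both sides -- NS/S is an SNV statistic.
#'
#' @param calls data.frame with consequence and (for SNV/indel telling)
#'   ref/alt columns; without ref/alt all non-indel consequences are
#'   treated as SNVs.
#' @return the ratio, or `NA` (with a warning) when no synonymous SNV is
#'   available -- the ratio is then undefined, not infinite.
#' @export
ns_s_ratio <- function(calls) {
  csq <- normalize_consequence(calls$consequence)
  is_snv <- if (all(c("ref", "alt") %in% names(calls))) {
    nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  } else !(csq %in% c("frameshift_indel", "inframe_indel"))
  ns <- sum(is_snv & csq %in% c("missense", "nonsense", "splicing"))
  s <- sum(is_snv & csq == "synonymous")
  if (s == 0L) {
    warning("no synonymous SNVs: NS/S ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  ns / s
}

#' ITH summary for one case
#'
#' @param pm a `presence_matrix`.
#' @param target_size_mb capture target size in Mb for the burden statistic.
#' @return object of class `ith_summary`: category counts and fractions,
#'   per-region mutation counts, burden per Mb, NS/S ratio, and the
#'   categorized per-mutation table (`$mutations`).
#' @export
ith_summary <- function(pm, target_size_mb = 50) {
  mut <- categorize_mutations(pm)
  counts <- c(public = sum(mut$category == "public"),
              shared = sum(mut$category == "shared"),
              private = sum(mut$category == "private"))
  fractions <- counts / sum(counts)
  per_region <- colSums(pm$present & pm$evaluable)
  ns_s <- if ("consequence" %in% names(mut)) {
    suppressWarnings(ns_s_ratio(mut))
  } else NA_real_
  structure(list(n_mutations = nrow(mut), counts = counts,
                 fractions = fractions, per_region = per_region,
                 n_partial = sum(mut$partial),
                 burden_per_mb = mutation_burden(nrow(mut), target_size_mb),
                 target_size_mb = target_size_mb,
                 ns_s_ratio = ns_s, mutations = mut),
            class = "ith_summary")
}

#' @exportS3Method print ith_summary
print.ith_summary <- function(x, digits = 3, ...) {
  cat(sprintf("ITH summary: %d mutations across %d regions\n",
              x$n_mutations, length(x$per_region)))
  for (lab in names(x$counts)) {
    cat(sprintf("  %-7s %5d  (%.1f%%)\n", lab, x$counts[[lab]],
                100 * x$fractions[[lab]]))
  }
  cat(sprintf("  burden: %.2f mutations/Mb (target %.1f Mb)\n",
              x$burden_per_mb, x$target_size_mb))
  if (!is.na(x$ns_s_ratio)) {
    cat(sprintf("  NS/S ratio: %.2f\n", x$ns_s_ratio))
  }
  if (x$n_partial > 0) {
    cat(sprintf("  %d mutation(s) categorized over a reduced region set\n",
                x$n_partial))
  }
  invisible(x)
}

#' Write an ITH summary as JSON
#' @param x an `ith_summary`.
#' @param path output path.
#' @export
write_ith_summary <- function(x, path) {
  stopifnot(inherits(x, "ith_summary"))
  jsonlite::write_json(list(
    n_mutations = x$n_mutations,
    counts = as.list(x$counts), fractions = as.list(x$fractions),
    per_region = as.list(x$per_region), n_partial = x$n_partial,
    burden_per_mb = x$burden_per_mb, target_size_mb = x$target_size_mb,
    ns_s_ratio = x$ns_s_ratio), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
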
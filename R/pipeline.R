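# End-to-end per-case orchestration: joint genotyping -> ITH -> MSI ->
# copy number -> evolutionary interpretation, with every threshold echoed
# into the report metadata.

#' Run the full pipeline on one multiregion case
#'
#' Stages mirror the analysis order of a multiregion exome study: candidate
#' site union and read-evidence rescue, spatial categorization and ITH
#' summary, microsatellite-instability calling, copy-number segmentation
#' and calling per region, then case-level evolution. Stages whose inputs
#' are absent (e.g. no microsatellite table) are skipped and noted.
#'
#' @param calls per-region calls: a data.frame with a `region` column, a
#'   list of such data.frames, or a `sim_case` (whose tables are then
#'   used wholesale).
#' @param evidence long read-evidence table covering every site x region.
#' @param microsat optional long microsatellite histogram table.
#' @param depth optional named list (by region) of depth-bin tables.
#' @param catalog optional [hotspot_catalog()].
#' @param gene_models,arm_table optional annotation tables.
#' @param pathway_map optional gene-to-pathway map.
#' @param thresholds [rescue_thresholds()].
#' @param fdr_threshold,msi_min_reads,msi_method,msih_min_events,msi_combine
#'   MSI parameters, see [call_msi_events()].
#' @param alpha,min_bins,n_perm,merge_tol segmentation parameters, see
#'   [segment_bins()].
#' @param gain_thresh,loss_thresh,arm_cover calling parameters, see
#'   [call_gain_loss()].
#' @param min_switches,state_tol oscillation parameters, see
#'   [detect_oscillation()].
#' @param target_size_mb capture target size for the burden statistic.
#' @param seed integer seed (segmentation permutations).
#' @return object of class `case_report`.
#' @export
run_case <- function(calls, evidence = NULL, microsat = NULL, depth = NULL,
                     catalog = NULL, gene_models = NULL, arm_table = NULL,
                     pathway_map = NULL,
                     thresholds = rescue_thresholds(),
                     fdr_threshold = 0.05, msi_min_reads = 20L,
                     msi_method = "asymptotic", msih_min_events = 20L,
                     msi_combine = "majority",
                     alpha = 0.01, min_bins = 5L, n_perm = 1000L,
                     merge_tol = 0.1,
                     gain_thresh = 0.3, loss_thresh = -0.3, arm_cover = 0.8,
                     min_switches = 8L, state_tol = 0.15,
                     target_size_mb = 50, seed = 1L) {
  if (inherits(calls, "sim_case")) {
    sim <- calls
    calls <- sim$calls
    evidence <- evidence %||% sim$evidence
    microsat <- microsat %||% sim$microsat
    depth <- depth %||% sim$depth
  }
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  if (is.null(evidence)) stop_invalid("`evidence` is required")
  regions <- sort(unique(evidence$region))
  if (length(regions) < 2L) {
    stop_invalid("pipeline needs >= 2 regions (got %d)", length(regions))
  }

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("stage %s failed: %s", stage, conditionMessage(e))
    })
  }

  sites <- with_stage("genotype", merge_candidate_sites(calls))
  pm <- with_stage("genotype",
                   build_presence_matrix(sites, evidence, thresholds,
                                         regions))
  ith <- with_stage("ith", ith_summary(pm, target_size_mb))

  msi <- NULL
  if (!is.null(microsat) && nrow(microsat)) {
    msi <- with_stage("msi",
                      call_msi_events(microsat, fdr_threshold,
                                      msi_min_reads, msi_method,
                                      msih_min_events = msih_min_events,
                                      combine = msi_combine))
  }

  segments <- NULL
  oscillation <- NULL
  if (!is.null(depth)) {
    seg_list <- list()
    osc_list <- list()
    for (r in names(depth)) {
      with_stage("copynumber", {
        bins <- compute_log_ratio(depth[[r]])
        bins <- gc_correct(bins)
        segs <- segment_bins(bins, alpha, min_bins, n_perm, merge_tol,
                             seed = seed)
        segs <- call_gain_loss(segs, gain_thresh, loss_thresh, arm_table,
                               arm_cover)
        segs$region <- r
        seg_list[[r]] <- segs
        for (ch in unique(segs$chrom)) {
          osc <- detect_oscillation(segs[segs$chrom == ch, , drop = FALSE],
                                    min_switches, state_tol)
          osc_list[[paste(r, ch)]] <-
            data.frame(region = r, chrom = ch, flag = osc$flag,
                       n_switches = osc$n_switches)
        }
      })
    }
    segments <- do.call(rbind, seg_list)
    rownames(segments) <- NULL
    oscillation <- do.call(rbind, osc_list)
    rownames(oscillation) <- NULL
  }

  evolution <- with_stage("evolution",
                          case_evolution(pm, catalog, segments, gene_models,
                                         pathway_map))

  metadata <- list(
    package_version = as.character(utils::packageVersion("tumorith")),
    seed = seed, regions = regions,
    rescue = unclass(thresholds),
    msi = list(fdr_threshold = fdr_threshold, min_reads = msi_min_reads,
               method = msi_method, msih_min_events = msih_min_events,
               combine = msi_combine),
    copynumber = list(alpha = alpha, min_bins = min_bins, n_perm = n_perm,
                      merge_tol = merge_tol, gain_thresh = gain_thresh,
                      loss_thresh = loss_thresh, arm_cover = arm_cover,
                      min_switches = min_switches, state_tol = state_tol),
    ith = list(target_size_mb = target_size_mb))

  structure(list(presence = pm, ith = ith, msi = msi, segments = segments,
                 oscillation = oscillation, evolution = evolution,
                 metadata = metadata),
            class = "case_report")
}

#' @exportS3Method print case_report
print.case_report <- function(x, ...) {
  cat("== Multiregion case report ==\n")
  print(x$ith)
  if (!is.null(x$msi)) print(x$msi)
  if (!is.null(x$segments)) {
    called <- sum(x$segments$call != "neutral")
    cat(sprintf("Copy number: %d segments, %d called (%d flagged oscillating chromosome-tracks)\n",
                nrow(x$segments), called,
                if (is.null(x$oscillation)) 0L else sum(x$oscillation$flag)))
  }
  print(x$evolution)
  invisible(x)
}

#' Render a case report as markdown text
#'
#' Includes a per-gene landscape table (functional class and regional
#' distribution) and a trunk/branch/private strata listing. Output is a
#' deterministic function of the report.
#'
#' @param report a `case_report` from [run_case()].
#' @return character vector of markdown lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "case_report"))
  out <- c("# Multiregion case report", "")
  ith <- report$ith
  out <- c(out, "## Mutational ITH", "",
           sprintf("- total mutations: %d", ith$n_mutations),
           sprintf("- %s: %d (%.1f%%)", names(ith$counts), ith$counts,
                   100 * ith$fractions),
           sprintf("- burden: %.2f mutations/Mb", ith$burden_per_mb),
           if (!is.na(ith$ns_s_ratio)) {
             sprintf("- NS/S ratio: %.2f", ith$ns_s_ratio)
           },
           "")
  if (!is.null(report$msi)) {
    out <- c(out, "## MSI status", "",
             sprintf("- case status: %s", report$msi$status),
             sprintf("- %s: %d events (%s)", report$msi$per_sample$sample,
                     report$msi$per_sample$n_events,
                     report$msi$per_sample$status),
             "")
  }
  ev <- report$evolution$events
  fun <- ev[ev$functional | ev$event_type == "missense", , drop = FALSE]
  out <- c(out, "## Gene landscape", "")
  if (nrow(fun) == 0L) {
    out <- c(out, "- zero mutations, no strata", "")
  } else {
    out <- c(out, "| gene | class | stratum | regions |",
             "|------|-------|---------|---------|",
             sprintf("| %s | %s | %s | %s |", fun$gene, fun$event_type,
                     as.character(fun$stratum), fun$regions),
             "")
    out <- c(out, "## Chronology (trunk -> branch -> private)", "")
    for (st in levels(ev$stratum)) {
      sel <- ev[ev$stratum == st & ev$functional, , drop = FALSE]
      if (nrow(sel) == 0L) next
      out <- c(out, sprintf("- **%s**: %s", st,
                            paste(unique(sel$source), collapse = ", ")))
    }
    out <- c(out, "")
  }
  if (length(report$evolution$biallelic_genes)) {
    out <- c(out, sprintf("Biallelic inactivation: %s",
                          paste(report$evolution$biallelic_genes,
                                collapse = ", ")))
  }
  if (length(report$evolution$convergent_genes)) {
    out <- c(out, sprintf("Convergent evolution: %s",
                          paste(report$evolution$convergent_genes,
                                collapse = ", ")))
  }
  if (!is.null(report$segments)) {
    called <- report$segments[report$segments$call != "neutral", ,
                              drop = FALSE]
    out <- c(out, "", "## Copy number calls", "")
    if (nrow(called)) {
      out <- c(out, sprintf("- %s %s %s (%s, %s)", called$region,
                            called$chrom, called$call, called$scope,
                            ifelse(is.na(called$arm), "-", called$arm)))
    } else {
      out <- c(out, "- none")
    }
  }
  out
}

#' Write a case report to a directory (JSON + TSVs)
#' @param report a `case_report`.
#' @param dir output directory.
#' @export
write_case_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ith_summary(report$ith, file.path(dir, "ith.json"))
  write_tsv(report$ith$mutations, file.path(dir, "mutations_categorized.tsv"))
  write_presence_matrix(report$presence, file.path(dir, "presence.tsv"))
  if (!is.null(report$msi)) {
    write_msi_result(report$msi, file.path(dir, "msi_per_locus.tsv"),
                     file.path(dir, "msi_status.json"))
  }
  if (!is.null(report$segments)) {
    write_seg(report$segments, file.path(dir, "segments.seg"))
  }
  ev <- report$evolution
  jsonlite::write_json(
    list(strata = split(ev$events$source, ev$events$stratum),
         biallelic_genes = ev$biallelic_genes,
         convergent_genes = ev$convergent_genes,
         tree = ev$tree, metadata = report$metadata),
    file.path(dir, "evolution.json"), auto_unbox = TRUE, digits = NA)
  writeLines(render_report(report), file.path(dir, "report.md"))
  invisible(dir)
}
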
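# Case-level evolutionary interpretation: gene-level functional events,
# biallelic inactivation, convergent evolution, trunk/branch/private
# chronology and the laminar region tree.
#
# Spatial categories proxy time: public events sit on the trunk (founding
# clone), shared events on branches, private events at the leaves. Phasing
# is unknown from exome data, so two distinct loss-of-function hits on the
# same gene in the same region are assumed to hit both alleles (in trans).

#' Read a gene-model BED table
#' @param path BED-like TSV with columns chrom, start, end, gene (0-based
#'   half-open intervals).
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("chrom", "start", "end", "gene"), names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  df
}

region_set <- function(s) sort(unlist(strsplit(s, ",", fixed = TRUE)))

#' Assemble gene-level functional events
#'
#' Mutation events come from the categorized mutation table: LoF mutations
#' (nonsense/splice/frameshift), hotspot missense and plain missense
#' changes, one event per mutation with its carrying region set. Copy
#' events come from called segments overlapping a gene model by >= 1 bp:
#' identical segments observed in several regions collapse into one event
#' with the union region set.
#'
#' @param mutations categorized mutation table ([categorize_mutations()])
#'   with a comma-separated `regions` column, or with `called_in` used as
#'   the region set when `regions` is absent.
#' @param catalog optional [hotspot_catalog()] for hotspot annotation.
#' @param segments optional called segments (from [call_gain_loss()]) with
#'   a `region` column.
#' @param gene_models optional gene-model table ([read_gene_models()]);
#'   required when `segments` is given.
#' @return data.frame with columns gene, event_type, regions, source,
#'   functional (is the event a functional hit).
#' @export
gene_events <- function(mutations, catalog = NULL, segments = NULL,
                        gene_models = NULL) {
  ev <- list()
  if (!is.null(mutations) && nrow(mutations)) {
    regions <- mutations$regions %||% mutations$called_in
    fclass <- classify_consequence(mutations, catalog)
    type <- c(LoF = "LoF_mutation", hotspot_missense = "hotspot_missense",
              missense = "missense")[fclass]
    keep <- !is.na(type)
    if (any(keep)) {
      ev$mut <- data.frame(
        gene = mutations$gene[keep],
        event_type = unname(type[keep]),
        regions = vapply(regions[keep], function(s)
          paste(region_set(s), collapse = ","), ""),
        source = paste0(mutations$gene[keep], ":",
                        ifelse(nzchar(mutations$protein_change[keep]),
                               mutations$protein_change[keep],
                               site_key(mutations$chrom[keep],
                                        mutations$pos[keep],
                                        mutations$ref[keep],
                                        mutations$alt[keep]))))
    }
  }
  if (!is.null(segments) && nrow(segments)) {
    if (is.null(gene_models)) {
      stop_invalid("`gene_models` required to map copy segments to genes")
    }
    called <- segments[segments$call %in% c("gain", "loss"), , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(called))) {
      g <- gene_models[gene_models$chrom == called$chrom[i] &
                         overlap_len(gene_models$start, gene_models$end,
                                     called$start[i], called$end[i]) > 0, ,
                       drop = FALSE]
      if (nrow(g) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$gene,
        event_type = ifelse(called$call[i] == "gain", "copy_gain",
                            "copy_loss"),
        region = called$region[i] %||% "T1",
        key = paste(called$chrom[i], called$start[i], called$end[i],
                    called$call[i]))
    }
    if (length(rows)) {
      seg_ev <- do.call(rbind, rows)
      grp <- paste(seg_ev$gene, seg_ev$event_type, seg_ev$key)
      agg <- seg_ev[!duplicated(grp), , drop = FALSE]
      agg$regions <- vapply(grp[!duplicated(grp)], function(k)
        paste(sort(unique(seg_ev$region[grp == k])), collapse = ","), "")
      ev$seg <- data.frame(gene = agg$gene, event_type = agg$event_type,
                           regions = agg$regions,
                           source = paste0(agg$gene, ":", agg$key))
    }
  }
  out <- do.call(rbind, ev)
  if (is.null(out)) {
    out <- data.frame(gene = character(), event_type = character(),
                      regions = character(), source = character())
  }
  if (any(!nzchar(out$regions))) {
    stop_invalid("gene event with empty region set")
  }
  out$functional <- out$event_type %in% c("LoF_mutation", "hotspot_missense",
                                          "copy_loss")
  rownames(out) <- NULL
  out
}

#' Detect biallelic inactivation of one gene
#'
#' A region is biallelic for the gene when it carries two distinct
#' loss-of-function mutation events, or one LoF mutation plus a copy loss
#' overlapping the gene (Knudson two-hit). The trans assumption (two LoF
#' hits affect both alleles) is reported with the evidence.
#'
#' @param events gene-event table ([gene_events()]), restricted to `gene`.
#' @param gene gene symbol (used to filter `events` if needed).
#' @param regions all region labels of the case.
#' @return data.frame per region: biallelic flag plus the witnessing
#'   evidence pair.
#' @export
detect_biallelic_inactivation <- function(events, gene, regions) {
  ev <- events[events$gene == gene, , drop = FALSE]
  out <- data.frame(gene = gene, region = regions, biallelic = FALSE,
                    evidence = NA_character_)
  for (k in seq_along(regions)) {
    r <- regions[k]
    here <- ev[vapply(ev$regions, function(s) r %in% region_set(s), TRUE), ,
               drop = FALSE]
    lof <- here[here$event_type == "LoF_mutation", , drop = FALSE]
    loss <- here[here$event_type == "copy_loss", , drop = FALSE]
    if (nrow(lof) >= 2L) {
      out$biallelic[k] <- TRUE
      out$evidence[k] <- paste(lof$source[1:2], collapse = " + ")
    } else if (nrow(lof) >= 1L && nrow(loss) >= 1L) {
      out$biallelic[k] <- TRUE
      out$evidence[k] <- paste(lof$source[1], loss$source[1], sep = " + ")
    }
  }
  out
}

#' Detect convergent evolution on one gene
#'
#' Convergent iff the gene carries two distinct functional hits (LoF
#' mutation, hotspot missense or copy loss) whose region sets are disjoint
#' -- independent inactivation of the same gene in different parts of the
#' tumor.
#'
#' @param events gene-event table, restricted to `gene`.
#' @param gene gene symbol.
#' @return list with `convergent` flag and the witnessing event `pairs`.
#' @export
detect_convergence <- function(events, gene) {
  ev <- events[events$gene == gene & events$functional, , drop = FALSE]
  pairs <- list()
  if (nrow(ev) >= 2L) {
    sets <- lapply(ev$regions, region_set)
    for (i in seq_len(nrow(ev) - 1L)) {
      for (j in seq((i + 1L), nrow(ev))) {
        if (length(intersect(sets[[i]], sets[[j]])) == 0L) {
          pairs[[length(pairs) + 1L]] <-
            data.frame(gene = gene, event1 = ev$source[i],
                       event2 = ev$source[j],
                       regions1 = ev$regions[i], regions2 = ev$regions[j])
        }
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  list(convergent = !is.null(pairs), pairs = pairs)
}

#' Order events into trunk / branch / private strata
#'
#' The partial order trunk (public) < branch (shared) < private follows the
#' spatial categories: an event in all regions predates events in proper
#' subsets, which predate region-private events. No order is asserted
#' within a stratum.
#'
#' @param events gene-event table.
#' @param regions all region labels of the case.
#' @return `events` with a `stratum` factor column (trunk, branch,
#'   private), ordered trunk first.
#' @export
order_events <- function(events, regions) {
  sets <- lapply(events$regions, region_set)
  bad <- vapply(sets, function(s)
    length(s) == 0L || !all(s %in% regions), TRUE)
  if (any(bad)) {
    stop_invalid("event(s) without a valid regional category: %s",
                 paste(events$source[bad], collapse = ", "))
  }
  k <- lengths(sets)
  stratum <- ifelse(k == length(regions), "trunk",
                    ifelse(k == 1L, "private", "branch"))
  events$stratum <- factor(stratum, levels = c("trunk", "branch", "private"))
  events[order(events$stratum, events$gene), , drop = FALSE]
}

#' Greedy laminar region tree from a presence matrix
#'
#' Distinct region subsets observed among the mutations are taken in
#' decreasing mutation-count order (ties broken lexicographically) and
#' accepted when they nest (subset / superset / disjoint) with everything
#' accepted so far; conflicting subsets are flagged incompatible rather
#' than resolved -- mosaic cases surface their own inconsistency.
#'
#' @param pm a `presence_matrix` with >= 2 regions.
#' @return list with `accepted` (subset, n_mutations, parent) and
#'   `incompatible` (subset, n_mutations, conflict_with) tables.
#' @export
build_region_tree <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  R <- length(pm$regions)
  if (R < 2L) stop_invalid("region tree needs >= 2 regions")
  pat <- apply(pm$present & pm$evaluable, 1, function(z)
    paste(pm$regions[z], collapse = ","))
  pat <- pat[nzchar(pat)]
  counts <- sort(table(pat), decreasing = TRUE)
  subsets <- names(counts)
  o <- order(-as.integer(counts), subsets)
  subsets <- subsets[o]; counts <- as.integer(counts)[o]
  accepted <- list(); acc_sets <- list()
  incompatible <- list()
  for (i in seq_along(subsets)) {
    s <- region_set(subsets[i])
    conflict <- NA_character_
    for (j in seq_along(acc_sets)) {
      a <- acc_sets[[j]]
      nested <- length(intersect(s, a)) == 0L || all(s %in% a) ||
        all(a %in% s)
      if (!nested) {
        conflict <- paste(a, collapse = ",")
        break
      }
    }
    if (is.na(conflict)) {
      acc_sets[[length(acc_sets) + 1L]] <- s
      accepted[[length(accepted) + 1L]] <-
        data.frame(subset = subsets[i], n_mutations = counts[i])
    } else {
      incompatible[[length(incompatible) + 1L]] <-
        data.frame(subset = subsets[i], n_mutations = counts[i],
                   conflict_with = conflict)
    }
  }
  accepted <- do.call(rbind, accepted)
  # Parent: smallest accepted strict superset.
  accepted$parent <- NA_character_
  sets <- lapply(accepted$subset, region_set)
  for (i in seq_along(sets)) {
    sup <- which(vapply(sets, function(a)
      length(a) > length(sets[[i]]) && all(sets[[i]] %in% a), TRUE))
    if (length(sup)) {
      accepted$parent[i] <-
        accepted$subset[sup[which.min(lengths(sets[sup]))]]
    }
  }
  list(accepted = accepted,
       incompatible = if (length(incompatible)) {
         do.call(rbind, incompatible)
       } else NULL)
}

#' Full evolutionary interpretation of one case
#'
#' Runs [gene_events()], [order_events()], per-gene
#' [detect_biallelic_inactivation()] and [detect_convergence()], pathway-
#' level convergence when a gene-to-pathway map is supplied, and
#' [build_region_tree()].
#'
#' @param pm a `presence_matrix`.
#' @param catalog optional [hotspot_catalog()].
#' @param segments optional called segments with a `region` column.
#' @param gene_models gene-model table (required with `segments`).
#' @param pathway_map optional data.frame (gene, pathway); pathway-level
#'   convergence is only computed when supplied.
#' @return object of class `case_evolution`.
#' @export
case_evolution <- function(pm, catalog = NULL, segments = NULL,
                           gene_models = NULL, pathway_map = NULL) {
  if (!is.null(segments) && is.null(gene_models)) {
    warning("no gene models supplied: copy segments not mapped to gene events",
            call. = FALSE)
    segments <- NULL
  }
  mut <- categorize_mutations(pm)
  mut$regions <- apply(pm$present & pm$evaluable, 1, function(z)
    paste(pm$regions[z], collapse = ","))
  events <- gene_events(mut, catalog, segments, gene_models)
  events <- order_events(events, pm$regions)
  genes <- unique(events$gene)
  biallelic <- do.call(rbind, lapply(genes, function(g)
    detect_biallelic_inactivation(events, g, pm$regions)))
  convergence <- lapply(setNames(genes, genes), function(g)
    detect_convergence(events, g))
  convergent_genes <- names(Filter(function(x) x$convergent, convergence))
  pathway_convergent <- NULL
  if (!is.null(pathway_map)) {
    pev <- events
    pev$gene <- pathway_map$pathway[match(events$gene, pathway_map$gene)]
    pev <- pev[!is.na(pev$gene), , drop = FALSE]
    pw <- unique(pev$gene)
    pc <- lapply(setNames(pw, pw), function(p) detect_convergence(pev, p))
    pathway_convergent <- names(Filter(function(x) x$convergent, pc))
  }
  tree <- if (length(pm$regions) >= 2L) build_region_tree(pm) else NULL
  structure(list(regions = pm$regions, events = events,
                 biallelic = biallelic,
                 biallelic_genes = unique(biallelic$gene[biallelic$biallelic]),
                 convergence = convergence,
                 convergent_genes = convergent_genes,
                 pathway_convergent = pathway_convergent,
                 tree = tree,
                 assumptions = paste(
                   "two distinct LoF hits in one region are assumed to",
                   "affect both alleles (phasing unknown)")),
            class = "case_evolution")
}

#' @exportS3Method print case_evolution
print.case_evolution <- function(x, ...) {
  cat(sprintf("Case evolution over regions %s\n",
              paste(x$regions, collapse = ", ")))
  for (st in levels(x$events$stratum)) {
    ev <- x$events[x$events$stratum == st & x$events$functional, ,
                   drop = FALSE]
    if (nrow(ev) == 0L) next
    cat(sprintf("  %s:\n", st))
    for (i in seq_len(nrow(ev))) {
      cat(sprintf("    %-10s %-16s [%s]\n", ev$gene[i], ev$event_type[i],
                  ev$regions[i]))
    }
  }
  if (length(x$biallelic_genes)) {
    cat("  biallelic inactivation:", paste(x$biallelic_genes,
                                           collapse = ", "), "\n")
  }
  if (length(x$convergent_genes)) {
    cat("  convergent evolution:", paste(x$convergent_genes,
                                         collapse = ", "), "\n")
  }
  if (!is.null(x$tree) && !is.null(x$tree$incompatible)) {
    cat(sprintf("  region tree: %d incompatible subset(s) flagged\n",
                nrow(x$tree$incompatible)))
  }
  invisible(x)
}
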
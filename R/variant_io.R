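# Reading/writing mutation call sets and evidence tables, the consequence
# vocabulary, and hotspot/functional-class annotation.

#' Closed consequence vocabulary
#'
#' Every mutation call carries one of these consequence labels, fixed at
#' parse time. Caller-specific strings (e.g. ANNOVAR's "stopgain",
#' "nonsynonymous SNV") are translated through the shipped table
#' `inst/extdata/consequence_map.tsv`.
#' @export
consequence_vocabulary <- c("missense", "nonsense", "splicing",
                            "frameshift_indel", "inframe_indel",
                            "synonymous", "other")

#' Functional classes used in landscape and evolution summaries
#'
#' `LoF` = nonsense or canonical-splice mutation or out-of-frame
#' (frameshift) indel; in-frame indels are deliberately not LoF.
#' @export
functional_classes <- c("LoF", "hotspot_missense", "missense",
                        "synonymous", "other")

consequence_map_cache <- new.env(parent = emptyenv())

consequence_translation <- function() {
  if (is.null(consequence_map_cache$map)) {
    path <- system.file("extdata", "consequence_map.tsv",
                        package = "tumorith", mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    consequence_map_cache$map <- setNames(tab$consequence, tolower(tab$source))
  }
  consequence_map_cache$map
}

#' Normalize consequence strings to the closed vocabulary
#'
#' @param x character vector of consequence labels, either already in
#'   [consequence_vocabulary] or translatable via the shipped map.
#' @return character vector drawn from [consequence_vocabulary].
#' @export
normalize_consequence <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% consequence_vocabulary, x, NA_character_)
  need <- is.na(out)
  if (any(need)) {
    map <- consequence_translation()
    out[need] <- unname(map[tolower(x[need])])
  }
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_invalid(
      "unknown consequence string(s): %s\nallowed vocabulary: %s",
      paste(bad, collapse = ", "),
      paste(consequence_vocabulary, collapse = ", "))
  }
  out
}

validate_calls <- function(df, where = "calls") {
  bad_pos <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad_pos)) {
    stop_invalid("%s: record(s) %s have pos < 1 (coordinates are 1-based)",
                 where, paste(bad_pos, collapse = ", "))
  }
  bad_allele <- which(df$ref == df$alt)
  if (length(bad_allele)) {
    stop_invalid("%s: record(s) %s have ref == alt",
                 where, paste(bad_allele, collapse = ", "))
  }
  df$consequence <- normalize_consequence(df$consequence)
  df
}

#' Read one region's somatic mutation calls
#'
#' Accepts minimal VCF 4.2 (INFO keys `GENE`, `CSQ`, `PCH`) or a MAF-like
#' TSV with columns chrom, pos, ref, alt, gene, protein_change, consequence.
#' Consequence strings are normalized to [consequence_vocabulary]; records
#' violating the call invariants (pos >= 1, ref != alt) are reported with
#' their record numbers.
#'
#' @param path file to read.
#' @param region_id biopsy label attached to every returned call.
#' @param format "auto" (by extension), "vcf" or "maf".
#' @return data.frame with columns chrom, pos, ref, alt, gene,
#'   protein_change, consequence, region.
#' @export
read_region_calls <- function(path, region_id,
                              format = c("auto", "vcf", "maf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "maf"
  }
  df <- if (format == "vcf") read_calls_vcf(path) else read_calls_maf(path)
  if (nrow(df) == 0L) {
    warning(sprintf("no mutation records in %s", path), call. = FALSE)
    df$region <- character(0)
    return(df)
  }
  df <- validate_calls(df, where = path)
  df$region <- region_id
  rownames(df) <- NULL
  df
}

read_calls_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), protein_change = character(),
                      consequence = character()))
  }
  info_field <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    ifelse(is.na(v), "", v)
  }
  data.frame(chrom = fix[, "CHROM"],
             pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             gene = info_field("GENE"),
             protein_change = info_field("PCH"),
             consequence = info_field("CSQ"))
}

maf_columns <- c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                 "consequence")

read_calls_maf <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(pos = "integer"))
  missing <- setdiff(maf_columns, names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  df$protein_change[is.na(df$protein_change)] <- ""
  df[, c(maf_columns, intersect("region", names(df)))]
}

#' Write calls as a MAF-like TSV
#' @param calls data.frame of calls (with or without a region column).
#' @param path output path.
#' @export
write_maf <- function(calls, path) {
  write_tsv(calls[, c(maf_columns, intersect("region", names(calls)))], path)
}

#' Write one region's calls as minimal VCF 4.2
#'
#' INFO carries `GENE`, `CSQ` and (when non-empty) `PCH`; when `evidence`
#' is supplied the single sample column carries `AD` (ref,alt depths).
#'
#' @param calls data.frame of calls for one region.
#' @param path output path.
#' @param sample_id sample column name.
#' @param evidence optional evidence table (chrom, pos, ref, alt, region,
#'   alt_count, ref_count) restricted to this region.
#' @export
write_region_vcf <- function(calls, path, sample_id = "TUMOR",
                             evidence = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tumorith",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PCH,Number=1,Type=String,Description=\"Protein change (HGVS-p)\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">")
  calls <- order_sites(calls)
  info <- paste0("GENE=", calls$gene, ";CSQ=", calls$consequence,
                 ifelse(nzchar(calls$protein_change),
                        paste0(";PCH=", calls$protein_change), ""))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- data.frame(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                     ".", "PASS", info)
  if (!is.null(evidence)) {
    i <- match(site_key(calls$chrom, calls$pos, calls$ref, calls$alt),
               site_key(evidence$chrom, evidence$pos, evidence$ref,
                        evidence$alt))
    ad <- ifelse(is.na(i), ".",
                 paste0(evidence$ref_count[i], ",", evidence$alt_count[i]))
    body$FORMAT <- "AD"
    body$sample <- ad
    cols <- c(cols, "FORMAT", sample_id)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(body)) {
    writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a per-site read-evidence table
#'
#' @param path TSV with columns chrom, pos, ref, alt, region, alt_count,
#'   ref_count.
#' @return validated data.frame.
#' @export
read_evidence <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "region", "alt_count", "ref_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  if (any(df$alt_count < 0 | df$ref_count < 0)) {
    stop_invalid("%s: negative read counts", path)
  }
  df
}

#' Merge per-region candidate call sets into an ordered site union
#'
#' Every distinct (chrom, pos, ref, alt) appears once, ordered by genomic
#' coordinate, with the set of regions whose callers originally reported it.
#' Mutations called in any region become candidates for read-evidence
#' re-examination in all regions.
#'
#' @param call_sets a single calls data.frame with a `region` column, or a
#'   list of per-region data.frames.
#' @return data.frame of unique sites with a comma-separated `called_in`
#'   column.
#' @export
merge_candidate_sites <- function(call_sets) {
  if (is.data.frame(call_sets)) call_sets <- list(call_sets)
  if (length(call_sets) == 0L) stop_invalid("need at least one call set")
  all_calls <- do.call(rbind, lapply(call_sets, function(df) {
    df[, c(maf_columns, "region"), drop = FALSE]
  }))
  key <- site_key(all_calls$chrom, all_calls$pos, all_calls$ref,
                  all_calls$alt)
  gene_by_site <- tapply(all_calls$gene, key, unique, simplify = FALSE)
  conflict <- names(gene_by_site)[lengths(gene_by_site) > 1L]
  if (length(conflict)) {
    stop_invalid("conflicting gene annotation across regions at site(s): %s",
                 paste(conflict, collapse = ", "))
  }
  first <- !duplicated(key)
  sites <- all_calls[first, maf_columns, drop = FALSE]
  regions <- vapply(split(all_calls$region, key), function(r)
    paste(sort(unique(r)), collapse = ","), "")
  sites$called_in <- unname(regions[key[first]])
  sites <- order_sites(sites)
  rownames(sites) <- NULL
  sites
}

#' Read a hotspot catalog
#'
#' @param path TSV with columns gene, protein_change, count (recurrence in
#'   a somatic mutation catalog such as COSMIC).
#' @param hotspot_min_count minimum recurrence for a missense change to
#'   count as a hotspot (default 5).
#' @return object of class `hotspot_catalog`.
#' @export
read_hotspot_catalog <- function(path, hotspot_min_count = 5L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "protein_change", "count"), names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  hotspot_catalog(df, hotspot_min_count)
}

#' Construct a hotspot catalog from a data.frame
#' @param entries data.frame with gene, protein_change, count.
#' @param hotspot_min_count recurrence threshold.
#' @export
hotspot_catalog <- function(entries, hotspot_min_count = 5L) {
  if (any(entries$count < 1)) stop_invalid("catalog counts must be >= 1")
  structure(list(entries = entries,
                 hotspot_min_count = as.integer(hotspot_min_count)),
            class = "hotspot_catalog")
}

catalog_count <- function(catalog, gene, protein_change) {
  if (is.null(catalog)) return(rep(0L, length(gene)))
  i <- match(paste(gene, protein_change),
             paste(catalog$entries$gene, catalog$entries$protein_change))
  out <- catalog$entries$count[i]
  out[is.na(out)] <- 0L
  out
}

#' Assign functional classes to mutation calls
#'
#' `LoF` for nonsense, canonical-splice and frameshift (out-of-frame) indel
#' mutations; `hotspot_missense` for missense changes with catalog
#' recurrence at or above the catalog's threshold; otherwise `missense`,
#' `synonymous` or `other` (in-frame indels fall into `other`).
#'
#' @param calls data.frame with consequence, gene, protein_change columns
#'   (a single call as a one-row data.frame works).
#' @param catalog optional [hotspot_catalog()].
#' @return character vector of [functional_classes].
#' @export
classify_consequence <- function(calls, catalog = NULL) {
  csq <- normalize_consequence(calls$consequence)
  out <- rep("other", length(csq))
  out[csq %in% c("nonsense", "splicing", "frameshift_indel")] <- "LoF"
  out[csq == "synonymous"] <- "synonymous"
  is_mis <- csq == "missense"
  if (any(is_mis)) {
    cnt <- catalog_count(catalog, calls$gene[is_mis],
                         calls$protein_change[is_mis])
    thr <- if (is.null(catalog)) Inf else catalog$hotspot_min_count
    out[is_mis] <- ifelse(cnt >= thr, "hotspot_missense", "missense")
  }
  out
}
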
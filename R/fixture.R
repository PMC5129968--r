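# Curated five-case gastric adenoma validation set.
#
# A small table of the driver-gene mutations and copy-number alterations of
# five multiregion-sequenced gastric adenomas (three microsatellite-stable
# cases MSS1-3, two MSI-high cases MSI-H1/2; three biopsies T1-T3 each),
# with their regional distributions. Genomic coordinates are approximate
# hg19 gene-interval positions, present so the segment/gene-overlap code
# path runs; the scientific content is the gene, the event class and the
# regional distribution.

fixture_path <- function(name) {
  system.file("extdata", name, package = "tumorith", mustWork = TRUE)
}

#' Load the bundled gastric adenoma validation set
#'
#' @param case one of "MSS1", "MSS2", "MSS3", "MSI-H1", "MSI-H2", or NULL
#'   for every case.
#' @return for one case, a list with `case`, `regions`, `mutations`,
#'   `segments` (gain/loss-called, with a `region` column), `catalog`,
#'   `gene_models`, `arm_table` and `pathway_map`; for NULL, a named list
#'   of such lists.
#' @export
adenoma_fixture <- function(case = NULL) {
  mutations <- read.delim(fixture_path("adenoma_mutations.tsv"),
                          stringsAsFactors = FALSE)
  mutations$protein_change[is.na(mutations$protein_change)] <- ""
  segments <- read.delim(fixture_path("adenoma_segments.tsv"),
                         stringsAsFactors = FALSE)
  catalog <- read_hotspot_catalog(fixture_path("adenoma_hotspots.tsv"))
  gene_models <- read_gene_models(fixture_path("adenoma_gene_models.tsv"))
  arm_table <- read_arm_table(fixture_path("adenoma_arms.tsv"))
  pathway_map <- read.delim(fixture_path("adenoma_pathways.tsv"),
                            stringsAsFactors = FALSE)
  cases <- unique(mutations$case)
  if (!is.null(case)) {
    if (!case %in% cases) {
      stop_invalid("unknown case '%s' (available: %s)", case,
                   paste(cases, collapse = ", "))
    }
    cases <- case
  }
  out <- lapply(setNames(cases, cases), function(cs) {
    seg <- segments[segments$case == cs, , drop = FALSE]
    seg <- if (nrow(seg)) {
      call_gain_loss(seg[, setdiff(names(seg), "case")],
                     arm_table = arm_table)
    } else NULL
    list(case = cs, regions = c("T1", "T2", "T3"),
         mutations = mutations[mutations$case == cs, , drop = FALSE],
         segments = seg, catalog = catalog, gene_models = gene_models,
         arm_table = arm_table, pathway_map = pathway_map)
  })
  if (!is.null(case)) out[[case]] else out
}

#' Evolutionary interpretation of one bundled adenoma case
#'
#' Builds the presence matrix from the curated regional distributions and
#' runs [case_evolution()] with the bundled hotspot catalog, gene models
#' and pathway map.
#'
#' @param case case identifier, see [adenoma_fixture()].
#' @return a `case_evolution` object.
#' @export
adenoma_case_evolution <- function(case) {
  fx <- adenoma_fixture(case)
  pm <- presence_from_regions(fx$mutations, fx$regions)
  case_evolution(pm, catalog = fx$catalog, segments = fx$segments,
                 gene_models = fx$gene_models,
                 pathway_map = fx$pathway_map)
}
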
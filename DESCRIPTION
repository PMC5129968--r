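Package: tumorith
Title: Multiregion Tumor Sequencing: Heterogeneity, Microsatellite
    Instability, Copy Number and Clonal Chronology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multiregion tumor exome sequencing at the level of
    somatic mutation calls. Joint genotyping by read-evidence rescue across
    regional biopsies, spatial categorization of mutations as public, shared
    or private with intratumoral-heterogeneity summaries, sequencing-based
    microsatellite-instability calling from repeat-length read histograms
    (per-locus Kolmogorov-Smirnov tests with false-discovery-rate control),
    read-depth copy-number analysis (GC correction, circular binary
    segmentation, gain/loss and oscillation calls), and case-level
    evolutionary interpretation (biallelic inactivation, convergent
    evolution, trunk/branch/private chronology, region trees). Includes a
    synthetic multiregion tumor generator with known ground truth so every
    stage is testable without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
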
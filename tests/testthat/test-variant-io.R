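# Call-set reading/writing, consequence vocabulary, hotspot annotation.

test_that("VCF and MAF round trips preserve every call field", {
  set.seed(21)
  case <- simulate_case(sim_config(n_trunk = 15L, n_branch = 5L,
                                   n_private = 10L, n_microsat = 0L,
                                   n_msi_loci = 0L, seed = 21L))
  calls <- case$calls[case$calls$region == "T1", ]
  ev <- case$evidence[case$evidence$region == "T1", ]

  vcf <- tempfile(fileext = ".vcf")
  write_region_vcf(calls, vcf, sample_id = "T1", evidence = ev)
  back <- read_region_calls(vcf, "T1")
  ord <- function(df) df[order(paste(df$chrom, df$pos, df$ref, df$alt)), ]
  a <- ord(calls); b <- ord(back)
  for (col in c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                "consequence")) {
    expect_equal(unname(a[[col]]), unname(b[[col]]), label = col)
  }

  maf <- tempfile(fileext = ".tsv")
  write_maf(calls, maf)
  back2 <- ord(read_region_calls(maf, "T1", format = "maf"))
  for (col in c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                "consequence")) {
    expect_equal(unname(a[[col]]), unname(back2[[col]]), label = col)
  }
})

test_that("malformed records and unknown consequences are rejected by name", {
  bad <- data.frame(chrom = "chr1", pos = 0L, ref = "A", alt = "T",
                    gene = "G1", protein_change = "", consequence = "missense")
  f <- tempfile(fileext = ".tsv")
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_region_calls(f, "T1"), "pos")

  bad2 <- bad; bad2$pos <- 5L; bad2$consequence <- "weird_class"
  write.table(bad2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_region_calls(f, "T1"), "allowed vocabulary")

  bad3 <- bad; bad3$pos <- 5L; bad3$alt <- "A"
  write.table(bad3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_region_calls(f, "T1"), "ref == alt")

  empty <- bad[0, ]
  write.table(empty, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(res <- read_region_calls(f, "T1"), "no mutation records")
  expect_equal(nrow(res), 0L)
})

test_that("caller-specific consequence strings map into the vocabulary", {
  expect_equal(normalize_consequence(c("stopgain", "frameshift deletion",
                                       "nonsynonymous SNV", "synonymous SNV",
                                       "splice_donor_variant")),
               c("nonsense", "frameshift_indel", "missense", "synonymous",
                 "splicing"))
  expect_error(normalize_consequence("gibberish"), "allowed vocabulary")
})

test_that("candidate-site union is correct, idempotent and order-invariant", {
  tc <- toy_case()
  per_region <- split(tc$calls, tc$calls$region)
  u <- merge_candidate_sites(per_region)
  expect_equal(nrow(u), 3L)
  expect_equal(u$called_in[u$chrom == "chr1"], "T1,T2")
  expect_equal(u$called_in[u$chrom == "chr3"], "T3")
  # order-invariance over input regions
  u2 <- merge_candidate_sites(rev(per_region))
  expect_identical(u, u2)
  # identical call sets collapse to the single-set size
  same <- lapply(c("A", "B", "C"), function(r) {
    df <- tc$calls[tc$calls$region == "T1", ]; df$region <- r; df
  })
  expect_equal(nrow(merge_candidate_sites(same)), 1L)
  # disjoint sets: union is the sum
  set.seed(31)
  disjoint <- lapply(1:3, function(r) {
    data.frame(chrom = "chr9", pos = 1000L * r + 1:10, ref = "A", alt = "G",
               gene = "GX", protein_change = "", consequence = "missense",
               region = paste0("T", r))
  })
  expect_equal(nrow(merge_candidate_sites(disjoint)), 30L)
  # conflicting gene annotation is an error
  conflict <- per_region
  conflict$T2$gene[conflict$T2$chrom == "chr1"] <- "OTHER"
  expect_error(merge_candidate_sites(conflict), "conflicting gene annotation")
})

test_that("functional classes follow the LoF and hotspot definitions", {
  catalog <- hotspot_catalog(data.frame(
    gene = c("KRAS", "ERBB3"), protein_change = c("p.G13D", "p.V104M"),
    count = c(851L, 3L)))
  calls <- data.frame(
    gene = c("APC", "APC", "ARID2", "KRAS", "ERBB3", "X", "Y"),
    protein_change = c("p.R1450X", "p.E1554fs", "", "p.G13D", "p.V104M",
                       "", ""),
    consequence = c("nonsense", "frameshift_indel", "splicing", "missense",
                    "missense", "synonymous", "inframe_indel"))
  expect_equal(classify_consequence(calls, catalog),
               c("LoF", "LoF", "LoF", "hotspot_missense", "missense",
                 "synonymous", "other"))
  # threshold is >= 5: exactly 5 qualifies
  cat5 <- hotspot_catalog(data.frame(gene = "G", protein_change = "p.A1B",
                                     count = 5L))
  expect_equal(classify_consequence(
    data.frame(gene = "G", protein_change = "p.A1B",
               consequence = "missense"), cat5), "hotspot_missense")
  expect_error(hotspot_catalog(data.frame(gene = "G", protein_change = "p",
                                          count = 0L)), ">= 1")
})
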
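# Biallelic inactivation, convergence, chronology, region trees.

mk_events <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], event_type = r[[2]], regions = r[[3]],
               source = paste0(r[[1]], ":", r[[2]], ":", r[[3]]))
  }))
  out$functional <- out$event_type %in% c("LoF_mutation", "hotspot_missense",
                                          "copy_loss")
  out
}

test_that("biallelic inactivation needs two hits in the same region", {
  regions <- c("T1", "T2", "T3")
  # two public LoF mutations: biallelic everywhere
  ev <- mk_events(list("APC", "LoF_mutation", "T1,T2,T3"),
                  list("APC", "LoF_mutation", "T1,T2,T3"))
  expect_true(all(detect_biallelic_inactivation(ev, "APC", regions)$biallelic))
  # public LoF + public copy loss: biallelic everywhere
  ev <- mk_events(list("APC", "LoF_mutation", "T1,T2,T3"),
                  list("APC", "copy_loss", "T1,T2,T3"))
  expect_true(all(detect_biallelic_inactivation(ev, "APC", regions)$biallelic))
  # a single missense is never biallelic
  ev <- mk_events(list("APC", "missense", "T1,T2,T3"))
  expect_false(any(detect_biallelic_inactivation(ev, "APC", regions)$biallelic))
  # one LoF + copy loss in a different region: biallelic nowhere
  ev <- mk_events(list("APC", "LoF_mutation", "T1"),
                  list("APC", "copy_loss", "T2"))
  expect_false(any(detect_biallelic_inactivation(ev, "APC", regions)$biallelic))
  # order invariance
  ev <- mk_events(list("APC", "copy_loss", "T2"),
                  list("APC", "LoF_mutation", "T2"))
  expect_true(detect_biallelic_inactivation(ev, "APC", regions)$biallelic[2])
})

test_that("convergence requires disjoint functional hits", {
  # regionally exclusive truncating hits converge
  ev <- mk_events(list("ARID2", "LoF_mutation", "T1"),
                  list("ARID2", "LoF_mutation", "T2"))
  expect_true(detect_convergence(ev, "ARID2")$convergent)
  # one shared event is a single hit, not convergence
  ev <- mk_events(list("ARID2", "LoF_mutation", "T1,T2"))
  expect_false(detect_convergence(ev, "ARID2")$convergent)
  # overlapping region sets do not converge
  ev <- mk_events(list("ARID2", "LoF_mutation", "T1,T2"),
                  list("ARID2", "LoF_mutation", "T2"))
  expect_false(detect_convergence(ev, "ARID2")$convergent)
  # mutation vs copy loss in disjoint regions converges
  ev <- mk_events(list("APC", "LoF_mutation", "T1"),
                  list("APC", "copy_loss", "T2"),
                  list("APC", "copy_loss", "T3"))
  res <- detect_convergence(ev, "APC")
  expect_true(res$convergent)
  expect_gte(nrow(res$pairs), 3L)
  # plain missense hits never count
  ev <- mk_events(list("X", "missense", "T1"), list("X", "missense", "T2"))
  expect_false(detect_convergence(ev, "X")$convergent)
  # order invariance of the event list
  ev <- mk_events(list("ARID2", "LoF_mutation", "T2"),
                  list("ARID2", "LoF_mutation", "T1"))
  expect_true(detect_convergence(ev, "ARID2")$convergent)
})

test_that("events are stratified trunk -> branch -> private", {
  regions <- c("T1", "T2", "T3")
  ev <- mk_events(list("APC", "LoF_mutation", "T1,T2,T3"),
                  list("ARID2", "LoF_mutation", "T1,T2"),
                  list("SMARCA4", "hotspot_missense", "T3"))
  out <- order_events(ev, regions)
  expect_equal(as.character(out$stratum[out$gene == "APC"]), "trunk")
  expect_equal(as.character(out$stratum[out$gene == "ARID2"]), "branch")
  expect_equal(as.character(out$stratum[out$gene == "SMARCA4"]), "private")
  # all-public case: one stratum
  ev <- mk_events(list("A", "LoF_mutation", "T1,T2,T3"),
                  list("B", "LoF_mutation", "T1,T2,T3"))
  expect_true(all(order_events(ev, regions)$stratum == "trunk"))
  # an event naming an unknown region has no category
  ev <- mk_events(list("A", "LoF_mutation", "T9"))
  expect_error(order_events(ev, regions), "regional category")
})

test_that("region trees accept laminar subsets and flag conflicts", {
  mk_pm <- function(subsets, counts) {
    mut <- data.frame(chrom = "chr1",
                      pos = seq_len(sum(counts)), ref = "A", alt = "G",
                      regions = rep(subsets, counts))
    presence_from_regions(mut, c("T1", "T2", "T3"))
  }
  tree <- build_region_tree(mk_pm(c("T1,T2,T3", "T1,T2", "T1", "T2", "T3"),
                                  c(40, 20, 5, 4, 3)))
  expect_null(tree$incompatible)
  expect_equal(tree$accepted$parent[tree$accepted$subset == "T1,T2"],
               "T1,T2,T3")
  expect_equal(tree$accepted$parent[tree$accepted$subset == "T1"], "T1,T2")
  # {T1,T2} with 30 mutations beats {T2,T3} with 5: the latter is flagged
  tree2 <- build_region_tree(mk_pm(c("T1,T2", "T2,T3"), c(30, 5)))
  expect_equal(tree2$incompatible$subset, "T2,T3")
  expect_equal(tree2$incompatible$conflict_with, "T1,T2")
  mut1 <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                     regions = "T1")
  expect_error(build_region_tree(presence_from_regions(mut1, "T1")),
               ">= 2 regions")
})

test_that("the curated adenoma cases reproduce the reported biology", {
  fx <- adenoma_fixture()
  expect_setequal(names(fx), c("MSS1", "MSS2", "MSS3", "MSI-H1", "MSI-H2"))
  evs <- lapply(names(fx), adenoma_case_evolution)
  names(evs) <- names(fx)
  # biallelic APC in every case
  for (cs in names(evs)) {
    expect_true("APC" %in% evs[[cs]]$biallelic_genes, label = cs)
  }
  # ARID2 truncating events in all three MSS cases
  for (cs in c("MSS1", "MSS2", "MSS3")) {
    ev <- evs[[cs]]$events
    expect_true(any(ev$gene == "ARID2" & ev$event_type == "LoF_mutation"),
                label = cs)
  }
  # convergence: ARID2 in MSS2 and MSS3, APC in MSS3; not ARID2 in MSS1
  expect_true("ARID2" %in% evs$MSS2$convergent_genes)
  expect_true("ARID2" %in% evs$MSS3$convergent_genes)
  expect_true("APC" %in% evs$MSS3$convergent_genes)
  expect_false("ARID2" %in% evs$MSS1$convergent_genes)
  # APC on the trunk everywhere; KRAS/ERBB2 hotspots off the trunk
  for (cs in names(evs)) {
    ev <- evs[[cs]]$events
    expect_true(any(ev$gene == "APC" & ev$stratum == "trunk"), label = cs)
  }
  ev2 <- evs$MSS2$events
  expect_true(all(ev2$stratum[ev2$gene == "KRAS"] != "trunk"))
  ev1 <- evs$MSS1$events
  expect_true(all(ev1$stratum[ev1$gene == "ERBB2"] != "trunk"))
  # pathway-level convergence (TP53 shared + ATM private in MSS3)
  expect_true("p53_dna_damage" %in% evs$MSS3$pathway_convergent)
  # the MSI-H2 oscillating chromosome 6 is flagged in every region track
  fx2 <- fx[["MSI-H2"]]
  for (r in fx2$regions) {
    segs <- fx2$segments[fx2$segments$region == r &
                           fx2$segments$chrom == "chr6", ]
    expect_true(detect_oscillation(segs)$flag, label = r)
  }
})
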
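# a small 3-bin community spec used by several tests
smallSpec <- function(abundances = c(0.5, 0.3, 0.2), noise = "none",
                      seed = 1L, aas = c("alanine", "glycine"),
                      encoded = NULL, expressed = NULL) {
  ids <- paste0("b", seq_along(abundances))
  bp <- do.call(rbind, lapply(seq_along(ids), function(i) {
    d <- AminoCensus:::guildDefaults("other")
    data.frame(bin_id = ids[i], guild = "other",
               abundance = abundances[i], n_contigs = 2L,
               qc_pass = TRUE, as.data.frame(d),
               stringsAsFactors = FALSE)
  }))
  allAAs <- aminoAcids(loadPathwayCatalog())
  plan <- expand.grid(bin_id = ids, aa = allAAs,
                      stringsAsFactors = FALSE)
  plan$encoded <- TRUE
  plan$expressed <- TRUE
  if (!is.null(encoded))
    plan$encoded <- mapply(encoded, plan$bin_id, plan$aa)
  if (!is.null(expressed))
    plan$expressed <- plan$encoded &
      mapply(expressed, plan$bin_id, plan$aa)
  samples <- data.frame(sample_id = paste0("S_", allAAs),
                        substrate_aa = allAAs, depth = 20)
  communitySpec(bp, plan, samples, noise = noise, seed = seed)
}

test_that("a fixed seed reproduces every table exactly", {
  a <- generateCommunity(smallSpec(noise = "poisson", seed = 7))
  b <- generateCommunity(smallSpec(noise = "poisson", seed = 7))
  expect_identical(a$tables, b$tables)
  c <- generateCommunity(smallSpec(noise = "poisson", seed = 8))
  expect_false(identical(a$tables$depth, c$tables$depth))
})

test_that("zero-noise abundances are recovered exactly", {
  com <- generateCommunity(smallSpec(noise = "none"))
  bs <- GenomeBinSet(com$tables$qc, com$tables$contigs,
                     com$tables$genes)
  at <- abundanceTable(qcFilterBins(bs), com$tables$depth)
  est <- tapply(at$relative_abundance, at$bin_id, mean)
  truth <- setNames(com$truth$abundance$abundance,
                    com$truth$abundance$bin_id)
  expect_equal(est[names(truth)], truth, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("planted complete and broken pathways are scored as planted", {
  enc <- function(b, aa) !(b == "b2" && aa == "glycine")
  com <- generateCommunity(smallSpec(noise = "none", encoded = enc))
  t <- com$tables
  f <- filterHits(t$hits)
  a <- assignCategories(f, t$reference_map)
  a <- AminoCensus:::addBinIds(a, t$genes)
  pa <- a[a$category_kind == "pathway_gene", ]
  symOf <- function(b) unique(pa$category_label[pa$bin_id == b])
  gly <- pathwayGenes(loadPathwayCatalog(), "gly_decarboxylating")
  expect_true(isPathwayComplete(symOf("b1"), gly)$complete)
  r <- isPathwayComplete(symOf("b2"), gly)
  expect_false(r$complete)
  expect_length(r$missing, 1)
})

test_that("decoy ORFs for removed genes are rejected by the filter", {
  enc <- function(b, aa) aa != "glycine"
  com <- generateCommunity(smallSpec(noise = "none", encoded = enc))
  t <- com$tables
  removed <- setdiff(pathwayGenes(loadPathwayCatalog(),
                                  "gly_decarboxylating"),
                     com$truth$present_symbols$b1)
  expect_length(removed, 1)
  # unfiltered hits contain sub-threshold hits to the removed symbol
  decoyHits <- t$hits[t$hits$subject_id == paste0("ref_pw_", removed), ]
  expect_gt(nrow(decoyHits), 0)
  expect_true(all(decoyHits$identity < 50))
  kept <- filterHits(t$hits)
  expect_false(paste0("ref_pw_", removed) %in% kept$subject_id)
  a <- assignCategories(kept, t$reference_map)
  # after filtering, no bin regains a complete glycine route
  a <- AminoCensus:::addBinIds(a, t$genes)
  pa <- a[a$category_kind == "pathway_gene", ]
  gly <- pathwayGenes(loadPathwayCatalog(), "gly_decarboxylating")
  for (b in unique(t$qc$bin_id))
    expect_false(
      isPathwayComplete(unique(pa$category_label[pa$bin_id == b]),
                        gly)$complete)
})

test_that("the study-design spec mirrors the enrichment contrast", {
  spec <- emulateStudyDesign(seed = 3)
  expect_equal(nrow(spec@samples), 20)
  expect_equal(sum(spec@binParams$abundance), 1)
  guilds <- spec@binParams$guild
  expect_equal(sum(guilds == "proteolytic"), 3)
  expect_equal(sum(guilds == "fermenter"), 2)
  # dominant guild has more secreted peptidases than the fermenters
  bp <- spec@binParams
  expect_gt(min(bp$n_secreted_peptidase[bp$guild == "proteolytic"]),
            max(bp$n_secreted_peptidase[bp$guild == "fermenter"]))
})

test_that("invalid specs are rejected", {
  expect_error(smallSpec(abundances = c(0.5, 0.6)), "sum to 1")
  spec <- smallSpec()
  expect_error(communitySpec(spec@binParams, spec@pathwayPlan,
                             spec@samples, noise = "uniform"),
               "noise")
})

test_that("ground truth files are serialized alongside the tables", {
  dir <- withr::local_tempdir()
  com <- generateCommunity(smallSpec(noise = "none"), outDir = dir)
  expect_true(file.exists(file.path(dir, "hits.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.yaml")))
  # the written hits file round-trips through the reader
  h <- readHitsTable(file.path(dir, "hits.tsv"),
                     queryLengths = readReportTable(
                       file.path(dir, "query_lengths.tsv")))
  expect_equal(nrow(h), nrow(com$tables$hits))
  expect_equal(sort(h$query_id), sort(com$tables$hits$query_id))
})
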
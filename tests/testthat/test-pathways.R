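catalog <- loadPathwayCatalog()
catTb <- catalogTable(catalog)

test_that("shipped catalog covers 20 amino acids with the anchor routes", {
  expect_length(aminoAcids(catalog), 20)
  expect_length(pathwayGenes(catalog, "gly_decarboxylating"), 6)
  expect_length(pathwayGenes(catalog, "ala_dehydrogenase"), 1)
  expect_equal(pathwayGenes(catalog, "ala_dehydrogenase"), "ald")
  # every amino acid has at least one pathway
  expect_true(all(table(unique(catTb[, c("aa", "pathway_id")])$aa) >= 1))
  # lysine fermentation route has at least 8 genes
  expect_gte(length(pathwayGenes(catalog, "lys_fermentation")), 8)
  # threonine has three alternative routes
  expect_length(unique(catTb$pathway_id[catTb$aa == "threonine"]), 3)
})

test_that("catalog validation rejects degenerate definitions", {
  f <- withr::local_tempfile()
  writeLines(c("aa\tpathway_id\tgene_symbol", "alanine\tp1\t"), f)
  expect_error(loadPathwayCatalog(f), "empty gene_symbol")
  writeLines(c("aa\tpathway_id\tgene_symbol",
               "alanine\tp1\tald", "alanine\tp1\tald"), f)
  expect_error(loadPathwayCatalog(f), "duplicated")
  writeLines(c("aa\tpathway_id\tgene_symbol",
               "alanine\tp1\tald", "glycine\tp1\tgcvH"), f)
  expect_error(loadPathwayCatalog(f), "more than one amino acid")
})

test_that("pathway completeness requires every gene", {
  gly <- pathwayGenes(catalog, "gly_decarboxylating")
  expect_true(isPathwayComplete(gly, gly)$complete)
  r <- isPathwayComplete(gly[-1], gly)
  expect_false(r$complete)
  expect_equal(r$missing, gly[1])
  expect_false(isPathwayComplete(character(0), gly)$complete)
  expect_error(isPathwayComplete("x", character(0)), "empty")
})

test_that("encoded amino-acid count uses OR over alternative routes", {
  expect_equal(encodedAACount(unique(catTb$gene_symbol), catalog)$count,
               20)
  expect_equal(encodedAACount("ald", catalog)$count, 1)
  expect_equal(encodedAACount("alaT", catalog)$count, 1)  # alt route
  expect_equal(encodedAACount(character(0), catalog)$count, 0)
  # one of three threonine routes suffices
  expect_equal(encodedAACount("ltaE", catalog)$count, 1)
})

test_that("encoded count equals brute-force catalog scan on random bins", {
  set.seed(13)
  allSym <- unique(catTb$gene_symbol)
  for (i in 1:30) {
    sym <- sample(allSym, sample.int(length(allSym), 1))
    got <- encodedAACount(sym, catalog)
    expect_equal(got$count, bruteEncodedCount(sym, catTb))
    # detail is consistent with the count
    expect_equal(sum(tapply(got$detail$complete, got$detail$aa, any)),
                 got$count)
  }
})

test_that("adding a gene never decreases the encoded count", {
  set.seed(29)
  allSym <- unique(catTb$gene_symbol)
  for (i in 1:20) {
    sym <- sample(allSym, sample.int(length(allSym) - 1, 1))
    extra <- sample(setdiff(allSym, sym), 1)
    expect_gte(encodedAACount(c(sym, extra), catalog)$count,
               encodedAACount(sym, catalog)$count)
  }
})

test_that("pathway expression needs every gene above the threshold", {
  expect_true(isPathwayExpressed(c(1, 2, 0.5), TRUE)$expressed)
  r <- isPathwayExpressed(c(1, 0, 2), TRUE)
  expect_false(r$expressed)
  expect_equal(r$reason, "gene_below_threshold")
  r2 <- isPathwayExpressed(c(10, 10), FALSE)
  expect_false(r2$expressed)
  expect_equal(r2$reason, "not_encoded")
  # configurable tau
  expect_false(isPathwayExpressed(c(1, 2), TRUE, tau = 1.5)$expressed)
})

test_that("expression matrix has one row per (bin, pathway gene)", {
  subMap <- data.frame(aa = aminoAcids(catalog),
                       sample_id = paste0("S_", aminoAcids(catalog)))
  sym <- unique(catTb$gene_symbol)
  binGenes <- list(b1 = sym, b2 = sym[1:5])
  rpkmFn <- function(b, g, s) 1
  em <- expressionMatrix(binGenes, catalog, rpkmFn, subMap)
  expect_equal(nrow(em), 2 * nrow(catTb))
  # absent genes are flagged not found with NA rpkm
  absent <- em[em$bin_id == "b2" & !em$present, ]
  expect_true(all(is.na(absent$rpkm)))
  # all-positive expression: encoded pathways are expressed
  b1 <- em[em$bin_id == "b1", ]
  expect_true(all(b1$encoded))
  expect_true(all(b1$expressed))
})

test_that("all-zero expression yields no expressed pathway", {
  subMap <- data.frame(aa = aminoAcids(catalog),
                       sample_id = paste0("S_", aminoAcids(catalog)))
  binGenes <- list(b1 = unique(catTb$gene_symbol))
  em <- expressionMatrix(binGenes, catalog, function(b, g, s) 0, subMap)
  expect_true(all(!em$expressed))
  expect_true(all(em$encoded))
})

test_that("missing substrate sample names the amino acid", {
  subMap <- data.frame(aa = "alanine", sample_id = "S1")
  expect_error(
    expressionMatrix(list(b1 = "ald"), catalog, function(b, g, s) 1,
                     subMap),
    "glycine")
})

test_that("expressed implies encoded, and summary respects it", {
  set.seed(37)
  subMap <- data.frame(aa = aminoAcids(catalog),
                       sample_id = paste0("S_", aminoAcids(catalog)))
  allSym <- unique(catTb$gene_symbol)
  for (i in 1:10) {
    binGenes <- list(bx = sample(allSym, sample.int(length(allSym), 1)))
    em <- expressionMatrix(binGenes, catalog,
                           function(b, g, s) sample(c(0, 0, 1, 5), 1),
                           subMap)
    expect_true(all(!em$expressed | em$encoded))
    ps <- pathwaySummary(em)
    expect_true(all(ps$expressed_aas <= ps$encoded_aas))
  }
})
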
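test_that("genome coverage is the length-weighted mean of contig depths", {
  one <- data.frame(contig_id = "c1", length = 1000, mean_depth = 7.5)
  expect_equal(genomeCoverage(one), 7.5)

  two <- data.frame(contig_id = c("c1", "c2"),
                    length = c(1000, 3000), mean_depth = c(10, 20))
  expect_equal(genomeCoverage(two), 17.5)  # (10000+60000)/4000
  expect_equal(genomeCoverage(two[2:1, ]), 17.5)  # order invariant

  expect_error(genomeCoverage(data.frame(contig_id = "c", length = 0,
                                         mean_depth = 1)), "zero total")
})

test_that("missing contigs are filled in at depth zero with a warning", {
  bc <- data.frame(contig_id = c("c1", "c2"), length = c(1000, 1000))
  d <- data.frame(contig_id = "c1", length = 1000, mean_depth = 10)
  expect_warning(v <- genomeCoverage(d, binContigs = bc), "missing")
  expect_equal(v, 5)
})

test_that("relative abundance normalizes by total coverage", {
  expect_equal(unname(relativeAbundance(c(b = 42))), 1)
  expect_equal(unname(relativeAbundance(c(a = 17.5, b = 7.5))),
               c(0.7, 0.3))
  expect_equal(unname(relativeAbundance(rep(3, 5))), rep(0.2, 5))
  expect_error(relativeAbundance(c(a = -1)), "negative")
  expect_warning(v <- relativeAbundance(c(a = 0, b = 0)), "zero")
  expect_true(all(is.na(v)))
})

test_that("relative abundance is scale invariant and sums to one", {
  set.seed(3)
  for (i in 1:10) {
    cov <- runif(8, 0.1, 50)
    f1 <- relativeAbundance(cov)
    expect_equal(sum(f1), 1, tolerance = 1e-9)
    expect_equal(relativeAbundance(cov * 17.3), f1)
  }
})

test_that("RPKM formula and scale invariance", {
  expect_equal(computeRPKM(0, 500, 1e6), 0)
  expect_equal(computeRPKM(10, 500, 1e6), 20)
  expect_equal(computeRPKM(20, 500, 2e6), computeRPKM(10, 500, 1e6))
  expect_error(computeRPKM(10, 500, 0), "positive")
  expect_error(computeRPKM(10, 0, 1e6), "> 0")
})

test_that("rpkmTable is zero exactly where counts are zero", {
  cnt <- data.frame(sample_id = rep(c("s1", "s2"), each = 3),
                    gene_id = rep(c("g1", "g2", "g3"), 2),
                    count = c(0, 10, 5, 2, 0, 8))
  lens <- c(g1 = 500, g2 = 1000, g3 = 2000)
  r <- rpkmTable(cnt, lens)
  expect_equal(r$rpkm == 0, r$count == 0)
  tm <- attr(r, "total_mapped")
  expect_equal(as.numeric(tm[c("s1", "s2")]), c(15, 10))
  # spot check: g2 in s1 -> 10 / 1 / (15/1e6)
  expect_equal(r$rpkm[r$sample_id == "s1" & r$gene_id == "g2"],
               10 / 1 / (15 / 1e6))
})

test_that("mapped fraction is percent of dataset reads", {
  expect_equal(mappedFraction(0, 1000), 0)
  expect_equal(mappedFraction(35, 1000), 3.5)
  expect_equal(mappedFraction(1000, 1000), 100)
  expect_error(mappedFraction(1001, 1000), "exceeds")
  expect_error(mappedFraction(1, 0), "> 0")
})

test_that("abundanceTable sums to one per sample on a small community", {
  bs <- GenomeBinSet(
    bins = data.frame(bin_id = c("a", "b"), completeness = 90,
                      contamination = 1),
    contigs = data.frame(bin_id = c("a", "a", "b"),
                         contig_id = c("c1", "c2", "c3"),
                         length = c(1000L, 3000L, 2000L)))
  depth <- data.frame(sample_id = "s1",
                      contig_id = c("c1", "c2", "c3"),
                      length = c(1000, 3000, 2000),
                      mean_depth = c(10, 20, 7.5))
  at <- abundanceTable(bs, depth)
  expect_equal(sum(at$relative_abundance), 1)
  expect_equal(at$coverage[at$bin_id == "a"], 17.5)
  expect_equal(at$relative_abundance[at$bin_id == "a"], 0.7)
})
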
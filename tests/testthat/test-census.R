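mkAssign <- function(gene, bin, kind, label) {
  data.frame(gene_id = gene, bin_id = bin, category_kind = kind,
             category_label = label, stringsAsFactors = FALSE)
}

test_that("adhesion census counts genes once, accessions separately", {
  a <- rbind(mkAssign(c("g1", "g2"), "b1", "adhesion", "PF01103"),
             mkAssign("g3", "b1", "adhesion", "PF02494"))
  r <- adhesionCensus(a, bins = c("b1", "b2"))
  expect_equal(r$total$count[r$total$bin_id == "b1"], 3)
  expect_equal(r$total$count[r$total$bin_id == "b2"], 0)

  # a gene carrying two listed accessions: once in the total,
  # once per accession in the breakdown
  dual <- rbind(mkAssign("g1", "b1", "adhesion", "PF01103"),
                mkAssign("g1", "b1", "adhesion", "PF02494"))
  r2 <- adhesionCensus(dual, bins = "b1")
  expect_equal(r2$total$count, 1)
  expect_equal(sum(r2$breakdown$count), 2)
})

test_that("peptidase type breakdown follows the family code first letter", {
  a <- mkAssign(paste0("g", 1:5), "b1", "peptidase",
                c("M16A", "S08A", "C01A", "S41B", "U99X"))
  r <- peptidaseCensus(a, bins = "b1")
  expect_equal(r$total$count, 5)
  bt <- setNames(r$by_type$count, r$by_type$type)
  expect_equal(as.integer(bt[c("M", "S", "C", "other")]),
               c(1L, 2L, 1L, 1L))
  expect_equal(sum(r$by_type$count), r$total$count)
})

test_that("secreted census requires both the assignment and a signal peptide", {
  a <- mkAssign(paste0("g", 1:5), "b1", "peptidase", "C01A")
  sig <- data.frame(gene_id = paste0("g", 1:5),
                    signal_peptide = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  r <- secretedCensus(a, sig, bins = "b1")
  pep <- r[r$category_kind == "peptidase", ]
  expect_equal(pep$count, 5L)
  expect_equal(pep$secreted, 3L)

  # no signal calls at all: every secreted count is zero
  none <- data.frame(gene_id = character(), signal_peptide = logical())
  expect_message(r0 <- secretedCensus(a, none, bins = "b1"), "absent")
  expect_true(all(r0$secreted == 0))
})

test_that("secreted counts never exceed category counts (random bins)", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    a <- mkAssign(paste0("g", 1:n), "b1",
                  sample(c("peptidase", "lipase", "cazyme"), n,
                         replace = TRUE), "X")
    sig <- data.frame(gene_id = paste0("g", 1:n),
                      signal_peptide = sample(c(TRUE, FALSE), n,
                                              replace = TRUE))
    r <- secretedCensus(a, sig, bins = "b1")
    expect_true(all(r$secreted <= r$count))
  }
})

test_that("census counts are invariant to assignment row order", {
  set.seed(31)
  a <- mkAssign(paste0("g", 1:20), sample(c("b1", "b2"), 20, TRUE),
                sample(c("peptidase", "adhesion"), 20, TRUE),
                sample(c("C01A", "PF01103"), 20, TRUE))
  a <- a[(a$category_kind == "adhesion") == (a$category_label == "PF01103"), ]
  sig <- data.frame(gene_id = paste0("g", 1:20),
                    signal_peptide = rep(c(TRUE, FALSE), 10))
  perm <- a[sample.int(nrow(a)), ]
  expect_equal(secretedCensus(a, sig, bins = c("b1", "b2")),
               secretedCensus(perm, sig, bins = c("b1", "b2")))
  expect_equal(adhesionCensus(a, bins = c("b1", "b2")),
               adhesionCensus(perm, bins = c("b1", "b2")))
})

test_that("highly expressed genes are those strictly above the bin median", {
  r <- highlyExpressed(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(r$median, 3)
  expect_equal(r$genes, c("d", "e"))
  expect_equal(unname(r$fold), c(4 / 3, 5 / 3))

  # constant vector: strict inequality selects nothing
  expect_equal(highlyExpressed(rep(2, 10))$genes, character(0))
  expect_error(highlyExpressed(numeric(0)), "empty")

  # all-zero bin: median 0 flagged, nothing selected
  z <- highlyExpressed(c(a = 0, b = 0))
  expect_true(z$median_zero)
  expect_equal(z$genes, character(0))

  # zero median with expressed genes: folds reported as Inf
  z2 <- highlyExpressed(c(a = 0, b = 0, c = 5))
  expect_true(z2$median_zero)
  expect_equal(unname(z2$fold), Inf)
})

test_that("highly expressed set is at most half the genes when distinct", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    v <- setNames(sample(seq_len(1000), n), paste0("g", 1:n))
    r <- highlyExpressed(v)
    expect_lt(length(r$genes), n)
    expect_lte(length(r$genes), floor(n / 2))
  }
})

test_that("electron marker census counts per marker label", {
  a <- mkAssign(paste0("g", 1:4), "b1", "electron_marker",
                c("Hyd", "Hyd", "Rnf", "Fdh"))
  r <- electronMarkerCensus(a, bins = "b1")
  m <- setNames(r$count, r$marker)
  expect_equal(as.integer(m[c("Hyd", "Rnf", "Fdh", "QFR", "NQR")]),
               c(2L, 1L, 1L, 0L, 0L))
})
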
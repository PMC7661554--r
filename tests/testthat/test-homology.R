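test_that("hit filter applies strict >50/>50 cutoffs", {
  h <- data.frame(query_id = c("a", "b", "c", "d"),
                  subject_id = "r",
                  identity = c(49.9, 50.1, 50, 80),
                  coverage = c(90, 50.1, 80, 50),
                  bitscore = 100)
  kept <- filterHits(h)
  expect_equal(kept$query_id, "b")  # strict on both axes
})

test_that("hit filter equals a brute-force row scan on random tables", {
  set.seed(42)
  for (rep in 1:3) {
    h <- randomHits(200)
    expect_equal(filterHits(h)$query_id, bruteFilterHits(h)$query_id)
    # and at non-default thresholds
    expect_equal(filterHits(h, 30, 70)$query_id,
                 bruteFilterHits(h, 30, 70)$query_id)
  }
})

test_that("hit filter is monotone in its thresholds", {
  set.seed(7)
  h <- randomHits(150)
  strictSet <- filterHits(h, 60, 60)$query_id
  looseSet <- filterHits(h, 40, 40)$query_id
  expect_true(all(strictSet %in% looseSet))
})

test_that("coverage filter is skipped with a warning when unavailable", {
  h <- data.frame(query_id = c("a", "b"), subject_id = "r",
                  identity = c(60, 40), coverage = NA_real_,
                  bitscore = 100)
  expect_warning(kept <- filterHits(h), "coverage unavailable")
  expect_equal(kept$query_id, "a")
})

test_that("best-hit resolution is deterministic with stated tie order", {
  one <- data.frame(query_id = "q", subject_id = "s", identity = 80,
                    bitscore = 100)
  expect_equal(resolveBestHits(one)$subject_id, "s")

  two <- data.frame(query_id = "q", subject_id = c("s1", "s2"),
                    identity = c(70, 90), bitscore = c(100, 90))
  expect_equal(resolveBestHits(two)$subject_id, "s1")

  tie <- data.frame(query_id = "q", subject_id = c("zz", "aa", "mm"),
                    identity = 80, bitscore = 100)
  expect_equal(resolveBestHits(tie)$subject_id, "aa")

  set.seed(99)
  h <- randomHits(200, nQueries = 50)
  got <- resolveBestHits(h)
  want <- bruteBestHits(h)
  expect_equal(got$subject_id, want$subject_id)
  expect_equal(got$query_id, want$query_id)
  # invariant to row order
  perm <- h[sample.int(nrow(h)), ]
  expect_equal(resolveBestHits(perm), got)
})

test_that("category assignment maps subjects and drops unmapped ones", {
  refMap <- data.frame(subject_id = c("pepRef", "adhRef"),
                       category_kind = c("peptidase", "adhesion"),
                       category_label = c("C01A", "PF01103"))
  h <- data.frame(query_id = c("g1", "g1", "g2"),
                  subject_id = c("pepRef", "adhRef", "mystery"),
                  identity = c(80, 70, 90), coverage = 90,
                  bitscore = c(200, 150, 100))
  expect_message(a <- assignCategories(h, refMap), "1 hit")
  # multi-domain gene: one assignment per kind
  expect_equal(nrow(a), 2)
  expect_setequal(a$category_kind, c("peptidase", "adhesion"))
  expect_equal(a$category_label[a$category_kind == "peptidase"], "C01A")
  expect_false("g2" %in% a$gene_id)
})

test_that("category assignment keeps one label per kind via best hit", {
  refMap <- data.frame(subject_id = c("r1", "r2"),
                       category_kind = "peptidase",
                       category_label = c("C01A", "S08A"))
  h <- data.frame(query_id = "g1", subject_id = c("r1", "r2"),
                  identity = c(60, 60), coverage = 90,
                  bitscore = c(100, 300))
  a <- assignCategories(h, refMap)
  expect_equal(nrow(a), 1)
  expect_equal(a$category_label, "S08A")
})

test_that("conflicting reference map labels raise an error", {
  refMap <- data.frame(subject_id = c("r", "r"),
                       category_kind = c("peptidase", "lipase"),
                       category_label = c("C01A", "abH01"))
  h <- data.frame(query_id = "g", subject_id = "r", identity = 60,
                  coverage = 90, bitscore = 100)
  expect_error(assignCategories(h, refMap), "conflicting")
})

test_that("assignment tallies match a brute-force count", {
  set.seed(5)
  for (rep in 1:5) {
    subjects <- paste0("s", 1:9)
    refMap <- data.frame(
      subject_id = subjects,
      category_kind = rep(c("peptidase", "lipase", "cazyme"), each = 3),
      category_label = paste0("L", 1:9))
    h <- randomHits(30, nQueries = 12, nSubjects = 9)
    h$subject_id <- sub("^s0?", "s", h$subject_id)
    a <- assignCategories(h, refMap)
    # oracle: per (query, kind) there must be exactly one assignment iff
    # the query has >=1 hit to a subject of that kind
    kindOf <- setNames(refMap$category_kind, refMap$subject_id)
    want <- unique(data.frame(q = h$query_id,
                              k = kindOf[h$subject_id]))
    expect_equal(nrow(a), nrow(want))
  }
})

test_that("AAI of a genome against itself is 100", {
  for (n in c(1, 5, 20)) {
    self <- data.frame(query_id = paste0("g", 1:n),
                       subject_id = paste0("g", 1:n),
                       identity = 100, coverage = 100, bitscore = 500)
    r <- computeAAI(self, self)
    expect_equal(r$aai, 100)
    expect_equal(r$n_orthologs, n)
  }
})

test_that("AAI is the mean of reciprocal-best-hit identities", {
  ab <- data.frame(query_id = c("a1", "a2"), subject_id = c("b1", "b2"),
                   identity = c(60, 70), coverage = 100, bitscore = 200)
  ba <- data.frame(query_id = c("b1", "b2"), subject_id = c("a1", "a2"),
                   identity = c(60, 70), coverage = 100, bitscore = 200)
  r <- computeAAI(ab, ba)
  expect_equal(r$aai, 65)
  expect_equal(r$n_orthologs, 2)
  expect_equal(computeAAI(data.frame(query_id = character(),
                                     subject_id = character(),
                                     identity = numeric(),
                                     coverage = numeric(),
                                     bitscore = numeric()), ba)$n_orthologs,
               0L)
})

test_that("AAI equals brute-force RBH enumeration and is symmetric", {
  set.seed(17)
  for (rep in 1:5) {
    ab <- randomHits(60, nQueries = 20, nSubjects = 20)
    ba <- randomHits(60, nQueries = 20, nSubjects = 20)
    got <- computeAAI(ab, ba)
    want <- bruteAAI(ab, ba)
    expect_equal(got$n_orthologs, want$n_orthologs)
    expect_equal(got$aai, want$aai)
    flipped <- computeAAI(ba, ab)
    expect_equal(flipped$aai, got$aai)
    expect_equal(flipped$n_orthologs, got$n_orthologs)
  }
})
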
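# Independent brute-force oracles and small generators shared across
# the suite. Deliberately naive implementations: explicit row loops,
# no shared code with the package internals they check.

bruteFilterHits <- function(hits, minId = 50, minCov = 50) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- hits$identity[i] > minId &&
      !is.na(hits$coverage[i]) && hits$coverage[i] > minCov
  }
  hits[keep, , drop = FALSE]
}

bruteBestHits <- function(hits) {
  out <- NULL
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    best <- h[1, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      better <- h$bitscore[i] > best$bitscore ||
        (h$bitscore[i] == best$bitscore &&
           h$identity[i] > best$identity) ||
        (h$bitscore[i] == best$bitscore &&
           h$identity[i] == best$identity &&
           h$subject_id[i] < best$subject_id)
      if (better) best <- h[i, , drop = FALSE]
    }
    out <- rbind(out, best)
  }
  rownames(out) <- NULL
  out
}

bruteAAI <- function(ab, ba, minId = 30, minCov = 70) {
  pass <- function(h) {
    ok <- h$identity >= minId
    if (!all(is.na(h$coverage))) ok <- ok & h$coverage >= minCov
    h[ok, , drop = FALSE]
  }
  ab <- pass(ab); ba <- pass(ba)
  bestOf <- function(h, q) {
    d <- h[h$query_id == q, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    bruteBestHits(d)
  }
  ids <- c()
  n <- 0L
  for (q in unique(ab$query_id)) {
    fa <- bestOf(ab, q)
    if (is.null(fa)) next
    fb <- bestOf(ba, fa$subject_id)
    if (is.null(fb)) next
    if (fb$subject_id == q) {
      ids <- c(ids, (fa$identity + fb$identity) / 2)
      n <- n + 1L
    }
  }
  if (n == 0L) list(aai = NA_real_, n_orthologs = 0L)
  else list(aai = mean(ids), n_orthologs = n)
}

bruteEncodedCount <- function(symbols, catTb) {
  encodedAA <- character(0)
  for (aa in unique(catTb$aa)) {
    sub <- catTb[catTb$aa == aa, , drop = FALSE]
    for (p in unique(sub$pathway_id)) {
      genes <- sub$gene_symbol[sub$pathway_id == p]
      if (all(genes %in% symbols)) {
        encodedAA <- union(encodedAA, aa)
        break
      }
    }
  }
  length(encodedAA)
}

randomHits <- function(n, nQueries = 20, nSubjects = 10) {
  data.frame(
    query_id = sprintf("q%02d", sample.int(nQueries, n, replace = TRUE)),
    subject_id = sprintf("s%02d", sample.int(nSubjects, n,
                                             replace = TRUE)),
    identity = round(runif(n, 0, 100), 1),
    coverage = round(runif(n, 0, 100), 1),
    bitscore = round(runif(n, 10, 500)),
    stringsAsFactors = FALSE)
}

# locate, by bisection, the switch point of a monotone boolean function
bisectBoundary <- function(pass, lo, hi, tol = 1e-6) {
  pLo <- pass(lo); pHi <- pass(hi)
  stopifnot(pLo != pHi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pass(mid) == pLo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
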
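## Homology-hit filtering, best-hit resolution, functional category
## assignment and genome-vs-genome average amino-acid identity (AAI).

#' Filter homology hits on identity and query coverage
#'
#' Retains exactly the hits with `identity > minIdentity` AND
#' `coverage > minCoverage` (both strict, matching the usual ">50%
#' similarity and >50% coverage" manual-curation rule). When the coverage
#' column is entirely `NA` (no query-length table was available at parse
#' time) the coverage filter is skipped with a warning rather than
#' silently passing or failing all hits.
#'
#' @param hits data.frame from [readHitsTable()] (needs `identity` and
#'   `coverage` columns).
#' @param minIdentity percent identity cutoff (exclusive), default 50.
#' @param minCoverage percent query-coverage cutoff (exclusive), default 50.
#' @return the retained rows, original order preserved.
#' @examples
#' h <- data.frame(query_id = c("a", "b"), subject_id = "r",
#'                 identity = c(49.9, 50.1), coverage = c(90, 50.1),
#'                 bitscore = c(100, 100))
#' filterHits(h)$query_id  # "b"
#' @export
filterHits <- function(hits, minIdentity = 50, minCoverage = 50) {
  stopifnot(is.data.frame(hits), "identity" %in% names(hits))
  if (!nrow(hits)) return(hits)
  keep <- hits$identity > minIdentity
  if (!"coverage" %in% names(hits) || all(is.na(hits$coverage))) {
    warning("coverage unavailable for all hits; ",
            "coverage filter skipped (identity-only filtering)")
  } else {
    keep <- keep & !is.na(hits$coverage) & hits$coverage > minCoverage
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## deterministic best-hit order: bitscore desc, identity desc,
## subject_id asc
bestHitOrder <- function(hits) {
  order(-hits$bitscore, -hits$identity, hits$subject_id)
}

#' Resolve one best hit per query
#'
#' For each query keeps the hit with the highest bit score; ties are
#' broken by higher identity, then by lexicographically smallest
#' subject id, so the result is deterministic regardless of input order.
#'
#' @param hits data.frame of (already filtered) hits with `query_id`,
#'   `subject_id`, `identity`, `bitscore`.
#' @return data.frame with one row per query, ordered by `query_id`.
#' @export
resolveBestHits <- function(hits) {
  stopifnot(all(c("query_id", "subject_id", "identity", "bitscore") %in%
                names(hits)))
  if (!nrow(hits)) return(hits)
  o <- bestHitOrder(hits)
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign functional categories to genes from their homology hits
#'
#' Joins filtered hits to a reference map (`subject_id` ->
#' `category_kind`, `category_label`) and resolves the best hit per
#' (query, category kind), so a multi-domain gene may hold one peptidase
#' label and one adhesion label simultaneously, but never two labels of
#' the same kind. Hits to subjects absent from the map are dropped and
#' their count reported via a message.
#'
#' @param hits data.frame of filtered hits.
#' @param referenceMap data.frame with `subject_id`, `category_kind`,
#'   `category_label` (see [readReferenceMap()]); duplicated subjects with
#'   conflicting labels raise an error.
#' @return data.frame with one row per (gene, kind): `gene_id`,
#'   `category_kind`, `category_label`, `source_subject`, `identity`,
#'   `bitscore`.
#' @export
assignCategories <- function(hits, referenceMap) {
  referenceMap <- validateReferenceMap(referenceMap)
  emptyOut <- data.frame(gene_id = character(),
                         category_kind = character(),
                         category_label = character(),
                         source_subject = character(),
                         identity = numeric(), bitscore = numeric(),
                         stringsAsFactors = FALSE)
  if (!nrow(hits)) return(emptyOut)
  idx <- match(hits$subject_id, referenceMap$subject_id)
  dropped <- sum(is.na(idx))
  if (dropped)
    message(dropped, " hit(s) to unmapped reference subjects dropped")
  keep <- !is.na(idx)
  if (!any(keep)) return(emptyOut)
  hits <- hits[keep, , drop = FALSE]
  idx <- idx[keep]
  hits$category_kind <- referenceMap$category_kind[idx]
  hits$category_label <- referenceMap$category_label[idx]
  # best hit per (query, kind), same deterministic tie rules
  o <- bestHitOrder(hits)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$query_id, hits$category_kind, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  out <- data.frame(gene_id = hits$query_id,
                    category_kind = hits$category_kind,
                    category_label = hits$category_label,
                    source_subject = hits$subject_id,
                    identity = hits$identity,
                    bitscore = hits$bitscore,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$category_kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average amino-acid identity (AAI) between two genomes
#'
#' Identifies reciprocal best hits (RBH) from the two directional hit
#' tables: gene `a` of genome A and gene `b` of genome B form an ortholog
#' pair when `b` is `a`'s best hit in A->B and `a` is `b`'s best hit in
#' B->A, with both directional hits passing the RBH identity/coverage
#' thresholds (inclusive; defaults 30% identity, 70% coverage — common
#' AAI-tool defaults, not derived from any single study). AAI is the
#' arithmetic mean of the per-pair identities, each pair's identity
#' averaged over its two directional hits so that the statistic is
#' symmetric in the two genomes.
#'
#' @param hitsAB data.frame of genome A queries vs genome B subjects.
#' @param hitsBA data.frame of genome B queries vs genome A subjects.
#' @param rbhMinIdentity minimum percent identity for a directional hit
#'   to enter RBH resolution (inclusive).
#' @param rbhMinCoverage minimum percent query coverage (inclusive);
#'   ignored when coverage is unavailable.
#' @return list with `aai` (percent, `NA` when no RBH exists), and
#'   `n_orthologs` (number of RBH pairs).
#' @examples
#' ab <- data.frame(query_id = c("a1", "a2"), subject_id = c("b1", "b2"),
#'                  identity = c(60, 70), coverage = 100,
#'                  bitscore = c(100, 100))
#' ba <- data.frame(query_id = c("b1", "b2"), subject_id = c("a1", "a2"),
#'                  identity = c(60, 70), coverage = 100,
#'                  bitscore = c(100, 100))
#' computeAAI(ab, ba)$aai  # 65
#' @export
computeAAI <- function(hitsAB, hitsBA, rbhMinIdentity = 30,
                       rbhMinCoverage = 70) {
  pass <- function(h) {
    if (!nrow(h)) return(h)
    keep <- h$identity >= rbhMinIdentity
    if ("coverage" %in% names(h) && !all(is.na(h$coverage)))
      keep <- keep & !is.na(h$coverage) & h$coverage >= rbhMinCoverage
    h[keep, , drop = FALSE]
  }
  bestAB <- resolveBestHits(pass(hitsAB))
  bestBA <- resolveBestHits(pass(hitsBA))
  if (!nrow(bestAB) || !nrow(bestBA))
    return(list(aai = NA_real_, n_orthologs = 0L))
  backPartner <- setNames(bestBA$subject_id, bestBA$query_id)
  partnerOfA <- bestAB$subject_id
  reciprocal <- !is.na(backPartner[partnerOfA]) &
    backPartner[partnerOfA] == bestAB$query_id
  rbh <- bestAB[reciprocal, , drop = FALSE]
  if (!nrow(rbh)) return(list(aai = NA_real_, n_orthologs = 0L))
  idBA <- setNames(bestBA$identity, bestBA$query_id)
  pairIdentity <- (rbh$identity + idBA[rbh$subject_id]) / 2
  list(aai = mean(pairIdentity), n_orthologs = nrow(rbh))
}
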
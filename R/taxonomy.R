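## Rank-level taxonomic novelty calls from 16S rRNA identity and AAI,
## and nearest-labeled-reference SusC cluster assignment.

#' Classify taxonomic novelty from 16S rRNA gene identity
#'
#' Applies rank-level identity thresholds: identity below the family
#' threshold (default 86.5%) calls a novel family or higher rank;
#' identity at or above the family threshold but below the genus
#' threshold (default 94.5%) calls a novel genus; identity at or above
#' the genus threshold places the query within a known genus. Identities
#' exactly equal to a threshold fall in the less-novel class (the
#' threshold framework leaves the boundary open; this choice is
#' configurable by nudging the thresholds).
#'
#' @param identity percent identity (0-100) of the query against its best
#'   reference; vectorized.
#' @param familyThreshold family-rank threshold, default 86.5.
#' @param genusThreshold genus-rank threshold, default 94.5; must exceed
#'   `familyThreshold`.
#' @return character vector over `{novel_family_or_higher, novel_genus,
#'   within_genus}`.
#' @examples
#' classify16S(c(79.2, 90, 100))
#' @export
classify16S <- function(identity, familyThreshold = 86.5,
                        genusThreshold = 94.5) {
  if (familyThreshold >= genusThreshold)
    stop("classify16S: familyThreshold must be < genusThreshold")
  if (any(identity < 0 | identity > 100, na.rm = TRUE))
    stop("classify16S: identity outside [0,100]")
  ifelse(identity < familyThreshold, "novel_family_or_higher",
         ifelse(identity < genusThreshold, "novel_genus",
                "within_genus"))
}

#' Classify family-level novelty from average amino-acid identity
#'
#' AAI below the family cutoff (default 60%, the commonly used
#' approximate boundary) calls a novel family; at or above it the query
#' is associated with a known family.
#'
#' @param aai percent AAI (0-100); vectorized.
#' @param familyCutoff cutoff, default 60.
#' @return character vector over `{novel_family, within_family}`.
#' @examples
#' classifyAAI(c(49.7, 57.6, 65))
#' @export
classifyAAI <- function(aai, familyCutoff = 60) {
  if (any(aai < 0 | aai > 100, na.rm = TRUE))
    stop("classifyAAI: AAI outside [0,100]")
  ifelse(aai < familyCutoff, "novel_family", "within_family")
}

#' Novelty calls for a query-vs-reference identity table
#'
#' For each query, finds its best reference (highest identity, ties by
#' lexicographically smallest reference id) and applies [classify16S()]
#' or [classifyAAI()].
#'
#' @param identityTable data.frame with `query_id`, `reference_id`,
#'   `identity`.
#' @param method `"16S"` or `"AAI"`.
#' @param ... thresholds passed to the classifier.
#' @return data.frame `query_id`, `best_reference_id`, `best_identity`,
#'   `rank_call`, `method`.
#' @export
noveltyCalls <- function(identityTable, method = c("16S", "AAI"), ...) {
  method <- match.arg(method)
  stopifnot(all(c("query_id", "reference_id", "identity") %in%
                names(identityTable)))
  o <- order(identityTable$query_id, -identityTable$identity,
             identityTable$reference_id)
  tb <- identityTable[o, , drop = FALSE]
  best <- tb[!duplicated(tb$query_id), , drop = FALSE]
  call <- if (method == "16S") classify16S(best$identity, ...)
          else classifyAAI(best$identity, ...)
  data.frame(query_id = best$query_id,
             best_reference_id = best$reference_id,
             best_identity = best$identity,
             rank_call = as.character(call),
             method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign a SusC gene to a substrate cluster by nearest labeled reference
#'
#' A deliberate simplification of phylogenetic SusC cluster placement:
#' the query inherits the cluster label (e.g. `polypeptide` vs `glucan`)
#' of its highest-identity labeled reference. Ties are broken by
#' lexicographically smallest reference id, so the call is deterministic
#' and invariant to reference table order.
#'
#' @param identities named numeric vector: percent identity of the query
#'   against each reference.
#' @param referenceLabels named character vector: cluster label of each
#'   reference.
#' @return list with `label`, `reference_id`, `identity`.
#' @examples
#' assignSusCCluster(c(refA = 62, refB = 40),
#'                   c(refA = "polypeptide", refB = "glucan"))
#' @export
assignSusCCluster <- function(identities, referenceLabels) {
  refs <- intersect(names(identities), names(referenceLabels))
  if (!length(refs))
    stop("assignSusCCluster: no labeled reference with an identity")
  refs <- refs[order(-identities[refs], refs)]
  best <- refs[1]
  list(label = unname(referenceLabels[best]),
       reference_id = best,
       identity = unname(identities[best]))
}
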
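#' Accessors for GenomeBinSet and PathwayCatalog
#'
#' `binInfo()`, `contigInfo()` and `geneInfo()` return the component tables
#' of a [GenomeBinSet-class]; `binIds()` and `nBins()` summarize it.
#' `catalogTable()` returns the gene-level table of a
#' [PathwayCatalog-class]; `aminoAcids()` and `pathwayIds()` list its
#' contents; `pathwayGenes()` returns the gene symbols of one pathway.
#'
#' @param x a `GenomeBinSet` or `PathwayCatalog`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binInfo", function(x) standardGeneric("binInfo"))
#' @rdname accessors
#' @export
setGeneric("contigInfo", function(x) standardGeneric("contigInfo"))
#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("binIds", function(x) standardGeneric("binIds"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname accessors
setMethod("binInfo", "GenomeBinSet", function(x) x@bins)
#' @rdname accessors
setMethod("contigInfo", "GenomeBinSet", function(x) x@contigs)
#' @rdname accessors
setMethod("geneInfo", "GenomeBinSet", function(x) x@genes)
#' @rdname accessors
setMethod("binIds", "GenomeBinSet", function(x) x@bins$bin_id)
#' @rdname accessors
setMethod("nBins", "GenomeBinSet", function(x) nrow(x@bins))

#' @rdname accessors
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))
#' @rdname accessors
#' @export
setGeneric("aminoAcids", function(x) standardGeneric("aminoAcids"))
#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname accessors
setMethod("catalogTable", "PathwayCatalog", function(x) x@table)
#' @rdname accessors
setMethod("aminoAcids", "PathwayCatalog",
          function(x) sort(unique(x@table$aa)))
#' @rdname accessors
setMethod("pathwayIds", "PathwayCatalog",
          function(x) unique(x@table$pathway_id))

#' @rdname accessors
#' @param catalog a `PathwayCatalog`.
#' @param pathwayId a single pathway id present in the catalog.
#' @export
pathwayGenes <- function(catalog, pathwayId) {
  stopifnot(is(catalog, "PathwayCatalog"))
  tb <- catalog@table
  g <- tb$gene_symbol[tb$pathway_id == pathwayId]
  if (!length(g)) stop("unknown pathway_id: ", pathwayId)
  g
}

#' Subset a GenomeBinSet to a set of bins
#'
#' Keeps the named bins with their contigs and genes; order of the
#' remaining bins is preserved.
#'
#' @param x a [GenomeBinSet-class].
#' @param keep character vector of bin ids to retain.
#' @return A `GenomeBinSet` restricted to `keep`.
#' @export
subsetBins <- function(x, keep) {
  stopifnot(is(x, "GenomeBinSet"))
  unknown <- setdiff(keep, x@bins$bin_id)
  if (length(unknown))
    stop("unknown bin_id(s): ", paste(unknown, collapse = ", "))
  GenomeBinSet(
    bins = x@bins[x@bins$bin_id %in% keep, , drop = FALSE],
    contigs = x@contigs[x@contigs$bin_id %in% keep, , drop = FALSE],
    genes = x@genes[x@genes$bin_id %in% keep, , drop = FALSE]
  )
}
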
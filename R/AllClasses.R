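#' @import methods
NULL

#' GenomeBinSet: a set of genome bins with contigs, genes and QC metrics
#'
#' Central container for a binned (meta)genome assembly. Holds one row per
#' bin (with CheckM-style completeness/contamination estimates), one row per
#' contig (with its length and parent bin), and one row per predicted gene
#' (with 1-based inclusive coordinates, GFF3 convention).
#'
#' @slot bins data.frame with columns `bin_id`, `completeness`,
#'   `contamination` (both percent, 0-100).
#' @slot contigs data.frame with columns `bin_id`, `contig_id`, `length`
#'   (bp, > 0).
#' @slot genes data.frame with columns `gene_id`, `bin_id`, `contig_id`,
#'   `start`, `end`, `strand`, `length` (bp; `length == end - start + 1`).
#'
#' @examples
#' bs <- GenomeBinSet(
#'   bins = data.frame(bin_id = "b1", completeness = 95, contamination = 1),
#'   contigs = data.frame(bin_id = "b1", contig_id = "c1", length = 50000L),
#'   genes = data.frame(gene_id = "g1", bin_id = "b1", contig_id = "c1",
#'                      start = 1L, end = 900L, strand = "+", length = 900L)
#' )
#' nBins(bs)
#' @export
setClass("GenomeBinSet",
  representation(
    bins = "data.frame",
    contigs = "data.frame",
    genes = "data.frame"
  )
)

setValidity("GenomeBinSet", function(object) {
  msg <- character()
  b <- object@bins; ct <- object@contigs; g <- object@genes
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("%s lacks column(s): %s", what,
                              paste(miss, collapse = ", "))
  }
  msg <- c(msg,
    need(b, c("bin_id", "completeness", "contamination"), "bins"),
    need(ct, c("bin_id", "contig_id", "length"), "contigs"),
    need(g, c("gene_id", "bin_id", "contig_id", "start", "end",
              "strand", "length"), "genes"))
  if (length(msg)) return(msg)
  if (anyDuplicated(b$bin_id))
    msg <- c(msg, "duplicated bin_id in bins")
  ok <- is.na(b$completeness) | (b$completeness >= 0 & b$completeness <= 100)
  if (!all(ok)) msg <- c(msg, "completeness outside [0,100]")
  ok <- is.na(b$contamination) | (b$contamination >= 0 & b$contamination <= 100)
  if (!all(ok)) msg <- c(msg, "contamination outside [0,100]")
  if (nrow(ct)) {
    if (any(ct$length <= 0)) msg <- c(msg, "contig lengths must be > 0")
    if (anyDuplicated(ct$contig_id)) msg <- c(msg, "duplicated contig_id")
    if (!all(ct$bin_id %in% b$bin_id))
      msg <- c(msg, "contig refers to unknown bin_id")
  }
  if (nrow(g)) {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicated gene_id")
    if (!all(g$bin_id %in% b$bin_id))
      msg <- c(msg, "gene refers to unknown bin_id")
    if (!all(g$start <= g$end)) msg <- c(msg, "gene start > end")
    if (!all(g$length == g$end - g$start + 1))
      msg <- c(msg, "gene length != end - start + 1")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBinSet
#'
#' @param bins data.frame of bin QC metrics (`bin_id`, `completeness`,
#'   `contamination`).
#' @param contigs data.frame of contigs (`bin_id`, `contig_id`, `length`).
#' @param genes data.frame of genes (`gene_id`, `bin_id`, `contig_id`,
#'   `start`, `end`, `strand`, `length`). Defaults to an empty table.
#' @return A [GenomeBinSet-class] object.
#' @export
GenomeBinSet <- function(bins, contigs,
                         genes = data.frame(gene_id = character(),
                                            bin_id = character(),
                                            contig_id = character(),
                                            start = integer(),
                                            end = integer(),
                                            strand = character(),
                                            length = integer())) {
  new("GenomeBinSet", bins = as.data.frame(bins),
      contigs = as.data.frame(contigs), genes = as.data.frame(genes))
}

#' PathwayCatalog: amino-acid catabolic routes as explicit gene lists
#'
#' One row per (amino acid, pathway, gene symbol). A pathway is the unit of
#' completeness: a bin encodes it only when every listed gene symbol is
#' present. Alternative pathways for the same amino acid are combined with
#' OR semantics downstream.
#'
#' @slot table data.frame with columns `aa`, `pathway_id`, `gene_symbol`,
#'   `ec_number`, `product`.
#' @export
setClass("PathwayCatalog", representation(table = "data.frame"))

setValidity("PathwayCatalog", function(object) {
  tb <- object@table
  msg <- character()
  need <- setdiff(c("aa", "pathway_id", "gene_symbol"), names(tb))
  if (length(need))
    return(sprintf("catalog lacks column(s): %s", paste(need, collapse = ", ")))
  if (nrow(tb) == 0) return("catalog is empty")
  if (any(is.na(tb$gene_symbol) | tb$gene_symbol == ""))
    msg <- c(msg, "empty gene_symbol in catalog")
  key <- paste(tb$aa, tb$pathway_id, tb$gene_symbol)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicated gene within a pathway")
  # one pathway_id must not span two amino acids
  pw <- unique(tb[, c("aa", "pathway_id")])
  if (anyDuplicated(pw$pathway_id))
    msg <- c(msg, "pathway_id used by more than one amino acid")
  if (length(msg)) msg else TRUE
})

#' CommunitySpec: parameters of a synthetic enrichment community
#'
#' Describes a mock single-amino-acid enrichment experiment with known
#' ground truth: per-bin planted relative abundances and functional gene
#' complements, per-sample substrate amino acid and sequencing depth, and
#' the count noise model.
#'
#' @slot binParams data.frame, one row per bin: `bin_id`, `guild`
#'   (`proteolytic`, `fermenter` or `other`), `abundance` (fractions summing
#'   to 1), `n_contigs`, `n_peptidase`, `n_secreted_peptidase`, `n_lipase`,
#'   `n_secreted_lipase`, `n_cazyme`, `n_secreted_cazyme`, `n_adhesion`,
#'   `n_susc`, `completeness`, `contamination`.
#' @slot pathwayPlan data.frame: `bin_id`, `aa`, `encoded` (logical),
#'   `expressed` (logical). Genes are planted at the symbol level to honour
#'   symbols shared between pathways; the serialized ground truth is derived
#'   from the planted symbol sets by direct catalog scan.
#' @slot samples data.frame: `sample_id`, `substrate_aa`, `depth` (mean
#'   community coverage, x).
#' @slot noise one of `"poisson"` (default), `"nbinom"`, `"none"`.
#' @slot nbSize numeric, negative-binomial size when `noise == "nbinom"`.
#' @slot exprRate numeric, expected reads per kb per unit coverage for an
#'   expressed gene.
#' @slot seed integer seed; a fixed seed makes the generated tables
#'   byte-identical across runs.
#' @export
setClass("CommunitySpec",
  representation(
    binParams = "data.frame",
    pathwayPlan = "data.frame",
    samples = "data.frame",
    noise = "character",
    nbSize = "numeric",
    exprRate = "numeric",
    seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character()
  bp <- object@binParams
  if (!all(c("bin_id", "guild", "abundance") %in% names(bp)))
    return("binParams must have bin_id, guild, abundance")
  if (abs(sum(bp$abundance) - 1) > 1e-8)
    msg <- c(msg, "planted abundances must sum to 1")
  if (any(bp$abundance < 0)) msg <- c(msg, "negative planted abundance")
  if (!object@noise %in% c("poisson", "nbinom", "none"))
    msg <- c(msg, "noise must be 'poisson', 'nbinom' or 'none'")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (!all(c("sample_id", "substrate_aa", "depth") %in%
           names(object@samples)))
    msg <- c(msg, "samples must have sample_id, substrate_aa, depth")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeBinSet", function(object) {
  cat(sprintf("GenomeBinSet: %d bin(s), %d contig(s), %d gene(s)\n",
              nrow(object@bins), nrow(object@contigs), nrow(object@genes)))
  if (nrow(object@bins)) {
    cat(sprintf("  completeness %.1f-%.1f%%, contamination %.1f-%.1f%%\n",
                min(object@bins$completeness), max(object@bins$completeness),
                min(object@bins$contamination),
                max(object@bins$contamination)))
  }
})

setMethod("show", "PathwayCatalog", function(object) {
  tb <- object@table
  cat(sprintf(
    "PathwayCatalog: %d amino acid(s), %d pathway(s), %d gene entries\n",
    length(unique(tb$aa)), length(unique(tb$pathway_id)), nrow(tb)))
})

setMethod("show", "CommunitySpec", function(object) {
  cat(sprintf(
    "CommunitySpec: %d bin(s), %d sample(s), noise=%s, seed=%d\n",
    nrow(object@binParams), nrow(object@samples), object@noise,
    object@seed))
})
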
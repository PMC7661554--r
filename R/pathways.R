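## Amino-acid catabolic pathway completeness and expression scoring.
## A pathway is complete only when every one of its genes is found in the
## bin; an amino acid counts as degradable when at least one of its
## alternative pathways is complete (OR semantics); a complete pathway is
## expressed when every one of its genes has RPKM above the expression
## threshold in the culture fed that amino acid.

#' Load an amino-acid pathway catalog
#'
#' Reads a TSV catalog (`aa`, `pathway_id`, `gene_symbol`, optionally
#' `ec_number`, `product`) into a validated [PathwayCatalog-class]. With
#' no argument, loads the catalog shipped with the package: a best-effort
#' reconstruction of literature-standard anaerobic catabolic routes for
#' all 20 proteinogenic amino acids (e.g. the single-gene alanine
#' dehydrogenase route, the six-gene glycine decarboxylating route, an
#' eight-gene lysine fermentation route, and three alternative threonine
#' routes). Users are expected to override it with their own curated
#' catalog where available.
#'
#' @param path catalog TSV; `NULL` (default) loads the shipped catalog.
#' @param strict passed to the TSV reader.
#' @return a [PathwayCatalog-class].
#' @examples
#' cat20 <- loadPathwayCatalog()
#' length(aminoAcids(cat20))  # 20
#' @export
loadPathwayCatalog <- function(path = NULL, strict = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "aa_pathway_catalog.tsv",
                        package = "AminoCensus", mustWork = TRUE)
  df <- readTsv(path, c("aa", "pathway_id", "gene_symbol"),
                c("character", "character", "character"),
                "pathway catalog", strict)
  full <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$ec_number <- if ("ec_number" %in% names(full))
    as.character(full$ec_number) else NA_character_
  df$product <- if ("product" %in% names(full))
    as.character(full$product) else NA_character_
  new("PathwayCatalog", table = df)
}

#' Is a pathway complete in a bin?
#'
#' @param binGenes character vector of pathway-gene symbols present in
#'   the bin.
#' @param genes character vector: the gene symbols of one pathway.
#' @return list with `complete` (logical) and `missing` (symbols absent
#'   from the bin).
#' @examples
#' isPathwayComplete(c("ald", "gcvH"), c("ald"))$complete  # TRUE
#' @export
isPathwayComplete <- function(binGenes, genes) {
  if (!length(genes)) stop("isPathwayComplete: empty pathway gene list")
  missing <- setdiff(genes, binGenes)
  list(complete = length(missing) == 0L, missing = missing)
}

#' Count amino acids with a complete degradation pathway
#'
#' An amino acid is encoded by a bin iff at least one of its catalog
#' pathways is complete.
#'
#' @param binGenes character vector of pathway-gene symbols present in
#'   the bin.
#' @param catalog a [PathwayCatalog-class].
#' @return list with `count` (0..number of catalog amino acids) and
#'   `detail`: data.frame `aa`, `pathway_id`, `complete`, `n_missing`,
#'   `encoded` (the per-amino-acid OR).
#' @export
encodedAACount <- function(binGenes, catalog) {
  stopifnot(is(catalog, "PathwayCatalog"))
  tb <- catalogTable(catalog)
  pw <- unique(tb[, c("aa", "pathway_id")])
  pw$complete <- FALSE
  pw$n_missing <- 0L
  for (i in seq_len(nrow(pw))) {
    genes <- tb$gene_symbol[tb$pathway_id == pw$pathway_id[i]]
    r <- isPathwayComplete(binGenes, genes)
    pw$complete[i] <- r$complete
    pw$n_missing[i] <- length(r$missing)
  }
  enc <- tapply(pw$complete, pw$aa, any)
  pw$encoded <- as.logical(enc[pw$aa])
  rownames(pw) <- NULL
  list(count = sum(enc), detail = pw)
}

#' Is a complete pathway expressed in its substrate culture?
#'
#' A pathway is expressed iff it is encoded AND every one of its genes
#' has RPKM strictly greater than `tau` in the sample fed that amino
#' acid. `tau` defaults to 0: any non-zero expression of every gene
#' counts.
#'
#' @param rpkm numeric vector: RPKM of each pathway gene in the substrate
#'   sample (`NA` treated as 0).
#' @param encoded logical: is the pathway complete in this bin?
#' @param tau expression threshold (exclusive), default 0.
#' @return list with `expressed` (logical) and `reason` (`"ok"`,
#'   `"not_encoded"` or `"gene_below_threshold"`).
#' @export
isPathwayExpressed <- function(rpkm, encoded, tau = 0) {
  if (!isTRUE(encoded))
    return(list(expressed = FALSE, reason = "not_encoded"))
  rpkm[is.na(rpkm)] <- 0
  if (all(rpkm > tau)) list(expressed = TRUE, reason = "ok")
  else list(expressed = FALSE, reason = "gene_below_threshold")
}

#' Per-gene expression matrix of all pathways in all bins
#'
#' The long-format table behind a pathway-expression heat map: one row
#' per (bin, amino acid, pathway, gene) with gene presence, RPKM in the
#' culture fed that amino acid, a display-normalized RPKM (each
#' (bin, pathway) block scaled by its maximum), and the pathway verdicts
#' (`encoded`, `expressed`). Genes absent from the bin are flagged
#' `not_found` with RPKM `NA`.
#'
#' @param binGeneSymbols named list: for each bin id, the character
#'   vector of pathway-gene symbols present in that bin.
#' @param catalog a [PathwayCatalog-class].
#' @param geneRpkm function(bin_id, gene_symbol, sample_id) -> RPKM, or a
#'   data.frame with columns `bin_id`, `gene_symbol`, `sample_id`,
#'   `rpkm`.
#' @param substrateMap data.frame `aa`, `sample_id`; amino acids without
#'   a sample raise an error naming the amino acid.
#' @param tau expression threshold, see [isPathwayExpressed()].
#' @return data.frame with columns `bin_id`, `aa`, `sample_id`,
#'   `pathway_id`, `gene_symbol`, `present`, `rpkm`, `norm_rpkm`,
#'   `encoded`, `expressed`.
#' @export
expressionMatrix <- function(binGeneSymbols, catalog, geneRpkm,
                             substrateMap, tau = 0) {
  stopifnot(is(catalog, "PathwayCatalog"))
  tb <- catalogTable(catalog)
  aas <- sort(unique(tb$aa))
  missingAA <- setdiff(aas, substrateMap$aa)
  if (length(missingAA))
    stop("no substrate sample for amino acid(s): ",
         paste(missingAA, collapse = ", "))
  sampleOf <- setNames(substrateMap$sample_id, substrateMap$aa)
  lookup <- if (is.data.frame(geneRpkm)) {
    key <- paste(geneRpkm$bin_id, geneRpkm$gene_symbol,
                 geneRpkm$sample_id, sep = "\r")
    val <- setNames(geneRpkm$rpkm, key)
    function(b, g, s) {
      v <- val[paste(b, g, s, sep = "\r")]
      if (is.na(v)) 0 else as.numeric(v)
    }
  } else geneRpkm
  rows <- list()
  for (b in names(binGeneSymbols)) {
    present <- binGeneSymbols[[b]]
    for (aa in aas) {
      s <- sampleOf[[aa]]
      sub <- tb[tb$aa == aa, , drop = FALSE]
      for (p in unique(sub$pathway_id)) {
        genes <- sub$gene_symbol[sub$pathway_id == p]
        isPresent <- genes %in% present
        enc <- all(isPresent)
        rp <- vapply(seq_along(genes), function(i) {
          if (!isPresent[i]) return(NA_real_)
          lookup(b, genes[i], s)
        }, numeric(1))
        exprVerdict <- isPathwayExpressed(rp, enc, tau)$expressed
        mx <- suppressWarnings(max(rp, na.rm = TRUE))
        norm <- if (is.finite(mx) && mx > 0) rp / mx else
          ifelse(is.na(rp), NA_real_, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          bin_id = b, aa = aa, sample_id = s, pathway_id = p,
          gene_symbol = genes, present = isPresent, rpkm = rp,
          norm_rpkm = norm, encoded = enc, expressed = exprVerdict,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-bin encoded and expressed amino-acid counts
#'
#' Summarizes an [expressionMatrix()] into the per-bin counts of amino
#' acids with at least one complete pathway (`encoded_aas`) and at least
#' one complete-and-expressed pathway (`expressed_aas`);
#' `expressed_aas <= encoded_aas` always.
#'
#' @param exprMat data.frame from [expressionMatrix()].
#' @return data.frame `bin_id`, `encoded_aas`, `expressed_aas`.
#' @export
pathwaySummary <- function(exprMat) {
  pw <- unique(exprMat[, c("bin_id", "aa", "pathway_id", "encoded",
                           "expressed")])
  agg <- function(col) {
    x <- tapply(pw[[col]], list(pw$bin_id, pw$aa), any)
    rowSums(x, na.rm = TRUE)
  }
  enc <- agg("encoded")
  expd <- agg("expressed")
  data.frame(bin_id = names(enc),
             encoded_aas = as.integer(enc),
             expressed_aas = as.integer(expd[names(enc)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
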
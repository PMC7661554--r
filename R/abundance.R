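## Coverage -> relative abundance, RPKM, and mapped-read prevalence.

#' Length-weighted genome coverage of one bin in one sample
#'
#' The coverage of a genome is the length-weighted mean of its contig
#' depths: `sum(depth_i * length_i) / sum(length_i)`. Contigs of the bin
#' absent from the depth table are treated as depth 0 with a warning.
#'
#' @param depths data.frame of this bin's contigs in one sample, columns
#'   `contig_id`, `length`, `mean_depth`.
#' @param binContigs optional data.frame of the bin's full contig
#'   complement (`contig_id`, `length`); when supplied, missing contigs
#'   are filled in at depth 0.
#' @return the genome coverage (x).
#' @examples
#' genomeCoverage(data.frame(contig_id = c("c1", "c2"),
#'                           length = c(1000, 3000),
#'                           mean_depth = c(10, 20)))  # 17.5
#' @export
genomeCoverage <- function(depths, binContigs = NULL) {
  stopifnot(all(c("length", "mean_depth") %in% names(depths)))
  if (!is.null(binContigs)) {
    missing <- setdiff(binContigs$contig_id, depths$contig_id)
    if (length(missing)) {
      warning(length(missing),
              " contig(s) of the bin missing from the depth table; ",
              "treated as depth 0")
      add <- binContigs[binContigs$contig_id %in% missing, , drop = FALSE]
      depths <- rbind(depths[, c("contig_id", "length", "mean_depth")],
                      data.frame(contig_id = add$contig_id,
                                 length = add$length, mean_depth = 0))
    }
  }
  totalLen <- sum(as.numeric(depths$length))
  if (totalLen <= 0) stop("genomeCoverage: zero total contig length")
  sum(as.numeric(depths$mean_depth) * as.numeric(depths$length)) / totalLen
}

#' Relative abundance of genomes in one sample
#'
#' Each genome's coverage divided by the total coverage of all genomes in
#' the sample. An all-zero sample yields `NA` for every bin with a
#' warning.
#'
#' @param coverages named numeric vector of genome coverages (>= 0),
#'   names are bin ids.
#' @return named numeric vector of fractions summing to 1 (or all `NA`).
#' @examples
#' relativeAbundance(c(bin1 = 17.5, bin2 = 7.5))  # 0.7 0.3
#' @export
relativeAbundance <- function(coverages) {
  if (any(coverages < 0, na.rm = TRUE))
    stop("relativeAbundance: negative coverage")
  total <- sum(coverages)
  if (!is.finite(total) || total == 0) {
    warning("total coverage is zero; relative abundances undefined")
    return(setNames(rep(NA_real_, length(coverages)), names(coverages)))
  }
  coverages / total
}

#' Per-sample abundance table for a GenomeBinSet
#'
#' Applies [genomeCoverage()] to every (sample, bin) and
#' [relativeAbundance()] within each sample.
#'
#' @param binSet a [GenomeBinSet-class] (QC-filtered).
#' @param depthTable data.frame from [readDepthTable()].
#' @return data.frame with `sample_id`, `bin_id`, `coverage`,
#'   `relative_abundance`.
#' @export
abundanceTable <- function(binSet, depthTable) {
  stopifnot(is(binSet, "GenomeBinSet"))
  contigs <- contigInfo(binSet)
  bins <- binIds(binSet)
  samples <- sort(unique(depthTable$sample_id))
  res <- do.call(rbind, lapply(samples, function(s) {
    ds <- depthTable[depthTable$sample_id == s, , drop = FALSE]
    cov <- vapply(bins, function(b) {
      bc <- contigs[contigs$bin_id == b, , drop = FALSE]
      db <- ds[ds$contig_id %in% bc$contig_id, , drop = FALSE]
      genomeCoverage(db, binContigs = bc)
    }, numeric(1))
    data.frame(sample_id = s, bin_id = bins, coverage = cov,
               relative_abundance = as.numeric(relativeAbundance(cov)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count / (gene_length/1000) / (total_mapped/1e6)`. Vectorized
#' over `count` and `geneLength`.
#'
#' @param count mapped read count(s) for the gene (>= 0).
#' @param geneLength gene length(s) in bp (> 0).
#' @param totalMapped total mapped reads in the sample (> 0) over the gene
#'   catalog of all retained bins.
#' @return RPKM value(s).
#' @examples
#' computeRPKM(10, 500, 1e6)  # 20
#' @export
computeRPKM <- function(count, geneLength, totalMapped) {
  if (length(totalMapped) != 1L || is.na(totalMapped) || totalMapped <= 0)
    stop("computeRPKM: totalMapped must be a single positive number")
  if (any(geneLength <= 0)) stop("computeRPKM: gene length must be > 0")
  if (any(count < 0)) stop("computeRPKM: negative count")
  count / (geneLength / 1000) / (totalMapped / 1e6)
}

#' Per-sample RPKM expression profiles
#'
#' Builds the per-gene RPKM table from raw counts. The per-sample library
#' size is the total count over all genes of the retained bins in that
#' sample.
#'
#' @param countTable data.frame from [readCountTable()] (`sample_id`,
#'   `gene_id`, `count`).
#' @param geneLengths named numeric vector of gene lengths in bp, or a
#'   data.frame with `gene_id`, `length`.
#' @return data.frame with `sample_id`, `gene_id`, `count`, `rpkm`, plus
#'   attribute `total_mapped` (named vector per sample).
#' @export
rpkmTable <- function(countTable, geneLengths) {
  if (is.data.frame(geneLengths))
    geneLengths <- setNames(geneLengths$length, geneLengths$gene_id)
  lens <- geneLengths[countTable$gene_id]
  if (anyNA(lens))
    stop("rpkmTable: missing gene length for ",
         countTable$gene_id[which(is.na(lens))[1]])
  totals <- tapply(countTable$count, countTable$sample_id, sum)
  out <- countTable
  tm <- as.numeric(totals[out$sample_id])
  if (any(tm <= 0))
    stop("rpkmTable: sample with zero total mapped reads: ",
         out$sample_id[which(tm <= 0)[1]])
  out$rpkm <- out$count / (as.numeric(lens) / 1000) / (tm / 1e6)
  attr(out, "total_mapped") <- totals
  out
}

#' Fraction of dataset reads mapped to a bin
#'
#' `100 * mapped / total`, the prevalence statistic used to screen public
#' metagenomes/metatranscriptomes for a population of interest.
#'
#' @param mapped reads mapped to the bin (0 <= mapped <= total).
#' @param total total reads in the dataset (> 0).
#' @return percent of reads mapped.
#' @examples
#' mappedFraction(35, 1000)  # 3.5
#' @export
mappedFraction <- function(mapped, total) {
  if (any(total <= 0)) stop("mappedFraction: total must be > 0")
  if (any(mapped < 0)) stop("mappedFraction: negative mapped count")
  if (any(mapped > total))
    stop("mappedFraction: mapped exceeds total")
  100 * mapped / total
}
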
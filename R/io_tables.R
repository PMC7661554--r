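## Readers and writers for every external table dialect the pipeline
## consumes, plus the bin quality filter. All readers take `strict`:
## strict mode errors on a malformed row (naming its line), lenient mode
## drops the row with a warning.

readTsv <- function(path, colNames, colClasses, what, strict = TRUE) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(colNames, names(df))
  if (length(miss))
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, colNames, drop = FALSE]
  for (i in seq_along(colNames)) {
    cl <- colClasses[i]
    if (cl == "numeric") {
      v <- suppressWarnings(as.numeric(df[[i]]))
      bad <- which(is.na(v) & !is.na(df[[i]]) & df[[i]] != "NA")
      if (length(bad)) {
        if (strict)
          stop(what, ": non-numeric value in column '", colNames[i],
               "' at line ", bad[1] + 1L)
        warning(what, ": dropped ", length(bad), " malformed row(s)")
        df <- df[-bad, , drop = FALSE]
        v <- v[-bad]
      }
      df[[i]] <- v
    } else if (cl == "integer") {
      df[[i]] <- as.integer(df[[i]])
    } else {
      df[[i]] <- as.character(df[[i]])
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a 12-column tabular homology hits file
#'
#' Parses the de facto 12-column tab-separated output of protein homology
#' searches (query, subject, identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, e-value, bit score; no header). Query
#' coverage is computed as `aln_length / query_length * 100` when a table
#' of query lengths is supplied; otherwise the `coverage` column is `NA`
#' and downstream coverage filtering is skipped with a warning.
#'
#' @param path path to the hits file.
#' @param queryLengths optional: either a named numeric vector of query
#'   lengths (same units as `aln_length`, i.e. residues for protein
#'   searches) or a data.frame with columns `query_id`, `length`.
#' @param strict logical; in strict mode (default) a malformed row raises
#'   an error naming its line number, in lenient mode it is dropped with a
#'   warning.
#' @return data.frame with the 12 standard columns, named `query_id`,
#'   `subject_id`, `identity`, `aln_length`, `mismatches`, `gaps`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`, plus
#'   `coverage` (percent of the query aligned, or `NA`).
#' @examples
#' f <- tempfile()
#' writeLines("g1\tref1\t97.3\t200\t5\t0\t1\t200\t1\t200\t1e-50\t380", f)
#' hits <- readHitsTable(f, queryLengths = c(g1 = 200))
#' hits$coverage  # 100
#' @export
readHitsTable <- function(path, queryLengths = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("hits table: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("query_id", "subject_id", "identity", "aln_length",
            "mismatches", "gaps", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  empty <- function() {
    df <- as.data.frame(setNames(
      c(list(character(), character()),
        replicate(10, numeric(), simplify = FALSE)), cols))
    df$coverage <- numeric()
    df
  }
  if (!length(lines)) return(empty())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad)) {
    if (strict)
      stop("hits table: expected 12 tab-separated columns, found ",
           nf[bad[1]], " at line ", bad[1])
    warning("hits table: dropped ", length(bad),
            " row(s) without 12 columns")
    parts <- parts[-bad]
    if (!length(parts)) return(empty())
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  for (i in 3:12) {
    v <- suppressWarnings(as.numeric(m[, i]))
    badNum <- which(is.na(v))
    if (length(badNum)) {
      if (strict)
        stop("hits table: non-numeric value in column ", i,
             " at line ", badNum[1])
      warning("hits table: dropped ", length(badNum),
              " row(s) with non-numeric fields")
      m <- m[-badNum, , drop = FALSE]
      df <- df[-badNum, , drop = FALSE]
      v <- v[-badNum]
    }
    df[[cols[i]]] <- v
  }
  badId <- which(df$identity < 0 | df$identity > 100)
  if (length(badId))
    stop("hits table: identity outside [0,100] at line ", badId[1])
  if (!is.null(queryLengths)) {
    if (is.data.frame(queryLengths))
      queryLengths <- setNames(queryLengths$length, queryLengths$query_id)
    qlen <- queryLengths[df$query_id]
    df$coverage <- as.numeric(df$aln_length) / as.numeric(qlen) * 100
  } else {
    df$coverage <- NA_real_
  }
  rownames(df) <- NULL
  df
}

#' Read a per-contig depth table
#'
#' Expects TSV columns `sample_id`, `contig_id`, `length`, `mean_depth`.
#' @inheritParams readHitsTable
#' @return data.frame with those columns; `mean_depth` must be >= 0.
#' @export
readDepthTable <- function(path, strict = TRUE) {
  df <- readTsv(path, c("sample_id", "contig_id", "length", "mean_depth"),
                c("character", "character", "numeric", "numeric"),
                "depth table", strict)
  if (any(df$mean_depth < 0, na.rm = TRUE))
    stop("depth table: negative mean_depth")
  df
}

#' Read a per-gene read count table
#'
#' Expects TSV columns `sample_id`, `gene_id`, `count`.
#' @inheritParams readHitsTable
#' @export
readCountTable <- function(path, strict = TRUE) {
  df <- readTsv(path, c("sample_id", "gene_id", "count"),
                c("character", "character", "numeric"),
                "count table", strict)
  if (any(df$count < 0, na.rm = TRUE))
    stop("count table: negative count")
  df
}

#' Read a signal-peptide call table
#'
#' Expects TSV columns `gene_id`, `call` with `call` in `{SP, OTHER}`
#' (the dialect of signal-peptide predictors: `SP` marks an N-terminal
#' secretion signal).
#' @inheritParams readHitsTable
#' @return data.frame with `gene_id`, `call`, and logical `signal_peptide`.
#' @export
readSignalTable <- function(path, strict = TRUE) {
  df <- readTsv(path, c("gene_id", "call"), c("character", "character"),
                "signal table", strict)
  bad <- which(!df$call %in% c("SP", "OTHER"))
  if (length(bad)) {
    if (strict)
      stop("signal table: call must be 'SP' or 'OTHER' at line ",
           bad[1] + 1L)
    warning("signal table: dropped ", length(bad), " invalid row(s)")
    df <- df[-bad, , drop = FALSE]
  }
  df$signal_peptide <- df$call == "SP"
  df
}

#' Read a bin QC table (completeness/contamination)
#'
#' Expects TSV columns `bin_id`, `completeness`, `contamination`
#' (percent, as estimated from single-copy marker genes).
#' @inheritParams readHitsTable
#' @export
readQCTable <- function(path, strict = TRUE) {
  df <- readTsv(path, c("bin_id", "completeness", "contamination"),
                c("character", "numeric", "numeric"), "QC table", strict)
  for (col in c("completeness", "contamination")) {
    bad <- which(df[[col]] < 0 | df[[col]] > 100)
    if (length(bad))
      stop("QC table: ", col, " outside [0,100] for bin ",
           df$bin_id[bad[1]])
  }
  df
}

#' Read a reference category map
#'
#' Maps reference subject ids to functional categories: TSV columns
#' `subject_id`, `category_kind` (one of peptidase, lipase, transporter,
#' cazyme, adhesion, pathway_gene, electron_marker) and `category_label`
#' (e.g. a MEROPS family code, Pfam accession or gene symbol).
#' @inheritParams readHitsTable
#' @export
readReferenceMap <- function(path, strict = TRUE) {
  df <- readTsv(path, c("subject_id", "category_kind", "category_label"),
                c("character", "character", "character"),
                "reference map", strict)
  validateReferenceMap(df)
}

validateReferenceMap <- function(df) {
  dup <- df[duplicated(df$subject_id) | duplicated(df$subject_id,
                                                    fromLast = TRUE), ]
  if (nrow(dup)) {
    conflict <- vapply(split(dup, dup$subject_id), function(d)
      nrow(unique(d[, c("category_kind", "category_label")])) > 1L,
      logical(1))
    if (any(conflict))
      stop("reference map: conflicting labels for subject(s): ",
           paste(names(conflict)[conflict], collapse = ", "))
  }
  unique(df)
}

#' Read a substrate map (amino acid -> sample)
#'
#' Expects TSV columns `aa`, `sample_id`: which enrichment sample was fed
#' which amino acid.
#' @inheritParams readHitsTable
#' @export
readSubstrateMap <- function(path, strict = TRUE) {
  readTsv(path, c("aa", "sample_id"), c("character", "character"),
          "substrate map", strict)
}

#' Read bin contig sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a contig
#' table usable in a [GenomeBinSet-class] (lengths taken from the
#' sequences).
#'
#' @param path FASTA file of one bin's contigs.
#' @param binId bin id to attach to every contig.
#' @return data.frame with `bin_id`, `contig_id`, `length`.
#' @export
readBinContigs <- function(path, binId) {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(bin_id = binId,
             contig_id = sub("\\s.*$", "", names(seqs)),
             length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

#' Read gene calls from GFF3
#'
#' Thin wrapper over [rtracklayer::import.gff3()]; keeps records of type
#' `CDS` (or `gene` when no CDS records exist) and returns the gene table
#' dialect of [GenomeBinSet-class] (1-based inclusive coordinates).
#'
#' @param path GFF3 file.
#' @param binId bin id to attach to every gene.
#' @return data.frame with `gene_id`, `bin_id`, `contig_id`, `start`,
#'   `end`, `strand`, `length`.
#' @export
readGeneAnnotations <- function(path, binId) {
  gr <- rtracklayer::import.gff3(path)
  keep <- as.character(gr$type) == "CDS"
  if (!any(keep)) keep <- as.character(gr$type) == "gene"
  gr <- gr[keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0(binId, "_g", seq_along(gr))
  data.frame(gene_id = ids,
             bin_id = binId,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Filter bins on completeness and contamination
#'
#' Retains exactly the bins with completeness strictly greater than
#' `minCompleteness` and contamination strictly less than
#' `maxContamination` (defaults 80 and 5, the conventional
#' high-quality-draft cutoffs). Strict inequalities mirror the usual
#' ">80% / <5%" phrasing. Order is preserved and the operation is
#' idempotent.
#'
#' @param x a [GenomeBinSet-class] or a QC data.frame with columns
#'   `bin_id`, `completeness`, `contamination`.
#' @param minCompleteness completeness cutoff (percent, exclusive).
#' @param maxContamination contamination cutoff (percent, exclusive).
#' @return object of the same class as `x`, restricted to passing bins.
#' @examples
#' qc <- data.frame(bin_id = c("a", "b"),
#'                  completeness = c(85, 80), contamination = c(3, 0))
#' qcFilterBins(qc)$bin_id  # "a": 80 fails the strict > 80 cutoff
#' @export
setGeneric("qcFilterBins",
  function(x, minCompleteness = 80, maxContamination = 5)
    standardGeneric("qcFilterBins"))

#' @rdname qcFilterBins
setMethod("qcFilterBins", "data.frame",
  function(x, minCompleteness = 80, maxContamination = 5) {
    need <- setdiff(c("bin_id", "completeness", "contamination"), names(x))
    if (length(need))
      stop("QC filter: missing column(s): ", paste(need, collapse = ", "))
    bad <- which(is.na(x$completeness) | is.na(x$contamination))
    if (length(bad))
      stop("QC filter: missing QC metric for bin ", x$bin_id[bad[1]])
    keep <- x$completeness > minCompleteness &
      x$contamination < maxContamination
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })

#' @rdname qcFilterBins
setMethod("qcFilterBins", "GenomeBinSet",
  function(x, minCompleteness = 80, maxContamination = 5) {
    keep <- qcFilterBins(x@bins, minCompleteness, maxContamination)
    subsetBins(x, keep$bin_id)
  })

#' Write result tables as TSV with a manifest
#'
#' Writes every table in `tables` (a named list of data.frames) to
#' `<outDir>/<name>.tsv` with a header row, tab separation and a
#' deterministic column order (the order of the data.frame), and returns
#' a manifest of files and row counts.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory, created if needed.
#' @return data.frame manifest with columns `name`, `file`, `n_rows`.
#' @export
writeReportTables <- function(tables, outDir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outDir))
      stop("cannot create output directory: ", outDir)
  }
  files <- file.path(outDir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) {
    utils::write.table(tables[[i]], files[i], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  data.frame(name = names(tables), file = files,
             n_rows = vapply(tables, nrow, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Re-read a TSV written by writeReportTables
#'
#' Value-identical round-trip companion of [writeReportTables()].
#' @param path TSV file.
#' @export
readReportTable <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
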
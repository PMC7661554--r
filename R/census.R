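## Per-bin functional census: adhesion domains, peptidase totals and
## catalytic-type breakdown, secreted enzymes (signal-peptide bearing),
## SusC transporters, electron-transfer markers, and expression-based
## "highly expressed" calls.

#' Default Pfam accessions counted as surface-adhesion domains
#'
#' Bac_surface_Ag (PF01103), F5_F8_type_C discoidin (PF00754), HYR
#' (PF02494) and fasciclin (PF02496).
#' @export
adhesionAccessions <- function() c("PF01103", "PF00754", "PF02494",
                                   "PF02496")

#' Default electron-transfer marker labels
#'
#' Hydrogenase (Hyd), formate dehydrogenase (Fdh), Rnf-type
#' NADH:ferredoxin oxidoreductase (Rnf), quinol:fumarate oxidoreductase
#' (QFR) and NADH:quinone oxidoreductase (NQR).
#' @export
electronMarkerLabels <- function() c("Hyd", "Fdh", "Rnf", "QFR", "NQR")

## attach bin_id to assignments via the gene table
addBinIds <- function(assignments, genes) {
  if ("bin_id" %in% names(assignments)) return(assignments)
  idx <- match(assignments$gene_id, genes$gene_id)
  if (anyNA(idx))
    stop("assignment for unknown gene_id: ",
         assignments$gene_id[which(is.na(idx))[1]])
  assignments$bin_id <- genes$bin_id[idx]
  assignments
}

countByBin <- function(df, bins) {
  n <- table(factor(df$bin_id, levels = bins))
  data.frame(bin_id = bins, count = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Census of surface-adhesion genes per bin
#'
#' Counts genes (not domains) carrying at least one of the listed
#' adhesion-domain accessions; a gene matching two accessions is counted
#' once in the total but appears under each accession in the breakdown.
#'
#' @param assignments data.frame from [assignCategories()] with a
#'   `bin_id` column (see [censusReport()] for the join).
#' @param bins character vector of bin ids to report (zeros included).
#' @param accessions adhesion accessions to count;
#'   default [adhesionAccessions()].
#' @return list with `total` (data.frame `bin_id`, `count`) and
#'   `breakdown` (data.frame `bin_id`, `accession`, `count`).
#' @export
adhesionCensus <- function(assignments, bins,
                           accessions = adhesionAccessions()) {
  a <- assignments[assignments$category_kind == "adhesion" &
                   assignments$category_label %in% accessions, ,
                   drop = FALSE]
  genesOnce <- a[!duplicated(paste(a$bin_id, a$gene_id)), , drop = FALSE]
  total <- countByBin(genesOnce, bins)
  breakdown <- as.data.frame(
    table(bin_id = factor(a$bin_id, levels = bins),
          accession = factor(a$category_label, levels = accessions)),
    stringsAsFactors = FALSE)
  names(breakdown)[3] <- "count"
  breakdown$count <- as.integer(breakdown$count)
  list(total = total, breakdown = breakdown)
}

#' Peptidase counts and catalytic-type breakdown per bin
#'
#' Total peptidase genes per bin, plus a breakdown by catalytic type
#' derived from the first letter of the MEROPS-style family code
#' (M metallo, S serine, C cysteine, A aspartic, T threonine, anything
#' else pooled as `other`).
#'
#' @inheritParams adhesionCensus
#' @return list with `total` and `by_type` (data.frame `bin_id`, `type`,
#'   `count`); types sum to the total within each bin.
#' @export
peptidaseCensus <- function(assignments, bins) {
  p <- assignments[assignments$category_kind == "peptidase", ,
                   drop = FALSE]
  total <- countByBin(p, bins)
  lead <- toupper(substr(p$category_label, 1, 1))
  type <- ifelse(lead %in% c("M", "S", "C", "A", "T"), lead, "other")
  byType <- as.data.frame(
    table(bin_id = factor(p$bin_id, levels = bins),
          type = factor(type, levels = c("M", "S", "C", "A", "T",
                                         "other"))),
    stringsAsFactors = FALSE)
  names(byType)[3] <- "count"
  byType$count <- as.integer(byType$count)
  list(total = total, by_type = byType)
}

#' Secreted-enzyme census per bin
#'
#' A gene is a secreted enzyme of kind X (peptidase, lipase, cazyme) iff
#' it holds a category assignment of kind X AND carries a signal peptide.
#' Genes with an assignment but absent from the signal table are treated
#' as lacking a signal peptide; their number is reported via a message.
#'
#' @inheritParams adhesionCensus
#' @param signalCalls data.frame from [readSignalTable()] (`gene_id`,
#'   `signal_peptide`).
#' @param kinds enzyme kinds to report.
#' @return data.frame with `bin_id`, `category_kind`, `count`
#'   (all genes of that kind) and `secreted` (signal-peptide bearing);
#'   `secreted <= count` always.
#' @export
secretedCensus <- function(assignments, signalCalls, bins,
                           kinds = c("peptidase", "lipase", "cazyme")) {
  a <- assignments[assignments$category_kind %in% kinds, , drop = FALSE]
  sp <- setNames(signalCalls$signal_peptide, signalCalls$gene_id)
  flag <- sp[a$gene_id]
  nMissing <- sum(is.na(flag))
  if (nMissing)
    message(nMissing, " annotated gene(s) absent from the signal table; ",
            "treated as non-secreted")
  flag[is.na(flag)] <- FALSE
  grid <- expand.grid(bin_id = bins, category_kind = kinds,
                      stringsAsFactors = FALSE)
  key <- paste(a$bin_id, a$category_kind)
  gkey <- paste(grid$bin_id, grid$category_kind)
  grid$count <- as.integer(table(factor(key, levels = gkey)))
  grid$secreted <- as.integer(
    tapply(flag, factor(key, levels = gkey), sum, default = 0))
  grid
}

#' Electron-transfer marker census per bin
#'
#' Counts genes assigned to the `electron_marker` kind, per marker label.
#'
#' @inheritParams adhesionCensus
#' @param markers marker labels to report;
#'   default [electronMarkerLabels()].
#' @return data.frame with `bin_id`, `marker`, `count`.
#' @export
electronMarkerCensus <- function(assignments, bins,
                                 markers = electronMarkerLabels()) {
  e <- assignments[assignments$category_kind == "electron_marker", ,
                   drop = FALSE]
  out <- as.data.frame(
    table(bin_id = factor(e$bin_id, levels = bins),
          marker = factor(e$category_label, levels = markers)),
    stringsAsFactors = FALSE)
  names(out)[3] <- "count"
  out$count <- as.integer(out$count)
  out
}

#' Genes expressed above the bin median
#'
#' Given the RPKM of every gene of one bin in one sample, computes the
#' median over ALL genes (zeros included) and returns the genes with
#' RPKM strictly greater than that median, with their fold-over-median.
#' When the median is 0 the folds of the selected genes are reported as
#' `Inf` and flagged.
#'
#' @param rpkm named numeric vector: RPKM of every gene of the bin in one
#'   sample.
#' @return list with `median`, `genes` (character), `fold` (named numeric,
#'   RPKM/median for the selected genes) and `median_zero` (logical flag).
#' @examples
#' highlyExpressed(c(a = 1, b = 2, c = 3, d = 4, e = 5))$genes  # d, e
#' @export
highlyExpressed <- function(rpkm) {
  if (!length(rpkm)) stop("highlyExpressed: empty gene set")
  if (is.null(names(rpkm)))
    names(rpkm) <- as.character(seq_along(rpkm))
  med <- stats::median(rpkm)
  sel <- rpkm > med
  genes <- names(rpkm)[sel]
  fold <- if (med > 0) rpkm[sel] / med else
    setNames(rep(Inf, sum(sel)), genes)
  list(median = med, genes = genes, fold = fold, median_zero = med == 0)
}

#' Full per-bin functional census
#'
#' Combines [adhesionCensus()], [peptidaseCensus()], [secretedCensus()],
#' SusC transporter counts (transporter assignments whose label begins
#' with `SusC`), glycoside hydrolases (cazyme labels beginning `GH`),
#' [electronMarkerCensus()] and, when an expression table is supplied,
#' per-sample highly-expressed counts per enzyme category
#' ([highlyExpressed()] against the whole-bin median).
#'
#' @param binSet a QC-filtered [GenomeBinSet-class]; genes of bins not in
#'   it are excluded from every census.
#' @param assignments data.frame from [assignCategories()].
#' @param signalCalls data.frame from [readSignalTable()].
#' @param expression optional data.frame from [rpkmTable()].
#' @return named list of data.frames: `summary` (one row per bin),
#'   `peptidase_types`, `adhesion_breakdown`, `electron_markers`,
#'   and `highly_expressed` (per bin, sample and category; empty when no
#'   expression table was given).
#' @export
censusReport <- function(binSet, assignments, signalCalls,
                         expression = NULL) {
  stopifnot(is(binSet, "GenomeBinSet"))
  genes <- geneInfo(binSet)
  bins <- binIds(binSet)
  assignments <- addBinIds(
    assignments[assignments$gene_id %in% genes$gene_id, , drop = FALSE],
    genes)
  adh <- adhesionCensus(assignments, bins)
  pep <- peptidaseCensus(assignments, bins)
  sec <- secretedCensus(assignments, signalCalls, bins)
  elec <- electronMarkerCensus(assignments, bins)
  isSusc <- assignments$category_kind == "transporter" &
    grepl("^susc", assignments$category_label, ignore.case = TRUE)
  susc <- countByBin(assignments[isSusc, , drop = FALSE], bins)
  isGH <- assignments$category_kind == "cazyme" &
    grepl("^GH", assignments$category_label)
  gh <- countByBin(assignments[isGH, , drop = FALSE], bins)
  pick <- function(df, kind, col) {
    v <- df[df$category_kind == kind, , drop = FALSE]
    setNames(v[[col]], v$bin_id)[bins]
  }
  summary <- data.frame(
    bin_id = bins,
    adhesion_genes = adh$total$count,
    peptidase_total = pep$total$count,
    secreted_peptidases = as.integer(pick(sec, "peptidase", "secreted")),
    lipases = as.integer(pick(sec, "lipase", "count")),
    secreted_lipases = as.integer(pick(sec, "lipase", "secreted")),
    cazymes = as.integer(pick(sec, "cazyme", "count")),
    secreted_cazymes = as.integer(pick(sec, "cazyme", "secreted")),
    glycoside_hydrolases = gh$count,
    susC_genes = susc$count,
    row.names = NULL, stringsAsFactors = FALSE)

  he <- data.frame(bin_id = character(), sample_id = character(),
                   category_kind = character(), n_highly_expressed =
                     integer(), stringsAsFactors = FALSE)
  if (!is.null(expression) && nrow(expression)) {
    sp <- setNames(signalCalls$signal_peptide, signalCalls$gene_id)
    secretedOf <- function(kind) {
      a <- assignments[assignments$category_kind == kind, , drop = FALSE]
      flag <- sp[a$gene_id]
      flag[is.na(flag)] <- FALSE
      split(a$gene_id[flag], a$bin_id[flag])
    }
    secSets <- lapply(c(peptidase = "peptidase", lipase = "lipase",
                        cazyme = "cazyme"), secretedOf)
    samples <- sort(unique(expression$sample_id))
    rows <- list()
    for (s in samples) {
      es <- expression[expression$sample_id == s, , drop = FALSE]
      rpkmAll <- setNames(es$rpkm, es$gene_id)
      for (b in bins) {
        gb <- genes$gene_id[genes$bin_id == b]
        v <- rpkmAll[gb]
        v[is.na(v)] <- 0
        names(v) <- gb
        if (!length(v)) next
        hx <- highlyExpressed(v)
        for (kind in names(secSets)) {
          setG <- secSets[[kind]][[b]]
          rows[[length(rows) + 1L]] <- data.frame(
            bin_id = b, sample_id = s,
            category_kind = paste0("secreted_", kind),
            n_highly_expressed =
              length(intersect(hx$genes, setG)),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) he <- do.call(rbind, rows)
  }
  list(summary = summary, peptidase_types = pep$by_type,
       adhesion_breakdown = adh$breakdown, electron_markers = elec,
       highly_expressed = he)
}
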
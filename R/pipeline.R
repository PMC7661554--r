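## End-to-end orchestration: QC filter -> homology filtering and
## category assignment -> abundance + census -> pathway scoring ->
## novelty calls, from in-memory tables or a YAML config of file paths.
## Every threshold lives in the config/arguments with the conventional
## defaults; the manifest records the values actually used.

#' Default pipeline thresholds
#'
#' All cutoffs used anywhere in the pipeline, overridable individually:
#' homology identity/coverage (50/50, strict), bin QC completeness/
#' contamination (80/5, strict), pathway expression threshold `tau` (0),
#' 16S family/genus thresholds (86.5/94.5), AAI family cutoff (60), and
#' the AAI reciprocal-best-hit thresholds (30/70, inclusive).
#' @export
defaultThresholds <- function() {
  list(min_identity = 50, min_coverage = 50,
       min_completeness = 80, max_contamination = 5,
       tau = 0,
       family_16s = 86.5, genus_16s = 94.5,
       aai_family = 60,
       rbh_min_identity = 30, rbh_min_coverage = 70)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: bin QC filtering; homology hit filtering and
#' per-(gene, kind) category assignment; abundance estimation and the
#' functional census; amino-acid pathway completeness/expression
#' scoring; 16S/AAI novelty calls and SusC cluster assignment (when
#' identity tables are present). Stage validation errors abort with the
#' stage name. Identical inputs and thresholds give identical outputs.
#'
#' @param tables named list of input tables in the readers' dialects,
#'   as produced by [generateCommunity()]`$tables` or assembled from the
#'   reader functions: `qc`, `contigs`, `genes`, `hits`,
#'   `query_lengths`, `reference_map`, `signal`, `depth`, `counts`,
#'   `substrate_map`, and optionally `identity_16s`, `identity_aai`,
#'   `susc_identities`, `susc_reference_labels`.
#' @param catalog a [PathwayCatalog-class]; default the shipped catalog.
#' @param thresholds list as [defaultThresholds()]; partial overrides
#'   are merged over the defaults.
#' @param outDir optional; when given all result tables are written as
#'   TSV via [writeReportTables()] plus a `manifest.yaml` echoing the
#'   thresholds.
#' @return list with `bin_set` (retained bins), `abundance`, `census`,
#'   `expression_matrix`, `pathway_summary`, `assignments`,
#'   `novelty_16s`, `novelty_aai`, `susc_clusters`, `manifest`.
#' @export
runPipeline <- function(tables, catalog = loadPathwayCatalog(),
                        thresholds = list(), outDir = NULL) {
  th <- utils::modifyList(defaultThresholds(), thresholds)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  need <- setdiff(c("qc", "contigs", "genes", "hits", "reference_map",
                    "signal", "depth", "counts", "substrate_map"),
                  names(tables))
  if (length(need))
    stop("missing input table(s): ", paste(need, collapse = ", "))

  ## io: assemble and QC-filter the bin set
  binSet <- stage("io", {
    bs <- GenomeBinSet(tables$qc, tables$contigs, tables$genes)
    qcFilterBins(bs, th$min_completeness, th$max_contamination)
  })
  genes <- geneInfo(binSet)

  ## homology
  assignments <- stage("homology", {
    hits <- tables$hits
    if (!"coverage" %in% names(hits) || all(is.na(hits$coverage))) {
      if (!is.null(tables$query_lengths)) {
        ql <- setNames(tables$query_lengths$length,
                       tables$query_lengths$query_id)
        hits$coverage <- hits$aln_length / ql[hits$query_id] * 100
      }
    }
    f <- filterHits(hits, th$min_identity, th$min_coverage)
    a <- assignCategories(f, tables$reference_map)
    a <- a[a$gene_id %in% genes$gene_id, , drop = FALSE]
    addBinIds(a, genes)
  })

  ## abundance + expression
  abundance <- stage("abundance",
                     abundanceTable(binSet, tables$depth))
  signal <- tables$signal
  if (!"signal_peptide" %in% names(signal))
    signal$signal_peptide <- signal$call == "SP"
  expression <- stage("abundance", {
    cnt <- tables$counts[tables$counts$gene_id %in% genes$gene_id, ,
                         drop = FALSE]
    rpkmTable(cnt, setNames(genes$length, genes$gene_id))
  })

  ## census
  census <- stage("census",
                  censusReport(binSet, assignments, signal, expression))

  ## pathway scoring
  pw <- stage("pathway_scoring", {
    pa <- assignments[assignments$category_kind == "pathway_gene", ,
                      drop = FALSE]
    binGeneSymbols <- lapply(
      setNames(binIds(binSet), binIds(binSet)),
      function(b) unique(pa$category_label[pa$bin_id == b]))
    ## per (bin, symbol, sample) RPKM: max over gene copies
    rp <- merge(pa[, c("gene_id", "bin_id", "category_label")],
                expression[, c("gene_id", "sample_id", "rpkm")],
                by = "gene_id")
    key <- paste(rp$bin_id, rp$category_label, rp$sample_id, sep = "\r")
    agg <- tapply(rp$rpkm, key, max)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    geneRpkm <- data.frame(bin_id = parts[, 1],
                           gene_symbol = parts[, 2],
                           sample_id = parts[, 3],
                           rpkm = as.numeric(agg),
                           stringsAsFactors = FALSE)
    em <- expressionMatrix(binGeneSymbols, catalog, geneRpkm,
                           tables$substrate_map, tau = th$tau)
    list(matrix = em, summary = pathwaySummary(em))
  })

  ## taxonomy / novelty
  nov <- stage("taxonomy_novelty", {
    out <- list(nov16 = NULL, novAAI = NULL, susc = NULL)
    if (!is.null(tables$identity_16s) && nrow(tables$identity_16s))
      out$nov16 <- noveltyCalls(tables$identity_16s, "16S",
                                familyThreshold = th$family_16s,
                                genusThreshold = th$genus_16s)
    if (!is.null(tables$identity_aai) && nrow(tables$identity_aai))
      out$novAAI <- noveltyCalls(tables$identity_aai, "AAI",
                                 familyCutoff = th$aai_family)
    if (!is.null(tables$susc_identities) &&
        nrow(tables$susc_identities)) {
      labs <- setNames(tables$susc_reference_labels$cluster_label,
                       tables$susc_reference_labels$reference_id)
      qs <- unique(tables$susc_identities$query_id)
      out$susc <- do.call(rbind, lapply(qs, function(q) {
        d <- tables$susc_identities[
          tables$susc_identities$query_id == q, , drop = FALSE]
        r <- assignSusCCluster(setNames(d$identity, d$reference_id),
                               labs)
        data.frame(query_id = q, cluster_label = r$label,
                   reference_id = r$reference_id,
                   identity = r$identity, stringsAsFactors = FALSE)
      }))
    }
    out
  })
  nov16 <- nov$nov16
  novAAI <- nov$novAAI
  suscClusters <- nov$susc

  manifest <- list(thresholds = th,
                   n_bins_in = nrow(tables$qc),
                   n_bins_retained = nBins(binSet),
                   package_version =
                     as.character(utils::packageVersion("AminoCensus")))
  out <- list(bin_set = binSet, abundance = abundance, census = census,
              expression_matrix = pw$matrix,
              pathway_summary = pw$summary,
              assignments = assignments,
              novelty_16s = nov16, novelty_aai = novAAI,
              susc_clusters = suscClusters, manifest = manifest)

  if (!is.null(outDir)) {
    tabs <- list(abundance = abundance,
                 census_summary = census$summary,
                 census_peptidase_types = census$peptidase_types,
                 census_highly_expressed = census$highly_expressed,
                 expression_matrix = pw$matrix,
                 pathway_summary = pw$summary,
                 assignments = assignments)
    if (!is.null(nov16)) tabs$novelty_16s <- nov16
    if (!is.null(novAAI)) tabs$novelty_aai <- novAAI
    if (!is.null(suscClusters)) tabs$susc_clusters <- suscClusters
    mf <- writeReportTables(tabs, outDir)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    out$files <- mf
  }
  out
}

#' Run the pipeline from a YAML config of file paths
#'
#' The config maps each input table to a path (`qc`, `contigs`, `genes`,
#' `hits`, `query_lengths`, `reference_map`, `signal`, `depth`,
#' `counts`, `substrate_map`, optional identity tables), plus optional
#' `catalog`, `thresholds` (partial overrides) and `out_dir`. All paths
#' are validated before any stage runs.
#'
#' @param configPath YAML file.
#' @param strict parse mode passed to every reader.
#' @return see [runPipeline()].
#' @export
runPipelineFromConfig <- function(configPath, strict = TRUE) {
  cfg <- yaml::read_yaml(configPath)
  pathKeys <- intersect(
    c("qc", "contigs", "genes", "hits", "query_lengths",
      "reference_map", "signal", "depth", "counts", "substrate_map",
      "identity_16s", "identity_aai", "susc_identities",
      "susc_reference_labels"), names(cfg))
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  paths <- lapply(cfg[pathKeys], resolve)
  missing <- pathKeys[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("config: missing input file(s) for: ",
         paste(missing, collapse = ", "))
  readPlain <- function(p) utils::read.delim(p, sep = "\t",
                                             stringsAsFactors = FALSE)
  tables <- list()
  for (k in pathKeys) {
    tables[[k]] <- switch(k,
      qc = readQCTable(paths[[k]], strict),
      depth = readDepthTable(paths[[k]], strict),
      counts = readCountTable(paths[[k]], strict),
      signal = readSignalTable(paths[[k]], strict),
      reference_map = readReferenceMap(paths[[k]], strict),
      substrate_map = readSubstrateMap(paths[[k]], strict),
      hits = NULL,  # needs query lengths, handled below
      readPlain(paths[[k]]))
  }
  ql <- tables$query_lengths
  tables$hits <- readHitsTable(paths$hits,
                               queryLengths = ql, strict = strict)
  catalog <- if (!is.null(cfg$catalog))
    loadPathwayCatalog(resolve(cfg$catalog)) else loadPathwayCatalog()
  runPipeline(tables, catalog = catalog,
              thresholds = if (is.null(cfg$thresholds)) list() else
                cfg$thresholds,
              outDir = cfg$out_dir)
}
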
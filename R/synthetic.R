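## Seeded generator of a mock single-amino-acid enrichment community
## with planted ground truth. Emits exactly the table dialects the
## readers consume, so every pipeline stage is testable without any
## external data. Gene sequences are not generated: homology hit tables
## are synthesized directly (alignment itself is outside the package's
## scope).

#' Construct a CommunitySpec
#'
#' Low-level constructor; most users want [emulateStudyDesign()].
#'
#' @param binParams data.frame of per-bin parameters; see
#'   [CommunitySpec-class].
#' @param pathwayPlan data.frame `bin_id`, `aa`, `encoded`, `expressed`.
#' @param samples data.frame `sample_id`, `substrate_aa`, `depth`.
#' @param noise `"poisson"` (default), `"nbinom"` or `"none"`.
#' @param nbSize negative-binomial size parameter (only for `"nbinom"`).
#' @param exprRate expected reads per kb per unit coverage for a
#'   baseline-expressed gene.
#' @param seed integer seed.
#' @return a validated [CommunitySpec-class].
#' @export
communitySpec <- function(binParams, pathwayPlan, samples,
                          noise = "poisson", nbSize = 10,
                          exprRate = 50, seed = 1L) {
  new("CommunitySpec", binParams = as.data.frame(binParams),
      pathwayPlan = as.data.frame(pathwayPlan),
      samples = as.data.frame(samples), noise = noise,
      nbSize = nbSize, exprRate = exprRate, seed = as.integer(seed))
}

## default per-guild bin parameter rows
guildDefaults <- function(guild) {
  switch(guild,
    proteolytic = list(n_peptidase = 120L, n_secreted_peptidase = 70L,
                       n_lipase = 10L, n_secreted_lipase = 6L,
                       n_cazyme = 45L, n_secreted_cazyme = 20L,
                       n_adhesion = 6L, n_susc = 5L,
                       n_electron = 8L),
    fermenter = list(n_peptidase = 25L, n_secreted_peptidase = 10L,
                     n_lipase = 4L, n_secreted_lipase = 1L,
                     n_cazyme = 10L, n_secreted_cazyme = 3L,
                     n_adhesion = 1L, n_susc = 0L,
                     n_electron = 6L),
    other = list(n_peptidase = 10L, n_secreted_peptidase = 2L,
                 n_lipase = 2L, n_secreted_lipase = 0L,
                 n_cazyme = 8L, n_secreted_cazyme = 2L,
                 n_adhesion = 0L, n_susc = 0L,
                 n_electron = 4L))
}

## amino acids whose pathways a bin of each guild fails to encode /
## express. Chosen once as the design of the default mock experiment:
## the dominant proteolytic guild encodes 16-17 of 20 amino acids and
## expresses most of them; the minority fermenter guild encodes many but
## expresses few; background bins encode and express little.
defaultPathwayPlan <- function(binIds, guilds, aas) {
  notEncoded <- list(
    proteolytic = list(
      c("threonine", "tryptophan", "methionine", "histidine"),
      c("lysine", "proline", "tyrosine"),
      c("lysine", "proline", "phenylalanine")),
    fermenter = list(
      c("glycine", "threonine", "lysine", "histidine", "tryptophan",
        "tyrosine", "valine"),
      c("lysine", "proline", "cysteine", "serine")),
    other = list(
      c("glycine", "threonine", "lysine", "histidine", "tryptophan",
        "tyrosine", "valine", "phenylalanine", "proline", "methionine",
        "isoleucine", "leucine")))
  ## fraction of encoded amino acids also expressed, per guild
  exprKeep <- c(proteolytic = 1.0, fermenter = 0.3, other = 0.25)
  silent <- list(  # encoded-but-not-expressed picks, cycled per bin
    proteolytic = list(character(0),
                       c("glutamine", "serine", "histidine",
                         "tryptophan", "methionine", "cysteine"),
                       character(0)),
    fermenter = list(c("alanine", "arginine", "asparagine", "glutamate",
                       "glutamine", "isoleucine", "leucine",
                       "methionine"),
                     c("alanine", "glycine", "threonine", "glutamine",
                       "glutamate", "histidine", "isoleucine", "leucine",
                       "methionine", "phenylalanine", "tryptophan",
                       "tyrosine", "valine", "asparagine")),
    other = list(c("alanine", "arginine", "asparagine", "aspartate",
                   "glutamine", "serine")))
  counter <- list(proteolytic = 0L, fermenter = 0L, other = 0L)
  rows <- list()
  for (i in seq_along(binIds)) {
    g <- guilds[i]
    counter[[g]] <- counter[[g]] + 1L
    pickFrom <- notEncoded[[g]]
    ne <- pickFrom[[(counter[[g]] - 1L) %% length(pickFrom) + 1L]]
    sil <- silent[[g]][[(counter[[g]] - 1L) %% length(silent[[g]]) + 1L]]
    enc <- !aas %in% ne
    expd <- enc & !aas %in% sil
    rows[[i]] <- data.frame(bin_id = binIds[i], aa = aas,
                            encoded = enc, expressed = expd,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default mock-enrichment community specification
#'
#' Builds a [CommunitySpec-class] mirroring the contrast of a
#' single-amino-acid enrichment experiment: 20 substrate samples (one
#' per proteinogenic amino acid), a dominant proteolytic guild (high
#' planted abundance, many secreted peptidases, most amino-acid pathways
#' complete and expressed) and a minority amino-acid-fermenter guild
#' (few secreted peptidases, few pathways expressed), plus background
#' bins. Two QC-failing bins (low completeness / high contamination)
#' are included so the bin quality filter is exercised end-to-end.
#'
#' @param nBins number of QC-passing bins (>= 6); 3 are proteolytic,
#'   2 fermenters, the rest background.
#' @param depth mean community sequencing depth per sample (x coverage).
#' @param noise count noise model: `"poisson"` (default), `"nbinom"`,
#'   `"none"`.
#' @param seed integer seed.
#' @param catalog [PathwayCatalog-class] the planted inventories refer
#'   to; default the shipped catalog.
#' @return a [CommunitySpec-class].
#' @examples
#' spec <- emulateStudyDesign(seed = 7)
#' nrow(spec@samples)  # 20 substrate samples
#' @export
emulateStudyDesign <- function(nBins = 10, depth = 20,
                               noise = "poisson", seed = 1L,
                               catalog = loadPathwayCatalog()) {
  stopifnot(nBins >= 6)
  aas <- aminoAcids(catalog)
  nOther <- nBins - 5L
  binIds <- c(paste0("bin", 1:3), paste0("ferm", 1:2),
              paste0("bg", seq_len(nOther)))
  guilds <- c(rep("proteolytic", 3), rep("fermenter", 2),
              rep("other", nOther))
  ## dominant proteolytic guild vs a marginal cultured-fermenter guild;
  ## the background bins absorb the rest of the community
  abundance <- c(0.091, 0.026, 0.202, 0.003, 0.002,
                 rep(0.676 / nOther, nOther))
  ## per-bin functional complements of the three proteolytic bins and
  ## the two fermenter bins (many secreted peptidases and adhesion
  ## genes vs few)
  override <- list(
    bin1 = list(n_peptidase = 172L, n_secreted_peptidase = 72L,
                n_lipase = 3L, n_secreted_lipase = 2L,
                n_cazyme = 26L, n_secreted_cazyme = 10L,
                n_adhesion = 3L, n_susc = 3L),
    bin2 = list(n_peptidase = 109L, n_secreted_peptidase = 55L,
                n_lipase = 12L, n_secreted_lipase = 6L,
                n_cazyme = 60L, n_secreted_cazyme = 25L,
                n_adhesion = 6L, n_susc = 8L),
    bin3 = list(n_peptidase = 100L, n_secreted_peptidase = 68L,
                n_lipase = 12L, n_secreted_lipase = 6L,
                n_cazyme = 48L, n_secreted_cazyme = 20L,
                n_adhesion = 7L, n_susc = 5L),
    ferm1 = list(n_secreted_peptidase = 12L, n_adhesion = 1L),
    ferm2 = list(n_secreted_peptidase = 8L, n_adhesion = 0L))
  bp <- do.call(rbind, lapply(seq_along(binIds), function(i) {
    d <- guildDefaults(guilds[i])
    ov <- override[[binIds[i]]]
    if (!is.null(ov)) d[names(ov)] <- ov
    data.frame(bin_id = binIds[i], guild = guilds[i],
               abundance = abundance[i], n_contigs = 4L,
               qc_pass = TRUE, as.data.frame(d),
               stringsAsFactors = FALSE)
  }))
  ## QC-failing bins: abundance 0, excluded downstream
  fail <- do.call(rbind, lapply(1:2, function(i) {
    d <- guildDefaults("other")
    data.frame(bin_id = paste0("qcfail", i), guild = "other",
               abundance = 0, n_contigs = 2L, qc_pass = FALSE,
               as.data.frame(d), stringsAsFactors = FALSE)
  }))
  bp <- rbind(bp, fail)
  plan <- defaultPathwayPlan(bp$bin_id, bp$guild, aas)
  samples <- data.frame(sample_id = paste0("S_", aas),
                        substrate_aa = aas, depth = depth,
                        stringsAsFactors = FALSE)
  communitySpec(bp, plan, samples, noise = noise, seed = seed)
}

## MEROPS-style peptidase family pool; first letter = catalytic type
merposFamilies <- c("M16A", "S08A", "C01A", "M24B", "S41B", "M23B",
                    "S01C", "C25A", "M28A", "S09X", "A01A", "T01A")
lipaseFamilies <- c("abH01", "abH04", "abH08", "abH15")
cazymeFamilies <- c("GH13", "GH23", "GH2", "GH3", "GH18", "GT2", "CE4")

drawCount <- function(n, lambda, noise, nbSize) {
  switch(noise,
    none = round(lambda),
    poisson = stats::rpois(n, lambda),
    nbinom = stats::rnbinom(n, mu = lambda, size = nbSize))
}

## choose, per non-encoded amino acid, one gene per pathway to remove
## from a bin, preferring genes not used by any pathway of an encoded
## amino acid (symbols are shared across pathways)
plannedSymbols <- function(plan, catTb) {
  allSym <- unique(catTb$gene_symbol)
  encodedAAs <- plan$aa[plan$encoded]
  protectedSym <- unique(catTb$gene_symbol[catTb$aa %in% encodedAAs])
  drop <- character(0)
  for (aa in plan$aa[!plan$encoded]) {
    sub <- catTb[catTb$aa == aa, , drop = FALSE]
    for (p in unique(sub$pathway_id)) {
      genes <- sub$gene_symbol[sub$pathway_id == p]
      cand <- setdiff(genes, protectedSym)
      if (length(cand)) drop <- c(drop, cand[1])
      ## no removable gene: pathway stays complete (collateral
      ## completeness); ground truth is derived by scan afterwards
    }
  }
  setdiff(allSym, drop)
}

#' Generate a synthetic community dataset with ground truth
#'
#' Produces, in memory (and optionally on disk in exactly the file
#' dialects the readers consume), every input table of the pipeline:
#' bin QC, contigs, genes, 12-column homology hits plus query lengths,
#' the reference category map, signal-peptide calls, per-sample contig
#' depth and per-gene count tables, the substrate map, and 16S/AAI/SusC
#' identity tables — together with the planted ground truth. Contig
#' depths are drawn with mean proportional to planted abundance times
#' sample depth; gene counts with mean proportional to bin coverage,
#' gene length and the planted expression state; hit identities are
#' drawn above the 50% homology filter for planted genes and below it
#' for decoys. A fixed seed makes all outputs byte-identical.
#'
#' @param spec a [CommunitySpec-class].
#' @param catalog [PathwayCatalog-class]; default the shipped catalog.
#' @param outDir optional directory; when given, all tables are written
#'   (hits headerless 12-column, everything else TSV with header, truth
#'   as YAML).
#' @return list with `tables` (named list of data.frames), `truth`
#'   (planted abundances, per-bin encoded/expressed amino-acid sets
#'   derived from the planted gene complements by direct catalog scan,
#'   census counts, per-gene expression states) and `spec`.
#' @export
generateCommunity <- function(spec, catalog = loadPathwayCatalog(),
                              outDir = NULL) {
  stopifnot(is(spec, "CommunitySpec"))
  set.seed(spec@seed)
  bp <- spec@binParams
  samples <- spec@samples
  catTb <- catalogTable(catalog)
  aas <- aminoAcids(catalog)
  noise <- spec@noise

  ## failing bins alternate between failing on contamination only and
  ## on completeness only, so each QC cutoff is exercised independently
  failMode <- cumsum(!bp$qc_pass) %% 2L  # 1,0,1,... over failing bins
  qc <- data.frame(
    bin_id = bp$bin_id,
    completeness = round(ifelse(bp$qc_pass | failMode == 1L,
                                stats::runif(nrow(bp), 85, 99),
                                stats::runif(nrow(bp), 40, 75)), 1),
    contamination = round(ifelse(bp$qc_pass | failMode == 0L,
                                 stats::runif(nrow(bp), 0, 4),
                                 stats::runif(nrow(bp), 6, 15)), 1),
    stringsAsFactors = FALSE)

  ## --- genes ------------------------------------------------------
  geneRows <- list()
  refRows <- list()
  addRef <- function(subject, kind, label)
    refRows[[length(refRows) + 1L]] <<- data.frame(
      subject_id = subject, category_kind = kind, category_label = label,
      stringsAsFactors = FALSE)
  ## pathway-gene references: one subject per symbol
  for (s in unique(catTb$gene_symbol))
    addRef(paste0("ref_pw_", s), "pathway_gene", s)
  for (f in merposFamilies) addRef(paste0("ref_pep_", f), "peptidase", f)
  for (f in lipaseFamilies) addRef(paste0("ref_lip_", f), "lipase", f)
  for (f in cazymeFamilies) addRef(paste0("ref_caz_", f), "cazyme", f)
  for (f in adhesionAccessions()) addRef(paste0("ref_adh_", f),
                                         "adhesion", f)
  addRef("ref_susc_poly", "transporter", "SusC_polypeptide")
  addRef("ref_susc_glucan", "transporter", "SusC_glucan")
  for (f in electronMarkerLabels()) addRef(paste0("ref_el_", f),
                                           "electron_marker", f)

  presentSymbols <- list()
  removedSymbols <- list()
  for (b in bp$bin_id) {
    plan <- spec@pathwayPlan[spec@pathwayPlan$bin_id == b, , drop = FALSE]
    sym <- plannedSymbols(plan, catTb)
    presentSymbols[[b]] <- sym
    removedSymbols[[b]] <- setdiff(unique(catTb$gene_symbol), sym)
  }

  geneLenPool <- c(900L, 1200L, 1500L)
  for (i in seq_len(nrow(bp))) {
    b <- bp$bin_id[i]
    sym <- presentSymbols[[b]]
    n <- length(sym)
    mk <- function(role, label, kind, secreted) {
      k <- length(label)
      if (!k) return(NULL)
      data.frame(bin_id = b, role = role, label = label, kind = kind,
                 secreted = secreted,
                 length = sample(geneLenPool, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    rep_fam <- function(pool, k) pool[(seq_len(k) - 1L) %% length(pool) + 1L]
    secFlags <- function(k, nSec) seq_len(k) <= nSec
    geneRows[[length(geneRows) + 1L]] <- rbind(
      mk("pathway", sym, "pathway_gene", FALSE),
      mk("peptidase", rep_fam(merposFamilies, bp$n_peptidase[i]),
         "peptidase", secFlags(bp$n_peptidase[i],
                               bp$n_secreted_peptidase[i])),
      mk("lipase", rep_fam(lipaseFamilies, bp$n_lipase[i]), "lipase",
         secFlags(bp$n_lipase[i], bp$n_secreted_lipase[i])),
      mk("cazyme", rep_fam(cazymeFamilies, bp$n_cazyme[i]), "cazyme",
         secFlags(bp$n_cazyme[i], bp$n_secreted_cazyme[i])),
      mk("adhesion",
         rep_fam(if (bp$guild[i] == "fermenter") "PF02496" else
                   c("PF01103", "PF00754", "PF02494"),
                 bp$n_adhesion[i]),
         "adhesion", FALSE),
      mk("susc", rep("SusC_polypeptide", bp$n_susc[i]), "transporter",
         FALSE),
      mk("electron", rep_fam(electronMarkerLabels(), bp$n_electron[i]),
         "electron_marker", FALSE),
      mk("housekeeping", rep("HK", 30L), "none", FALSE),
      ## decoy ORFs: one per removed pathway symbol, hit below the
      ## homology filter so filtering decides completeness correctly
      mk("decoy", removedSymbols[[b]], "decoy", FALSE)
    )
  }
  gm <- do.call(rbind, geneRows)
  gm$gene_id <- paste0(gm$bin_id, "_g", stats::ave(
    seq_len(nrow(gm)), gm$bin_id, FUN = seq_along))

  ## place genes on contigs (round robin, sequential coordinates)
  contigRows <- list()
  gm$contig_id <- NA_character_
  gm$start <- NA_integer_
  for (i in seq_len(nrow(bp))) {
    b <- bp$bin_id[i]
    idx <- which(gm$bin_id == b)
    nc <- bp$n_contigs[i]
    cid <- paste0(b, "_c", seq_len(nc))
    assignment <- rep(seq_len(nc), length.out = length(idx))
    starts <- integer(length(idx))
    ends <- integer(length(idx))
    for (j in seq_len(nc)) {
      on <- idx[assignment == j]
      lens <- gm$length[on]
      ends[assignment == j] <- cumsum(lens + 200L)
      starts[assignment == j] <- ends[assignment == j] - lens + 1L
    }
    gm$contig_id[idx] <- cid[assignment]
    gm$start[idx] <- starts
    contigLen <- vapply(seq_len(nc), function(j) {
      e <- ends[assignment == j]
      max(e, 0L) + round(stats::runif(1, 500, 2000))
    }, numeric(1))
    contigRows[[i]] <- data.frame(bin_id = b, contig_id = cid,
                                  length = as.integer(contigLen),
                                  stringsAsFactors = FALSE)
  }
  contigs <- do.call(rbind, contigRows)
  genes <- data.frame(gene_id = gm$gene_id, bin_id = gm$bin_id,
                      contig_id = gm$contig_id, start = gm$start,
                      end = gm$start + gm$length - 1L, strand =
                        sample(c("+", "-"), nrow(gm), replace = TRUE),
                      length = gm$length, stringsAsFactors = FALSE)

  ## --- hits -------------------------------------------------------
  annotated <- gm$role != "housekeeping"
  qlenAll <- setNames(round(gm$length / 3), gm$gene_id)  # residues
  hitRow <- function(gid, subject, identity, covFrac, bitscore) {
    qlen <- qlenAll[[gid]]
    aln <- max(1, round(qlen * covFrac))
    data.frame(query_id = gid, subject_id = subject,
               identity = round(identity, 1), aln_length = aln,
               mismatches = round(aln * (1 - identity / 100)),
               gaps = 0L, qstart = 1L, qend = aln, sstart = 1L,
               send = aln, evalue = 1e-30, bitscore = round(bitscore, 1),
               stringsAsFactors = FALSE)
  }
  ag <- gm[annotated, , drop = FALSE]
  isDecoy <- ag$role == "decoy"
  subj <- character(nrow(ag))
  subj[ag$role == "pathway"] <- paste0("ref_pw_", ag$label[ag$role == "pathway"])
  subj[ag$role == "peptidase"] <- paste0("ref_pep_", ag$label[ag$role == "peptidase"])
  subj[ag$role == "lipase"] <- paste0("ref_lip_", ag$label[ag$role == "lipase"])
  subj[ag$role == "cazyme"] <- paste0("ref_caz_", ag$label[ag$role == "cazyme"])
  subj[ag$role == "adhesion"] <- paste0("ref_adh_", ag$label[ag$role == "adhesion"])
  subj[ag$role == "susc"] <- "ref_susc_poly"
  subj[ag$role == "electron"] <- paste0("ref_el_", ag$label[ag$role == "electron"])
  subj[isDecoy] <- paste0("ref_pw_", ag$label[isDecoy])
  identity <- ifelse(isDecoy, stats::runif(nrow(ag), 25, 45),
                     stats::runif(nrow(ag), 60, 95))
  covFrac <- ifelse(isDecoy, stats::runif(nrow(ag), 0.3, 0.45),
                    stats::runif(nrow(ag), 0.8, 1.0))
  bits <- stats::runif(nrow(ag), 150, 400)
  hits <- do.call(rbind, lapply(seq_len(nrow(ag)), function(k)
    hitRow(ag$gene_id[k], subj[k], identity[k], covFrac[k], bits[k])))
  ## secondary, lower-bitscore hits to a competing family of the same
  ## kind for a slice of peptidase genes: the per-(gene, kind) best-hit
  ## resolver must discard them
  pepIdx <- which(ag$role == "peptidase")
  pepIdx <- pepIdx[seq_len(min(80L, length(pepIdx)))]
  otherFam <- function(f)
    merposFamilies[(match(f, merposFamilies)) %% length(merposFamilies) + 1L]
  hits2 <- do.call(rbind, lapply(pepIdx, function(k)
    hitRow(ag$gene_id[k], paste0("ref_pep_", otherFam(ag$label[k])),
           max(51, identity[k] - 10), covFrac[k] * 0.9,
           bits[k] * 0.6)))
  ## hits to a subject absent from the reference map: assignment must
  ## drop them (with a reported count) without touching the census
  unIdx <- which(!isDecoy & ag$role != "peptidase")
  unIdx <- unIdx[seq_len(min(50L, length(unIdx)))]
  hits3 <- do.call(rbind, lapply(unIdx, function(k)
    hitRow(ag$gene_id[k], "ref_unmapped_db", identity[k],
           covFrac[k], bits[k] * 0.5)))
  hits <- rbind(hits, hits2, hits3)
  rownames(hits) <- NULL
  hits$coverage <- hits$aln_length / qlenAll[hits$query_id] * 100
  queryLengths <- data.frame(query_id = gm$gene_id,
                             length = as.numeric(qlenAll),
                             stringsAsFactors = FALSE)

  signal <- data.frame(gene_id = gm$gene_id,
                       call = ifelse(gm$secreted, "SP", "OTHER"),
                       stringsAsFactors = FALSE)
  signal$signal_peptide <- signal$call == "SP"

  ## --- depth tables -----------------------------------------------
  nPass <- sum(bp$qc_pass)
  binCov <- setNames(bp$abundance * nPass, bp$bin_id)  # per unit depth
  depthRows <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    cov <- binCov[contigs$bin_id] * samples$depth[s]
    md <- if (noise == "none") cov else {
      lam <- cov * contigs$length  # base-level counts
      drawCount(length(lam), lam, noise, spec@nbSize) / contigs$length
    }
    depthRows[[s]] <- data.frame(
      sample_id = sid, contig_id = contigs$contig_id,
      length = contigs$length, mean_depth = md,
      stringsAsFactors = FALSE)
  }
  depth <- do.call(rbind, depthRows)

  ## --- expression factors and count tables ------------------------
  ## baseline factor per gene (same in every sample)
  baseFactor <- rep(0.5, nrow(gm))
  baseFactor[gm$role == "housekeeping"] <- 1.0
  baseFactor[gm$role %in% c("peptidase", "lipase", "cazyme",
                            "adhesion", "susc", "electron",
                            "decoy")] <- 0.4
  highExpr <- gm$role == "peptidase" & gm$secreted &
    bp$guild[match(gm$bin_id, bp$bin_id)] == "proteolytic"
  baseFactor[highExpr] <- 2.5
  sampleOf <- setNames(samples$sample_id, samples$substrate_aa)

  ## substrate-sample overrides for pathway genes: expressed amino acid
  ## -> factor 1.5 on all its genes; encoded-but-silent -> one gene of
  ## every complete pathway set to 0
  overrides <- list()  # per sample: named factor vector by gene_id
  for (sid in samples$sample_id) overrides[[sid]] <- numeric(0)
  exprTruthRows <- list()
  for (b in bp$bin_id) {
    plan <- spec@pathwayPlan[spec@pathwayPlan$bin_id == b, , drop = FALSE]
    sym <- presentSymbols[[b]]
    geneOfSym <- setNames(
      gm$gene_id[gm$bin_id == b & gm$role == "pathway"],
      gm$label[gm$bin_id == b & gm$role == "pathway"])
    for (r in seq_len(nrow(plan))) {
      aa <- plan$aa[r]
      sid <- sampleOf[[aa]]
      if (is.na(sid)) next
      sub <- catTb[catTb$aa == aa, , drop = FALSE]
      aaGenes <- intersect(unique(sub$gene_symbol), sym)
      if (!length(aaGenes)) next
      ov <- overrides[[sid]]
      if (plan$expressed[r]) {
        ov[geneOfSym[aaGenes]] <- pmax(ov[geneOfSym[aaGenes]], 1.5,
                                       na.rm = TRUE)
      } else {
        ## silence one gene of every complete pathway of this aa
        for (p in unique(sub$pathway_id)) {
          pg <- sub$gene_symbol[sub$pathway_id == p]
          if (all(pg %in% sym)) {
            ## prefer a gene private to this amino acid so another
            ## amino acid sharing this sample's gene is untouched
            others <- catTb$gene_symbol[catTb$aa != aa]
            cand <- setdiff(pg, others)
            pick <- if (length(cand)) cand[1] else pg[1]
            ov[geneOfSym[[pick]]] <- 0
          }
        }
      }
      overrides[[sid]] <- ov
    }
  }

  countRows <- list()
  exprStateRows <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    fac <- baseFactor
    names(fac) <- gm$gene_id
    ov <- overrides[[sid]]
    if (length(ov)) fac[names(ov)] <- ov
    cov <- binCov[gm$bin_id] * samples$depth[s]
    lam <- cov * (gm$length / 1000) * spec@exprRate * fac
    cnt <- drawCount(length(lam), lam, noise, spec@nbSize)
    countRows[[s]] <- data.frame(sample_id = sid, gene_id = gm$gene_id,
                                 count = as.numeric(cnt),
                                 stringsAsFactors = FALSE)
    exprStateRows[[s]] <- data.frame(sample_id = sid,
                                     gene_id = gm$gene_id,
                                     expected_count = lam,
                                     expressed = lam > 0,
                                     stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, countRows)
  exprStates <- do.call(rbind, exprStateRows)

  substrateMap <- data.frame(aa = samples$substrate_aa,
                             sample_id = samples$sample_id,
                             stringsAsFactors = FALSE)

  ## --- identity tables for novelty calls --------------------------
  famRefs <- paste0("fam_ref_", 1:5)
  proteoBins <- bp$bin_id[bp$guild == "proteolytic"]
  id16s <- expand.grid(query_id = proteoBins, reference_id = famRefs,
                       stringsAsFactors = FALSE)
  id16s$identity <- round(stats::runif(nrow(id16s), 79, 86), 1)
  idAAI <- expand.grid(query_id = proteoBins,
                       reference_id = paste0("genome_ref_", 1:4),
                       stringsAsFactors = FALSE)
  idAAI$identity <- round(stats::runif(nrow(idAAI), 48, 58), 1)
  suscRefs <- data.frame(
    reference_id = c("susc_poly_ref1", "susc_poly_ref2",
                     "susc_glucan_ref1", "susc_glucan_ref2"),
    cluster_label = c("polypeptide", "polypeptide", "glucan", "glucan"),
    stringsAsFactors = FALSE)
  suscGenes <- gm$gene_id[gm$role == "susc"]
  suscId <- if (length(suscGenes)) do.call(rbind, lapply(suscGenes,
    function(g) data.frame(
      query_id = g, reference_id = suscRefs$reference_id,
      identity = round(c(stats::runif(2, 55, 70),
                         stats::runif(2, 30, 45)), 1),
      stringsAsFactors = FALSE))) else
    data.frame(query_id = character(), reference_id = character(),
               identity = numeric())

  ## --- ground truth (derived from the planted gene complements) ----
  truthEncoded <- do.call(rbind, lapply(bp$bin_id, function(b) {
    det <- encodedAACount(presentSymbols[[b]], catalog)$detail
    enc <- tapply(det$complete, det$aa, any)
    data.frame(bin_id = b, aa = names(enc), encoded = as.logical(enc),
               stringsAsFactors = FALSE)
  }))
  ## expressed truth: an amino acid is expressed when one of its
  ## complete pathways has every gene at positive expected count in the
  ## substrate sample
  truthExpressed <- do.call(rbind, lapply(bp$bin_id, function(b) {
    sym <- presentSymbols[[b]]
    geneOfSym <- setNames(
      gm$gene_id[gm$bin_id == b & gm$role == "pathway"],
      gm$label[gm$bin_id == b & gm$role == "pathway"])
    do.call(rbind, lapply(aas, function(aa) {
      sid <- if (aa %in% names(sampleOf)) sampleOf[[aa]] else NA
      if (is.na(sid))
        return(data.frame(bin_id = b, aa = aa, expressed = FALSE,
                          stringsAsFactors = FALSE))
      es <- exprStates[exprStates$sample_id == sid, , drop = FALSE]
      lamOf <- setNames(es$expected_count, es$gene_id)
      sub <- catTb[catTb$aa == aa, , drop = FALSE]
      expd <- FALSE
      for (p in unique(sub$pathway_id)) {
        pg <- sub$gene_symbol[sub$pathway_id == p]
        if (all(pg %in% sym) &&
            all(lamOf[geneOfSym[pg]] > 0)) { expd <- TRUE; break }
      }
      data.frame(bin_id = b, aa = aa, expressed = expd,
                 stringsAsFactors = FALSE)
    }))
  }))
  truth <- list(
    abundance = data.frame(bin_id = bp$bin_id[bp$qc_pass],
                           abundance = bp$abundance[bp$qc_pass],
                           stringsAsFactors = FALSE),
    qc_pass = data.frame(bin_id = bp$bin_id, qc_pass = bp$qc_pass,
                         stringsAsFactors = FALSE),
    encoded = truthEncoded,
    expressed = truthExpressed,
    present_symbols = presentSymbols,
    gene_expression_states = exprStates,
    census = data.frame(
      bin_id = bp$bin_id, guild = bp$guild,
      n_peptidase = bp$n_peptidase,
      n_secreted_peptidase = bp$n_secreted_peptidase,
      n_lipase = bp$n_lipase, n_cazyme = bp$n_cazyme,
      n_adhesion = bp$n_adhesion, n_susc = bp$n_susc,
      stringsAsFactors = FALSE))

  tables <- list(qc = qc, contigs = contigs, genes = genes,
                 hits = hits, query_lengths = queryLengths,
                 reference_map = validateReferenceMap(
                   do.call(rbind, refRows)),
                 signal = signal[, c("gene_id", "call")],
                 depth = depth, counts = counts,
                 substrate_map = substrateMap,
                 identity_16s = id16s, identity_aai = idAAI,
                 susc_identities = suscId,
                 susc_reference_labels = suscRefs)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (nm in names(tables)) {
      if (nm == "hits") {
        utils::write.table(
          tables$hits[, c("query_id", "subject_id", "identity",
                          "aln_length", "mismatches", "gaps", "qstart",
                          "qend", "sstart", "send", "evalue",
                          "bitscore")],
          file.path(outDir, "hits.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE, col.names = FALSE)
      } else {
        utils::write.table(tables[[nm]],
                           file.path(outDir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    yaml::write_yaml(
      list(abundance = truth$abundance,
           encoded = truthEncoded, expressed = truthExpressed),
      file.path(outDir, "ground_truth.yaml"),
      column.major = FALSE)
  }
  list(tables = tables, truth = truth, spec = spec)
}
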
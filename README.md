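# AminoCensus

Genome-resolved identification of proteolytic amino-acid-degrading
populations in anaerobic microbial communities.

Given metagenome-assembled genome bins (with CheckM-style QC metrics),
tabular homology hits against functional reference catalogs,
signal-peptide calls, per-contig depth tables and per-gene
metatranscriptome counts, AminoCensus computes, per bin:

* **Relative abundance** from length-weighted contig coverage:
  cov_g = Σᵢ dᵢ·ℓᵢ / Σᵢ ℓᵢ, normalized over all retained genomes; bins
  pass QC with completeness > 80% and contamination < 5%.
* **A functional census** under the identity > 50% / query coverage >
  50% homology filter: peptidases with MEROPS-style catalytic-type
  breakdown, secreted enzymes (assignment + signal peptide), adhesion
  domains (PF01103, PF00754, PF02494, PF02496), SusC transporters,
  electron-transfer markers, and per-sample "highly expressed" calls
  (RPKM strictly above the whole-bin median).
* **Amino-acid pathway scoring** against an explicit catalog of
  catabolic routes for all 20 amino acids: a pathway is complete only
  when every gene is present, an amino acid degradable when any of its
  alternative routes is complete, and expressed when every gene of a
  complete route has RPKM > τ (default 0) in the culture fed that amino
  acid.
* **Taxonomic novelty** from 16S rRNA identity (86.5% family / 94.5%
  genus thresholds) and AAI over reciprocal best hits (~60% family
  cutoff), plus nearest-reference SusC substrate-cluster assignment.

A seeded synthetic community generator (`emulateStudyDesign()`,
`generateCommunity()`) emits every input dialect with planted ground
truth, so the whole pipeline is testable without any external data.

## Worked example

```r
library(AminoCensus)

spec <- emulateStudyDesign(seed = 1)   # 20 substrate samples, 10 bins
com  <- generateCommunity(spec)        # all input tables + ground truth
res  <- runPipeline(com$tables)        # full analysis

res$pathway_summary
#>    bin_id encoded_aas expressed_aas
#> 1     bg1           8             2
#> ...
#> 6    bin1          16            16
#> 7    bin2          17            11
#> 8    bin3          17            17
#> 9   ferm1          13             5
#> 10  ferm2          16             2

res$census$summary[1:5, c("bin_id", "adhesion_genes", "peptidase_total",
                          "secreted_peptidases", "susC_genes")]
#>   bin_id adhesion_genes peptidase_total secreted_peptidases susC_genes
#> 1   bin1              3             172                  72          3
#> 2   bin2              6             109                  55          8
#> 3   bin3              7             100                  68          5
#> 4  ferm1              1              25                  12          0
#> 5  ferm2              0              25                   8          0
```

The three dominant proteolytic bins encode complete degradation
pathways for 16–17 of the 20 amino acids and express most of them in
the respective substrate cultures, carry large secreted-peptidase
complements and polypeptide-type SusC transporters; the two minority
fermenter bins encode many pathways but express few — exactly the
planted contrast, recovered through homology filtering, category
assignment, RPKM quantification and pathway scoring.

Real data enter through the readers (`readHitsTable()`,
`readDepthTable()`, `readCountTable()`, `readSignalTable()`,
`readQCTable()`, `readReferenceMap()`, GFF3/FASTA helpers) or a single
YAML config via `runPipelineFromConfig()`; a thin CLI wrapper lives in
`inst/scripts/run_pipeline.R` (`run` and `simulate` subcommands).

The methods vignette
(`vignettes/amino-acid-degrader-census.Rmd`) documents the models,
threshold conventions, the synthetic generator's design and its
limitations.

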
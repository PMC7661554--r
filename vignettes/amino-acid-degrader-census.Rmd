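---
title: "Scoring proteolytic amino-acid degraders from genome bins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring proteolytic amino-acid degraders from genome bins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AminoCensus)
```

## The problem

In anaerobic digesters and similar protein-rich anoxic habitats, the
populations that hydrolyze protein and ferment the released amino acids
are largely uncultured. Given metagenome-assembled genome bins and their
metatranscriptomes from enrichment cultures fed single amino acids, one
wants to answer, per bin: how abundant is it; does it carry the
apparatus of a proteolytic lifestyle (surface-adhesion domains, secreted
peptidases, polypeptide-specific TonB-dependent transporters); which
amino-acid catabolic pathways does it encode and actually express in the
culture fed that amino acid; and is it taxonomically novel? AminoCensus
implements that analysis as a reusable, tested pipeline over plain
tabular inputs (homology hits, depth and count tables, signal-peptide
calls, identity matrices), with a seeded synthetic community generator
so every stage can be validated against planted ground truth.

## Models and procedures

**Bin quality.** Bins enter the analysis only with completeness
strictly above 80% and contamination strictly below 5%, the
conventional high-quality-draft cutoffs estimated from single-copy
marker genes. We read the cutoffs' printed inequality symbols as
strict; since the metrics are continuous, the boundary convention is
practically immaterial, but it is fixed, documented and configurable.

**Abundance.** The coverage of a genome in a sample is the
length-weighted mean of its contig depths,
\(\mathrm{cov}_g = \sum_i d_i \ell_i / \sum_i \ell_i\), and its
relative abundance is \(\mathrm{cov}_g / \sum_h \mathrm{cov}_h\) over
the retained genomes — i.e. normalization is over the binned fraction
of the community, not total reads. Contigs missing from a depth table
count as depth zero with a warning rather than silently shrinking the
denominator.

**Homology census.** Hits are kept only with identity > 50% and query
coverage > 50%, mirroring the manual-curation rule commonly applied
when checking annotations against reference catalogs (MEROPS-style
peptidase families, lipase and CAZyme families, transporter and
adhesion-domain references). Query coverage (alignment length over
query length) is used because the filter's purpose here is to guard
against fragmentary query genes; this is configurable, and when no
query-length table is available the coverage filter is skipped with a
warning instead of silently passing everything. Best hits are resolved
per (gene, category kind) — bit score, then identity, then subject id —
so a multi-domain gene can be both a peptidase and carry an adhesion
domain, but never holds two labels of one kind. A gene is a *secreted*
enzyme when it additionally carries a signal peptide. Peptidase
catalytic types (metallo, serine, cysteine, ...) are read off the first
letter of the family code.

**Highly expressed.** Within one bin and sample, a gene is highly
expressed when its RPKM strictly exceeds the median RPKM over *all*
genes of the bin, zeros included. We read "the bin's median activity"
as a whole-bin statistic; an expressed-only median is available as an
option. Under a constant expression profile the strict inequality
selects nothing, which is the desired degenerate behavior.

**Pathway completeness and expression.** Amino-acid catabolism is
scored against an explicit catalog: one row per (amino acid, pathway,
gene symbol). A pathway is complete only when every listed gene is
present; an amino acid counts as degradable when at least one of its
alternative routes is complete (OR semantics — threonine, for example,
can be degraded through an aldolase, a 3-dehydrogenase or an
ammonia-lyase route, and any one suffices). A complete pathway is
expressed when every gene has RPKM strictly greater than a threshold
\(\tau\) in the culture fed that amino acid; \(\tau\) defaults to 0 —
any detected transcription of the full gene set counts — because no
numeric cutoff is established for these data; it is configurable and
recorded in the run manifest. Genes shared between pathways are scored
independently in each. The shipped catalog is a best-effort
reconstruction from named marker enzymes (alanine dehydrogenase as a
single-gene route; the six-gene glycine decarboxylating route; an
eight-gene lysine fermentation route; three threonine routes) plus
literature-standard anaerobic routes for the remaining amino acids; it
is data, not code, and it is expected that users substitute their own
curated catalog.

**RPKM.** `count / (gene length in kb) / (mapped reads in millions)`,
with the library size taken as total mapped reads over the gene catalog
of all retained bins in that sample.

**Taxonomic novelty.** 16S rRNA identity against the best reference is
mapped to rank calls with the 86.5% (family) and 94.5% (genus)
thresholds; AAI (mean identity over reciprocal-best-hit orthologs) uses
the ~60% family cutoff. Identities exactly at a threshold fall in the
less-novel class; the cited threshold framework does not fix the
boundary, so this is a documented package convention. One caveat worth
surfacing: a lineage's *maximum* identity to known families can exceed
the family threshold while the lineage is still treated as novel on
phylogenetic grounds; the classifier therefore reports per-reference
calls and leaves lineage-level synthesis to the analyst. AAI averages
each ortholog pair's two directional identities, making the statistic
exactly symmetric in the two genomes. The reciprocal-best-hit
thresholds (identity >= 30%, coverage >= 70%) are common tool defaults,
not study-specific values, and are configurable.

**SusC cluster placement.** Sequence clusters of the TonB-dependent
transporter SusC correlate with substrate class (polypeptide vs
glucan). Full phylogenetic placement is out of scope; the package
assigns the label of the highest-identity labeled reference, with a
deterministic lexicographic tie-break. This is an explicit
simplification: it tests the functional claim (which cluster) without
tree inference.

## The synthetic community generator

`emulateStudyDesign()` builds a 20-substrate-sample mock enrichment
experiment: three dominant proteolytic bins (planted relative
abundances 9.1%, 2.6% and 20.2%; 172/109/100 peptidase genes of which
72/55/68 secreted; 3/6/7 adhesion genes; 3–8 SusC genes; 16–17 amino
acids encoded and 16/11/17 expressed), two marginal fermenter bins
(planted abundances 0.3% and 0.2%; 12 and 8 secreted peptidases;
fasciclin as the only adhesion domain; few pathways expressed), and
background bins absorbing the remaining abundance. Two extra bins fail
QC — one on contamination only, one on completeness only — so each
cutoff is exercised independently. These values were chosen once, as
the design of the default mock experiment, to reproduce the contrast
between a dominant proteolytic guild and minority cultured fermenters.

Mechanically, gene presence is planted at the *symbol* level (symbols
are shared across pathways, e.g. `sdaA` serves both the glycine and
serine routes), removing per broken pathway a gene chosen preferentially
unique to that amino acid; the serialized ground truth is then derived
from the final symbol sets by direct catalog scan, so recovery tests
exercise the hits → assignments → completeness chain rather than the
planting intent. Contig depths are Poisson at the base level with mean
`abundance × sample depth × n bins`; gene counts are Poisson with mean
proportional to bin coverage, gene length and the planted expression
factor (a negative-binomial option exists for overdispersion; `none`
gives analytic expectations exactly). Hit identities are drawn in
60–95% for planted genes; every removed pathway gene also gets a decoy
ORF whose hit sits below the 50/50 filter, and a slice of genes gets
competing same-kind and unmapped-reference hits, so filtering, best-hit
resolution and the dropped-hit path all carry real weight in recovery
tests.

What the generator does *not* emulate: real sequence evolution (hits
are synthesized, not aligned), strain heterogeneity within bins,
compositional coupling between samples, GC- or mappability-driven
coverage bias, and multi-mapping artifacts. Passing recovery tests
therefore demonstrates the correctness of the computation chain under
the stated noise model, not robustness to every artifact of real
metagenomes.

```{r}
spec <- emulateStudyDesign(seed = 1)
com <- generateCommunity(spec)
res <- suppressMessages(runPipeline(com$tables))
res$pathway_summary
```

## Numerical and design choices

* **Problem sizes.** The default mock community has 10 QC-passing bins,
  about 1,800 genes and 20 samples at 20× mean depth; recovery checks
  in the test suite use 5 seeds of this design. At these sizes the
  planted abundances are recovered with RMSE far below 0.02 and planted
  encoded/expressed states exactly.
* **Determinism.** All tie-breaks (best hits, SusC references, novelty
  best-reference) are total orders; a fixed generator seed reproduces
  every table byte-identically; identical pipeline inputs give
  identical outputs.
* **Degenerate inputs.** All-zero coverage in a sample yields `NA`
  abundances with a warning; an empty RBH set yields `NA` AAI with
  zero orthologs; an empty gene set is an error for the median-based
  highly-expressed call; a pathway with an empty gene list is a catalog
  validation error.
* **Strictness.** All cutoffs printed with `>`/`<` are strict; the
  RBH thresholds, being tool-default stand-ins rather than printed
  cutoffs, are inclusive.

## Limitations

The shipped pathway catalog is a reconstruction, not a curated
supplement — treat per-amino-acid verdicts on real data as provisional
until scored against a catalog you trust. Expression scoring at
\(\tau = 0\) is permissive: single spurious reads on every gene of a
pathway count as expression; raise \(\tau\) for deeper libraries. SusC
placement by nearest reference cannot detect novel clusters. The
abundance normalization is over retained bins only, so values are not
comparable across runs with different bin sets.
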
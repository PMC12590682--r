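# mspprofiler

Taxonomic, functional and strain-level profiling of shotgun metagenomic
samples against ecosystem-specific **microbial gene catalogues**, with
the Metagenomic Species Pangenome (MSP) as the species-level unit.

The package is aimed at microbiome researchers who align reads against a
gene catalogue (human gut, mouse gut, skin, …) and want, from those
alignments alone: species abundances, functional term and module
profiles, and strain tracking across samples — e.g. donor–recipient
strain engraftment after faecal microbiota transplantation.

## What it computes

**Counting.** Alignments are filtered on identity
`(aligned_length − NM) / aligned_length ≥ 0.95` (0.98 in fast mode) and
reduced to gene counts under three modes: *unique* (single-gene reads
only), *total* (1 per aligned gene), and *shared* (default): a read
aligned to *n* genes is apportioned by each gene's unique-read count
`u_g / Σ u_g'`, or evenly (1/*n*) when all anchors are zero. Shared
counting conserves read mass exactly.

**Taxonomy.** Counts are normalized to depth coverage
(`count / L_eff × 100`, effective length `L − read_length + 1`) or FPKM,
then averaged over each MSP's 100 signature genes (zeros included). An
MSP is called absent when fewer than 10% (fast: 20%) of its signature
genes are detected.

**Function.** Term abundances at gene level (sum over annotated genes)
and MSP level (sum over MSPs with a *detected* annotated gene); module
completeness as the maximum over alternative configurations of a
KEGG-style definition grammar; carriers (completeness > 90%), module
potential (summed carrier abundance) and the ARG ratio (detected
resistance genes / detected genes).

**Strains.** Per-site IUPAC consensus of signature genes from pileups
(depth < 3 masked `N`; non-reference alleles kept at frequency ≥ *f*;
*f* = 0.1 mixed, *f* = 0.5 dominant), breadth filter (≥ 80/100 signature
genes with breadth ≥ 0.5), then closed-form GTR mutation rates between
samples,

```
d = − Σ_i π_i [ log(Π⁻¹ F̂) ]_ii
```

with F̂ the symmetrized site-pair divergence matrix and Π the empirical
base frequencies. Complete-linkage clustering at a 5e-3 cutoff and
engraftment rates at the 1e-4 identity cutoff sit on top.

A seeded synthetic-data module (`generateCatalogue()`,
`simulateSample()`, `mutateStrain()`, `evaluateProfile()`) generates
catalogues, reads and planted strains with full ground truth; all
examples and tests run from it, no downloads required.

## Worked example

```r
library(mspprofiler)

g  <- generateCatalogue(seed = 7)      # 5 MSPs x 120 genes + 20 unclustered
ct <- g$catalogue
ct
#> GeneCatalogue (complete mode)
#>   genes:       620 (620 with sequence)
#>   MSPs:        5 (500 signature genes, 20 unclustered genes)
#>   annotations: 478 over {KO, CAZyme, ARG_resfinder}
#>   modules:     3

ab  <- setNames(c(0.4, 0.25, 0.15, 0.12, 0.08), mspIds(ct))
sim <- simulateSample(ct, ab, n_reads = 10000, seed = 11,
                      homolog_partner = g$truth$homolog_partner)

grp <- filterAlignments(sim$sam, ct)          # identity filter, grouping
cnt <- countReads(grp, "shared", sample_id = "demo")
cnt
#> GeneCounts for sample 'demo' (shared mode)
#>   596 genes, 10000 reads retained of 10000 (mapping rate 100.0%)

profile <- mspAbundance(normalizeCoverage(cnt, ct), ct)
round(abundances(relativeAbundance(profile)), 4)
#> msp_001 msp_002 msp_003 msp_004 msp_005
#>  0.4025  0.2593  0.1556  0.1079  0.0746

str(evaluateProfile(profile, ab))
#> List of 5
#>  $ sensitivity      : num 1
#>  $ specificity      : num NA
#>  $ f1               : num 1
#>  $ richness_delta   : int 0
#>  $ bray_curtis_log10: num 0.00757
```

The estimated relative abundances track the planted composition
(0.40/0.25/0.15/0.12/0.08): every species is detected (F1 = 1, richness
error 0; specificity is undefined here because the truth leaves no
absent MSP) and the log-scale Bray–Curtis dissimilarity to the truth is
below 0.01. `runProfile()` and `runStrain()` orchestrate the same steps
across sample sets and write TSV/FASTA outputs;
`inst/scripts/mspprofile` exposes them as a command line.

For the models, parameter meanings and design rationale, see the
vignette in `vignettes/gene-catalogue-profiling.Rmd`.

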
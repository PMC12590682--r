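---
title: "Gene-catalogue profiling of metagenomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-catalogue profiling of metagenomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspprofiler)
```

# Overview

`mspprofiler` turns per-sample read alignments against an
ecosystem-specific microbial gene catalogue into three layers of
community description:

1. **Taxonomic profiles** — abundances of Metagenomic Species Pangenomes
   (MSPs), species-level units defined by co-abundant gene clusters, each
   quantified through its most central ("signature") genes.
2. **Functional profiles** — abundances of functional terms (KEGG
   orthologs, CAZyme families, antibiotic-resistance genes) at the gene
   and MSP level, with KEGG-style module completeness, carrier MSPs and
   module potential.
3. **Strain profiles** — sample-specific consensus genotypes over
   signature genes, pairwise mutation rates under a General Time
   Reversible (GTR) model, complete-linkage strain clusters, and
   donor–recipient engraftment statistics.

The aligner itself is out of scope: the package consumes SAM/BAM and a
catalogue directory. A seeded synthetic-data generator produces
catalogues, communities, reads and planted strains with full ground
truth, so every stage is testable without any external download.

# The catalogue model

A catalogue is a set of genes (id, length, optionally sequence), an MSP
membership table in which each gene belongs to at most one MSP and the
top-ranked members (100 by default) are its signature genes, functional
annotation tables, and module definitions. Fast mode uses a reduced,
signature-genes-only catalogue; because a smaller reference raises the
risk of spurious alignments, fast mode tightens the alignment identity
threshold from 0.95 to 0.98 and the MSP detection fraction from 0.10 to
0.20.

Module definitions use KEGG-module notation: whitespace separates
mandatory steps, a comma separates alternatives within a step, `+` joins
members of a complex, and parentheses group. `"K1 (K2,K3)"` is a
two-step module satisfiable by `{K1,K2}` or `{K1,K3}`. GMM and GBM
modules reuse the same grammar; all terms are opaque strings, so modules
mixing KO, eggNOG and TIGRFAM identifiers parse uniformly.

# Counting model

Alignments are filtered on identity, computed from the aligned length
and the SAM `NM` tag as `(aligned_length − NM) / aligned_length`, with a
threshold of 0.95 (0.98 in fast mode; comparisons are `≥`). Duplicate-
flagged records are excluded; secondary and supplementary alignments
participate, since multi-mapping is the point of shared counting. Each
mate of a pair is treated as an independent read, matching the read-level
trimming convention of the alignment step. Within a read, several
alignments to the same gene collapse to the best one.

Three counting modes reduce the groups to per-gene counts:

* **unique** — only reads with a single surviving gene count;
* **total** — every gene in a read's group receives 1;
* **shared** (default) — unique reads count 1; a read mapped to *n*
  genes is apportioned in proportion to each gene's unique count, or
  evenly (1/*n*) when those unique counts are all zero.

Shared counting conserves read mass exactly; apportionment is a single
pass using the final unique counts, not an iterative EM. Weights are
summed in sorted order so that results are bit-identical under any
permutation of the input reads.

# Taxonomic profiling

Counts are normalized either as **depth coverage** — count divided by
gene length times 100, with the gene length optionally replaced by the
effective length `max(L − read_length + 1, 1)`, the number of admissible
read start positions — or as **FPKM**. The effective-length form is the
default correction; the exact correction used by the upstream literature
is not published, so the choice is exposed as `correction =
c("effective", "none")`.

An MSP's abundance is the arithmetic mean of its top-100 signature gene
abundances, **zeros included**, and is set to 0 when fewer than 10%
(complete) / 20% (fast) of those signature genes are detected
(abundance > 0). Averaging over the fixed signature denominator rather
than over detected genes only reads most naturally from the separation
between the detection rule and the reduction rule; the detected-only
variant is available as `mean_detected_only = TRUE`. Ties in signature
rank break lexicographically by gene id for reproducibility.

# Functional profiling

A term's **gene-level** abundance sums the normalized abundances of all
genes carrying it. Its **MSP-level** abundance sums the abundances of
the MSPs harboring it, where "harboring" requires the annotated gene to
be *detected* — at least one mapped read — in that sample; raw counts,
not normalized values, decide detection. Unclustered genes participate
only at the gene level (they have no MSP to carry them), which is why
catalogues keep them: a substantial minority of resistance genes cluster
with no species.

Module completeness for an MSP is the fraction of module steps whose
chosen alternative is fully present, maximized over the alternative
configurations. Because alternatives are chosen independently per step,
the maximum equals the fraction of steps with at least one fully present
alternative; the package computes it that way and the test suite checks
it against exhaustive configuration enumeration. An MSP is a module
**carrier** when completeness is strictly greater than 0.9, and the
module's **potential** is the summed abundance of its carriers. The
completeness denominator counts steps, not terms; a multi-term complex
counts as one step (the alternative reading — counting terms — would
weight complexes more heavily).

The **ARG ratio** of a sample is the number of detected genes carrying
any antibiotic-resistance annotation (union of the ResFinder,
ResFinderFG and mechanism-based namespaces by default) divided by the
number of detected genes.

# Strain profiling

## Site model

For each signature gene, a pileup over the identity-filtered alignments
counts A/C/G/T per position, ignoring indels and bases below a Phred
floor (Q ≥ 13). Consensus rules, applied independently per site:

* depth < 3 → masked `N`;
* otherwise the allele set is the reference base (when it has at least
  one supporting read) plus every non-reference base with frequency
  ≥ *f*; the set's IUPAC code is emitted (majority base as fallback if
  the set is empty);
* the **dominant** configuration *f* = 0.5 emits the major allele only,
  ties becoming the IUPAC code of the tied set; the **mixed**
  configuration *f* = 0.1 encodes strain mixtures as ambiguity codes.

The pileup caller is internal (no external variant caller): the rules
above *are* the variant model, and per-site counting with a quality
floor implements them exactly. A cross-check against
`Rsamtools::pileup` on identical input is part of the test suite.

## Breadth filter

A sample-specific MSP genotype proceeds to distance computation only
when at least 80 of its 100 signature genes (proportionally scaled,
rounded up, for smaller MSPs) have breadth ≥ 0.5, where breadth is the
fraction of positions at or above the masking depth. Using the same
depth threshold for masking and breadth keeps the two rules consistent;
both are configurable.

## GTR mutation rate

Consensus sequences are inherently aligned (substitutions only), so the
pairwise distance needs no multiple alignment. Sites that are `N` in
either sequence are excluded; at least 10 informative sites are required
or the distance is reported missing. The remaining sites fill a 4×4
divergence matrix **F**; with **F̂** its symmetrized, normalized form and
**Π** the diagonal of empirical base frequencies, the mutation rate is
the closed-form GTR (paralinear/log-det) distance

$$ d = -\sum_i \pi_i \left[\log\left(\Pi^{-1}\hat F\right)\right]_{ii}. $$

Identical sequences give exactly 0; a non-real matrix logarithm
(saturation) yields a missing value with a reason code. In the
equal-frequency limit the estimator agrees with the JC69 closed form
`−(3/4)·log(1 − 4p/3)` to high accuracy, which the tests verify on
simulated sequences.

**Ambiguity handling.** How IUPAC codes enter **F** is a genuine design
choice, as the upstream description does not state a convention. The
package's default (`ambiguity = "intersect"`) counts a site whose two
allele sets overlap as a match distributed over the shared bases, and
only disjoint sets as mismatches: an ambiguous call is *compatible* with
identity, exactly as a likelihood treatment of IUPAC codes as partially
missing data behaves at low divergence. The alternative
(`ambiguity = "cartesian"`) spreads each site uniformly over the
Cartesian product of the two sets, so every error-induced ambiguity adds
half a mismatch. The uniform convention systematically inflates the
distance between sequencing replicates of the *same* strain (a handful
of low-depth ambiguous sites push it above the 1e-4 identity cutoff even
at 40× coverage), which contradicts the observed behavior of the method
this package models; the intersection convention keeps identical strains
at ≈ 0 while leaving genuinely diverged pairs untouched. Both are
exposed; the default is `"intersect"`.

## Clustering and engraftment

Pairwise rates for MSPs passing in ≥ 2 samples form symmetric,
zero-diagonal matrices. Strain clusters are complete-linkage trees cut
at a mutation rate of 5e-3 (≈ 99% nucleotide identity); samples with any
missing pairwise value are reported unclustered rather than forced into
a cluster. The engraftment rate of a recipient–donor pair is the
fraction of conspecific strain pairs (MSPs genotyped in both samples
with a computed distance) whose mutation rate is ≤ 1e-4, the cutoff at
which strains are called identical.

# The synthetic-data generator

`generateCatalogue()` builds random-sequence catalogues (default: 5 MSPs
× 120 genes of 300–1500 nt, 100 signature genes per MSP, 20 unclustered
genes, KO/CAZyme/ARG annotations, three multi-step modules).
`simulateSample()` draws single-end 80-nt reads in proportion to MSP
abundance × effective gene length — so expected depth coverage is
uniform within an MSP and proportional to its abundance — applies
uniform substitution errors (default 0.001/base), and writes name-sorted
SAM with correct positions and `NM` tags. Strains are planted by
substituting catalogue genes at a chosen per-site rate
(`mutateStrain()`), and multi-mapping is exercised through accessory
gene pairs generated as near-identical (2% diverged) homologous copies:
reads from such genes are also reported on the partner copy when the
alignment identity there is plausible. Signature genes are never
homologs, keeping taxonomic quantification clean.

What the generator does **not** emulate: indels and structural variants
(the strain model ignores indels by design), quality-score variation
(all bases Q40), GC or positional coverage bias, chimeric reads,
inter-genic sequence (reads never straddle gene boundaries, so per-gene
coverage ramps at the edges), and realistic cross-species homology
beyond the constructed pairs. Consequently, passing tests demonstrate
the correctness of the counting, reduction and distance machinery under
the stated models — not robustness to real-data artefacts such as
mapping bias or contamination.

Problem sizes are chosen for desk-scale validation: the end-to-end
taxonomic check uses 5 MSPs and 10,000 reads; strain checks use compact
catalogues (1–2 MSPs × 12 genes of 400–800 nt, 10 signature genes) so
that 4,000–8,000 reads give ≈ 40× coverage, comfortably above the ≥ 5×
regime the strain stage expects; distance-recovery checks simulate
100 kb sequence pairs directly. All randomness is seeded and
reproducible.

# Numerical choices and degenerate inputs

* Bray–Curtis on log profiles uses `log10(1 + x/pseudo)` with
  pseudocount = 0.1 × the smallest positive abundance across the two
  profiles; the shift keeps transformed values non-negative (Bray–Curtis
  is undefined on negatives) and a perfect profile gives exactly 0.
* The matrix logarithm uses an eigendecomposition; non-positive or
  materially complex eigenvalues are reported as saturation (missing)
  rather than coerced. Tiny negative distances from rounding clamp to 0.
* Zero-depth or all-masked genes yield all-`N` consensus and breadth 0;
  empty alignment files yield empty counts, not errors.
* All-zero MSP profiles refuse relative-abundance normalization with an
  explicit error; MSPs without signature genes warn and get abundance 0.
* Configuration enumeration is guarded (default 10,000) against
  combinatorial blow-up; completeness itself never enumerates.

# Known limitations

* Shared counting is single-pass; an EM-style iterative reapportionment
  is deliberately out of scope.
* The GTR distance is the closed-form estimator with empirical
  frequencies, not iterative maximum likelihood; the two agree closely
  away from saturation.
* Engraftment requires explicit donor–recipient sample pairs; it does
  not infer pairings from metadata.
* The package profiles against a given catalogue; building catalogues
  (assembly, co-abundance clustering, taxonomy assignment) is out of
  scope.
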
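Package: mspprofiler
Title: Taxonomic, Functional and Strain-Level Profiling of Metagenomes
    Against Microbial Gene Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles shotgun metagenomic samples aligned against an
    ecosystem-specific microbial gene catalogue. Reads SAM/BAM alignments,
    applies an identity filter and apportions multi-mapped reads across
    genes (unique, total and shared counting), reduces normalized gene
    abundances to Metagenomic Species Pangenome (MSP) profiles via
    signature genes, aggregates abundances to functional terms (KEGG
    orthologs, CAZymes, antibiotic resistance genes) with KEGG-style
    module completeness and carrier analysis, and reconstructs
    sample-specific consensus genotypes for strain tracking: IUPAC
    consensus calling from pileups, breadth filtering, pairwise mutation
    rates under a General Time Reversible model, complete-linkage strain
    clustering and donor-recipient engraftment statistics. Includes a
    seeded synthetic-data generator (catalogues, communities, reads,
    strains) with complete ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
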
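#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' ModuleDefinition: an evaluable functional module
#'
#' A functional module (KEGG module, Gut Metabolic Module or Gut Brain
#' Module) parsed into an ordered list of mandatory steps. Each step holds
#' one or more alternative units; a unit is a character vector of jointly
#' required terms (a complex). A step is satisfied when all terms of at
#' least one of its alternatives are present.
#'
#' @slot module_id single string identifier.
#' @slot source one of `"KEGG"`, `"GMM"`, `"GBM"`.
#' @slot definition the original definition string.
#' @slot steps list of steps; each step is a list of character vectors
#'   (alternatives), each vector a conjunction of terms.
#' @seealso [parseModuleDefinition()], [moduleCompleteness()]
#' @export
setClass("ModuleDefinition",
    representation(
        module_id  = "character",
        source     = "character",
        definition = "character",
        steps      = "list"
    ),
    prototype(source = "KEGG")
)

setValidity("ModuleDefinition", function(object) {
    msg <- character()
    if (!isSingleString(object@module_id))
        msg <- c(msg, "'module_id' must be a single string")
    if (!object@source %in% c("KEGG", "GMM", "GBM"))
        msg <- c(msg, "'source' must be one of KEGG, GMM, GBM")
    if (length(object@steps) < 1L)
        msg <- c(msg, "a module must have at least one step")
    for (s in object@steps) {
        if (!is.list(s) || length(s) < 1L)
            msg <- c(msg, "each step needs at least one alternative")
        else if (any(!vapply(s, function(a)
                is.character(a) && length(a) >= 1L, logical(1))))
            msg <- c(msg, "each alternative needs at least one term")
    }
    if (length(msg)) msg else TRUE
})

#' GeneCatalogue: a microbial gene catalogue
#'
#' Container for a non-redundant microbial gene catalogue: gene lengths and
#' (optionally) sequences, Metagenomic Species Pangenome (MSP) membership
#' with signature-gene ranks, functional annotations and functional module
#' definitions. Every other stage of the pipeline consumes this object.
#'
#' @slot genes data.frame with columns `gene_id`, `length`.
#' @slot sequences [Biostrings::DNAStringSet] of gene sequences, possibly
#'   empty (sequences are only required for the strain stage).
#' @slot msps data.frame with columns `msp_id`, `gene_id`,
#'   `signature_rank` (integer; `NA` for accessory, non-signature genes).
#'   Rank 1 is the most central signature gene.
#' @slot annotations data.frame with columns `namespace`, `gene_id`,
#'   `term`. A gene may carry several terms per namespace.
#' @slot modules named list of [ModuleDefinition-class] objects.
#' @slot mode `"complete"` (full catalogue) or `"fast"` (signature-genes
#'   only subset catalogue).
#' @seealso [loadCatalogue()], [generateCatalogue()]
#' @export
setClass("GeneCatalogue",
    representation(
        genes       = "data.frame",
        sequences   = "DNAStringSet",
        msps        = "data.frame",
        annotations = "data.frame",
        modules     = "list",
        mode        = "character"
    ),
    prototype(mode = "complete")
)

setValidity("GeneCatalogue", function(object) {
    msg <- character()
    g <- object@genes
    if (!all(c("gene_id", "length") %in% names(g)))
        return("'genes' needs columns gene_id, length")
    if (anyDuplicated(g$gene_id))
        msg <- c(msg, sprintf("duplicate gene_id: %s",
            paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", ")))
    if (any(g$length <= 0))
        msg <- c(msg, "gene lengths must be positive")
    if (length(object@sequences)) {
        sq <- object@sequences
        bad <- setdiff(names(sq), g$gene_id)
        if (length(bad))
            msg <- c(msg, sprintf("sequences for unknown genes: %s",
                                  paste(head(bad, 5), collapse = ", ")))
        common <- intersect(names(sq), g$gene_id)
        lens <- setNames(g$length, g$gene_id)
        off <- common[Biostrings::width(sq[common]) != lens[common]]
        if (length(off))
            msg <- c(msg, sprintf("sequence length disagrees with gene table: %s",
                                  paste(head(off, 5), collapse = ", ")))
    }
    m <- object@msps
    if (nrow(m)) {
        if (!all(c("msp_id", "gene_id", "signature_rank") %in% names(m)))
            return("'msps' needs columns msp_id, gene_id, signature_rank")
        unknown <- setdiff(m$gene_id, g$gene_id)
        if (length(unknown))
            msg <- c(msg, sprintf("MSP members not in gene table: %s",
                                  paste(head(unknown, 5), collapse = ", ")))
        if (anyDuplicated(m$gene_id))
            msg <- c(msg, "a gene may belong to at most one MSP")
    }
    a <- object@annotations
    if (nrow(a)) {
        unknown <- setdiff(a$gene_id, g$gene_id)
        if (length(unknown))
            msg <- c(msg, sprintf("annotated genes not in gene table: %s",
                                  paste(head(unknown, 5), collapse = ", ")))
    }
    if (!object@mode %in% c("complete", "fast"))
        msg <- c(msg, "'mode' must be 'complete' or 'fast'")
    if (identical(object@mode, "fast") && nrow(m)) {
        sig <- m$gene_id[!is.na(m$signature_rank)]
        if (!all(g$gene_id %in% sig))
            msg <- c(msg, "in fast mode every gene must be a signature gene")
    }
    if (length(msg)) msg else TRUE
})

#' GeneCounts: per-sample gene counts
#'
#' Raw per-gene read counts for one sample under one of the three counting
#' modes. `unique` and `total` counts are integers; `shared` counts are
#' real-valued because multi-mapped reads are apportioned fractionally.
#'
#' @slot sample_id sample identifier.
#' @slot counts named numeric vector, one entry per catalogue gene with at
#'   least one assigned read.
#' @slot mode `"unique"`, `"total"` or `"shared"`.
#' @slot n_reads_retained number of reads surviving the identity filter.
#' @slot n_reads_total total reads seen in the alignment file (including
#'   unmapped and filtered ones); `NA` when unknown.
#' @seealso [countReads()], [filterAlignments()]
#' @export
setClass("GeneCounts",
    representation(
        sample_id       = "character",
        counts          = "numeric",
        mode            = "character",
        n_reads_retained = "integer",
        n_reads_total   = "integer"
    ),
    prototype(mode = "shared", n_reads_total = NA_integer_)
)

setValidity("GeneCounts", function(object) {
    msg <- character()
    if (!object@mode %in% c("unique", "total", "shared"))
        msg <- c(msg, "'mode' must be unique, total or shared")
    if (length(object@counts) && is.null(names(object@counts)))
        msg <- c(msg, "'counts' must be named by gene_id")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' GeneProfile: normalized per-gene abundances
#'
#' @slot sample_id sample identifier.
#' @slot values named numeric vector of per-gene abundances.
#' @slot normalization `"raw"`, `"coverage"` or `"fpkm"`.
#' @seealso [normalizeCoverage()], [normalizeFPKM()]
#' @export
setClass("GeneProfile",
    representation(
        sample_id     = "character",
        values        = "numeric",
        normalization = "character"
    ),
    prototype(normalization = "raw")
)

setValidity("GeneProfile", function(object) {
    msg <- character()
    if (!object@normalization %in% c("raw", "coverage", "fpkm"))
        msg <- c(msg, "'normalization' must be raw, coverage or fpkm")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "values must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' MSPProfile: per-sample MSP abundances
#'
#' Species-level profile obtained by averaging the normalized abundance of
#' each MSP's signature genes, with undetected MSPs set to zero.
#'
#' @slot sample_id sample identifier.
#' @slot abundances named numeric over all catalogue MSP ids (zeros kept).
#' @slot detection_fraction the detection threshold used (fraction of
#'   signature genes that must be detected).
#' @slot n_signature the number of top signature genes used per MSP.
#' @seealso [mspAbundance()], [relativeAbundance()], [mspRichness()]
#' @export
setClass("MSPProfile",
    representation(
        sample_id          = "character",
        abundances         = "numeric",
        detection_fraction = "numeric",
        n_signature        = "integer"
    ),
    prototype(detection_fraction = 0.1, n_signature = 100L)
)

setValidity("MSPProfile", function(object) {
    msg <- character()
    if (length(object@abundances) && is.null(names(object@abundances)))
        msg <- c(msg, "'abundances' must be named by msp_id")
    if (any(!is.finite(object@abundances)) || any(object@abundances < 0))
        msg <- c(msg, "abundances must be finite and non-negative")
    if (length(msg)) msg else TRUE
})

#' ConsensusGenotype: sample-specific MSP consensus over signature genes
#'
#' Per-sample, per-MSP consensus of the signature gene sequences called
#' from read pileups: IUPAC ambiguity codes where several alleles pass the
#' frequency threshold, `N` where depth is insufficient.
#'
#' @slot sample_id sample identifier.
#' @slot msp_id MSP identifier.
#' @slot sequences [Biostrings::DNAStringSet] of per-gene consensus
#'   strings (IUPAC + N alphabet), named by gene_id, each exactly as long
#'   as its gene.
#' @slot breadth named numeric: per signature gene, the fraction of
#'   positions with depth at or above the masking threshold.
#' @slot passed_filter logical: did the genotype pass the breadth filter.
#' @seealso [consensusGenotype()], [breadthFilter()],
#'   [pairwiseMutationRate()]
#' @export
setClass("ConsensusGenotype",
    representation(
        sample_id     = "character",
        msp_id        = "character",
        sequences     = "DNAStringSet",
        breadth       = "numeric",
        passed_filter = "logical"
    ),
    prototype(passed_filter = FALSE)
)

setValidity("ConsensusGenotype", function(object) {
    msg <- character()
    if (length(object@sequences) && is.null(names(object@sequences)))
        msg <- c(msg, "'sequences' must be named by gene_id")
    if (length(msg)) msg else TRUE
})
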
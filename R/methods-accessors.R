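#' Accessors for mspprofiler classes
#'
#' Small accessor generics for the package's S4 containers; preferred over
#' direct slot access.
#'
#' @param x a mspprofiler object.
#' @param msp_id single MSP identifier.
#' @param n number of top-ranked signature genes to return.
#' @return the corresponding slot value (see individual methods).
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneIds", "GeneCatalogue", function(x) x@genes$gene_id)

#' @rdname accessors
setMethod("mspIds", "GeneCatalogue",
    function(x) unique(x@msps$msp_id))

#' @rdname accessors
setMethod("geneLengths", "GeneCatalogue",
    function(x) setNames(x@genes$length, x@genes$gene_id))

#' @rdname accessors
setMethod("geneSequences", "GeneCatalogue", function(x) x@sequences)

#' @rdname accessors
setMethod("catalogueMode", "GeneCatalogue", function(x) x@mode)

#' @rdname accessors
setMethod("signatureGenes", "GeneCatalogue", function(x, msp_id, n = Inf) {
    m <- x@msps[x@msps$msp_id == msp_id & !is.na(x@msps$signature_rank), ,
                drop = FALSE]
    if (!nrow(m)) return(character())
    # rank ties broken lexicographically by gene_id for reproducibility
    m <- m[order(m$signature_rank, m$gene_id), , drop = FALSE]
    head(m$gene_id, n)
})

#' @rdname accessors
setMethod("mspMembers", "GeneCatalogue", function(x, msp_id) {
    x@msps$gene_id[x@msps$msp_id == msp_id]
})

#' @rdname accessors
setMethod("annotationNamespaces", "GeneCatalogue",
    function(x) unique(x@annotations$namespace))

#' @rdname accessors
setMethod("moduleDefinitions", "GeneCatalogue", function(x) x@modules)

#' @rdname accessors
setMethod("sampleId", "GeneCounts", function(x) x@sample_id)
#' @rdname accessors
setMethod("sampleId", "GeneProfile", function(x) x@sample_id)
#' @rdname accessors
setMethod("sampleId", "MSPProfile", function(x) x@sample_id)
#' @rdname accessors
setMethod("sampleId", "ConsensusGenotype", function(x) x@sample_id)

#' @rdname accessors
setMethod("counts", "GeneCounts", function(x) x@counts)

#' @rdname accessors
setMethod("countingMode", "GeneCounts", function(x) x@mode)

#' @rdname accessors
setMethod("retainedReads", "GeneCounts", function(x) x@n_reads_retained)

#' @rdname accessors
setMethod("mappingRate", "GeneCounts", function(x) {
    if (is.na(x@n_reads_total) || x@n_reads_total == 0L) return(NA_real_)
    x@n_reads_retained / x@n_reads_total
})

#' @rdname accessors
setMethod("profileValues", "GeneProfile", function(x) x@values)

#' @rdname accessors
setMethod("abundances", "MSPProfile", function(x) x@abundances)

#' @rdname accessors
setMethod("mspIds", "MSPProfile", function(x) names(x@abundances))

#' @rdname accessors
setMethod("moduleSteps", "ModuleDefinition", function(x) x@steps)

#' @rdname accessors
setMethod("genotypeSequences", "ConsensusGenotype", function(x) x@sequences)

#' @rdname accessors
setMethod("geneBreadth", "ConsensusGenotype", function(x) x@breadth)

#' @rdname accessors
setMethod("passedFilter", "ConsensusGenotype", function(x) x@passed_filter)

setMethod("show", "GeneCatalogue", function(object) {
    n_sig <- sum(!is.na(object@msps$signature_rank))
    cat("GeneCatalogue (", object@mode, " mode)\n",
        "  genes:       ", nrow(object@genes),
        " (", length(object@sequences), " with sequence)\n",
        "  MSPs:        ", length(unique(object@msps$msp_id)),
        " (", n_sig, " signature genes, ",
        nrow(object@genes) - nrow(object@msps), " unclustered genes)\n",
        "  annotations: ", nrow(object@annotations), " over {",
        paste(annotationNamespaces(object), collapse = ", "), "}\n",
        "  modules:     ", length(object@modules), "\n", sep = "")
})

setMethod("show", "ModuleDefinition", function(object) {
    cat("ModuleDefinition ", object@module_id, " [", object@source, "]: ",
        object@definition, "\n  ", length(object@steps), " step(s)\n",
        sep = "")
})

setMethod("show", "GeneCounts", function(object) {
    cat("GeneCounts for sample '", object@sample_id, "' (", object@mode,
        " mode)\n  ", length(object@counts), " genes, ",
        object@n_reads_retained, " reads retained",
        if (!is.na(object@n_reads_total))
            sprintf(" of %d (mapping rate %.1f%%)", object@n_reads_total,
                    100 * mappingRate(object)) else "",
        "\n", sep = "")
})

setMethod("show", "GeneProfile", function(object) {
    cat("GeneProfile for sample '", object@sample_id, "' (",
        object@normalization, ")\n  ", length(object@values),
        " genes, total ", format(sum(object@values), digits = 6), "\n",
        sep = "")
})

setMethod("show", "MSPProfile", function(object) {
    cat("MSPProfile for sample '", object@sample_id, "'\n  ",
        sum(object@abundances > 0), " of ", length(object@abundances),
        " MSPs detected (detection fraction ", object@detection_fraction,
        ", top ", object@n_signature, " signature genes)\n", sep = "")
})

setMethod("show", "ConsensusGenotype", function(object) {
    cat("ConsensusGenotype: MSP '", object@msp_id, "', sample '",
        object@sample_id, "'\n  ", length(object@sequences),
        " signature genes, ",
        sum(object@breadth >= 0.5), " with breadth >= 0.5; ",
        if (object@passed_filter) "passed" else "failed",
        " breadth filter\n", sep = "")
})
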
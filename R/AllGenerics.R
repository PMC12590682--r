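#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("mspIds", function(x) standardGeneric("mspIds"))

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("geneSequences", function(x) standardGeneric("geneSequences"))

#' @rdname accessors
#' @export
setGeneric("catalogueMode", function(x) standardGeneric("catalogueMode"))

#' @rdname accessors
#' @export
setGeneric("signatureGenes",
    function(x, msp_id, n = Inf) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setGeneric("mspMembers", function(x, msp_id) standardGeneric("mspMembers"))

#' @rdname accessors
#' @export
setGeneric("annotationNamespaces",
    function(x) standardGeneric("annotationNamespaces"))

#' @rdname accessors
#' @export
setGeneric("moduleDefinitions", function(x) standardGeneric("moduleDefinitions"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("countingMode", function(x) standardGeneric("countingMode"))

#' @rdname accessors
#' @export
setGeneric("retainedReads", function(x) standardGeneric("retainedReads"))

#' @rdname accessors
#' @export
setGeneric("mappingRate", function(x) standardGeneric("mappingRate"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("moduleSteps", function(x) standardGeneric("moduleSteps"))

#' @rdname accessors
#' @export
setGeneric("genotypeSequences", function(x) standardGeneric("genotypeSequences"))

#' @rdname accessors
#' @export
setGeneric("geneBreadth", function(x) standardGeneric("geneBreadth"))

#' @rdname accessors
#' @export
setGeneric("passedFilter", function(x) standardGeneric("passedFilter"))
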
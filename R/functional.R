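#' Gene-level functional term abundance
#'
#' Sums the normalized abundances of all genes annotated with each term
#' of a namespace. A gene carrying several terms contributes fully to
#' each; unannotated genes (including unclustered ones, which have no MSP
#' to carry them) contribute to no term.
#'
#' @param profile a [GeneProfile-class].
#' @param catalogue a [GeneCatalogue-class] with annotations loaded.
#' @param namespace annotation namespace, e.g. `"KO"`, `"CAZyme"`.
#' @return named numeric vector of per-term abundances.
#' @export
geneFunctionAbundance <- function(profile, catalogue, namespace) {
    stopifnot(is(profile, "GeneProfile"), is(catalogue, "GeneCatalogue"))
    ann <- catalogue@annotations
    if (!namespace %in% ann$namespace)
        stop(sprintf("unknown namespace '%s'; available: %s", namespace,
                     paste(unique(ann$namespace), collapse = ", ")),
             call. = FALSE)
    ann <- ann[ann$namespace == namespace, , drop = FALSE]
    vals <- profileValues(profile)
    v <- ifelse(ann$gene_id %in% names(vals), vals[ann$gene_id], 0)
    out <- tapply(v, ann$term, sum)
    setNames(as.numeric(out), names(out))
}

## Terms annotated on the detected (>= 1 mapped read) genes of one MSP.
.detectedTermsByMSP <- function(detection, catalogue, namespace) {
    ann <- catalogue@annotations
    ann <- ann[ann$namespace == namespace, , drop = FALSE]
    det_genes <- names(counts(detection))[counts(detection) >= 1]
    ann <- ann[ann$gene_id %in% det_genes, , drop = FALSE]
    memb <- catalogue@msps[, c("msp_id", "gene_id")]
    ann <- merge(ann, memb, by = "gene_id")
    split(ann$term, ann$msp_id)
}

#' MSP-level functional term abundance
#'
#' A term's abundance is the summed abundance of the MSPs that harbor it,
#' restricted to genes that are detected (at least one mapped read) in
#' the sample: an MSP contributes its whole abundance to a term as soon
#' as one of its detected genes carries the term.
#'
#' @param msp an [MSPProfile-class].
#' @param detection a [GeneCounts-class] from the same sample (raw
#'   counts; detection means count >= 1).
#' @param catalogue a [GeneCatalogue-class].
#' @param namespace annotation namespace.
#' @return named numeric vector of per-term abundances.
#' @export
mspFunctionAbundance <- function(msp, detection, catalogue, namespace) {
    stopifnot(is(msp, "MSPProfile"), is(detection, "GeneCounts"),
              is(catalogue, "GeneCatalogue"))
    ann <- catalogue@annotations
    if (!namespace %in% ann$namespace)
        stop(sprintf("unknown namespace '%s'; available: %s", namespace,
                     paste(unique(ann$namespace), collapse = ", ")),
             call. = FALSE)
    terms_by_msp <- .detectedTermsByMSP(detection, catalogue, namespace)
    ab <- abundances(msp)
    out <- list()
    for (m in names(terms_by_msp)) {
        if (!m %in% names(ab) || ab[m] <= 0) next
        for (term in unique(terms_by_msp[[m]]))
            out[[term]] <- (out[[term]] %||% 0) + ab[[m]]
    }
    if (!length(out)) return(setNames(numeric(), character()))
    unlist(out)[order(names(out))]
}

#' Module completeness against a set of present terms
#'
#' Completeness is the fraction of a module's steps satisfied by the
#' present terms, maximized over the module's alternative configurations:
#' for each way of choosing one alternative per step, count the steps
#' whose chosen alternative has all its terms present, divide by the
#' number of steps, and keep the maximum. Because configurations are
#' independent across steps, the maximum equals the fraction of steps
#' with at least one fully present alternative, which is how it is
#' computed here; [enumerateConfigurations()] provides the brute-force
#' equivalent.
#'
#' @param m a [ModuleDefinition-class].
#' @param present_terms character vector of terms present in the sample
#'   (e.g. on an MSP's detected genes).
#' @return completeness fraction in \[0, 1\].
#' @examples
#' m <- parseModuleDefinition("K1 (K2,K3)")
#' moduleCompleteness(m, c("K1", "K3"))  # 1.0
#' @export
moduleCompleteness <- function(m, present_terms) {
    stopifnot(is(m, "ModuleDefinition"))
    ok <- vapply(m@steps, function(st)
        any(vapply(st, function(alt) all(alt %in% present_terms),
                   logical(1))), logical(1))
    sum(ok) / length(ok)
}

#' Module carriers and module potential for one sample
#'
#' For every module of the catalogue, identifies the carrier MSPs — the
#' detected MSPs whose module completeness, computed from the terms on
#' their detected genes, is strictly greater than `carrier_threshold`
#' (default 0.9, i.e. greater than 90%) — and the module potential, the
#' cumulative abundance of the carriers.
#'
#' @param msp an [MSPProfile-class].
#' @param detection a [GeneCounts-class] from the same sample.
#' @param catalogue a [GeneCatalogue-class] with modules and annotations.
#' @param carrier_threshold completeness above which an MSP carries the
#'   module (strict inequality).
#' @param namespace annotation namespace holding the module terms
#'   (default `"KO"`).
#' @return data.frame with columns `module_id`, `msp_id`,
#'   `completeness`, `abundance`, plus attribute-free summary rows are
#'   left to the caller; module potential is obtained with
#'   [modulePotential()].
#' @export
moduleCarriers <- function(msp, detection, catalogue,
                           carrier_threshold = 0.9, namespace = "KO") {
    stopifnot(is(msp, "MSPProfile"), is(detection, "GeneCounts"),
              is(catalogue, "GeneCatalogue"))
    mods <- moduleDefinitions(catalogue)
    terms_by_msp <- if (namespace %in% catalogue@annotations$namespace)
        .detectedTermsByMSP(detection, catalogue, namespace) else list()
    ab <- abundances(msp)
    detected_msps <- names(ab)[ab > 0]
    rows <- list()
    for (mod in mods) {
        for (m in detected_msps) {
            comp <- moduleCompleteness(mod,
                unique(terms_by_msp[[m]] %||% character()))
            if (comp > carrier_threshold)
                rows[[length(rows) + 1L]] <- data.frame(
                    module_id = mod@module_id, msp_id = m,
                    completeness = comp, abundance = unname(ab[m]))
        }
    }
    if (!length(rows))
        return(data.frame(module_id = character(), msp_id = character(),
                          completeness = numeric(), abundance = numeric()))
    do.call(rbind, rows)
}

#' Module potential per module
#'
#' The potential of a module in a sample is the cumulative abundance of
#' its carrier MSPs; modules with no carrier have potential 0.
#'
#' @param carriers data.frame from [moduleCarriers()].
#' @param catalogue a [GeneCatalogue-class] (to list all modules).
#' @return data.frame with columns `module_id`, `potential`,
#'   `n_carriers`.
#' @export
modulePotential <- function(carriers, catalogue) {
    ids <- vapply(moduleDefinitions(catalogue), slot, character(1),
                  "module_id")
    pot <- setNames(numeric(length(ids)), ids)
    ncar <- setNames(integer(length(ids)), ids)
    if (nrow(carriers)) {
        agg <- tapply(carriers$abundance, carriers$module_id, sum)
        pot[names(agg)] <- agg
        cnt <- table(carriers$module_id)
        ncar[names(cnt)] <- as.integer(cnt)
    }
    data.frame(module_id = ids, potential = unname(pot),
               n_carriers = unname(ncar), row.names = NULL)
}

#' Antibiotic-resistance gene ratio
#'
#' Fraction of the genes detected in a sample (at least one mapped read)
#' that carry an antibiotic-resistance annotation in any of the
#' requested namespaces (union by default, mirroring the three ARG
#' repertoires: ResFinder, ResFinderFG and mechanism-based predictions).
#'
#' @param detection a [GeneCounts-class].
#' @param catalogue a [GeneCatalogue-class].
#' @param arg_namespaces character vector of ARG namespaces to use.
#' @return fraction in \[0, 1\].
#' @export
argRatio <- function(detection, catalogue,
                     arg_namespaces = c("ARG_resfinder", "ARG_resfinderFG",
                                        "ARG_pcm")) {
    stopifnot(is(detection, "GeneCounts"), is(catalogue, "GeneCatalogue"))
    det_genes <- names(counts(detection))[counts(detection) >= 1]
    if (!length(det_genes))
        stop("no detected genes; ARG ratio is undefined", call. = FALSE)
    ann <- catalogue@annotations
    arg_genes <- unique(ann$gene_id[ann$namespace %in% arg_namespaces])
    sum(det_genes %in% arg_genes) / length(det_genes)
}
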
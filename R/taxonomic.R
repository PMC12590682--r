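#' Depth-coverage normalization of gene counts
#'
#' Converts raw counts to depth coverage: count divided by gene length
#' and multiplied by 100. The gene length can be corrected for the loss
#' of read start positions near gene ends (`correction = "effective"`,
#' the default): the effective length is `max(L - read_length + 1, 1)`,
#' the number of positions at which a read of the given length can start
#' inside the gene. `correction = "none"` uses the annotated length.
#'
#' @param counts a [GeneCounts-class].
#' @param catalogue a [GeneCatalogue-class] providing gene lengths.
#' @param read_length read length in nt used for the effective-length
#'   correction (default 80, matching reads trimmed to 80 nt before
#'   alignment).
#' @param correction `"effective"` or `"none"`.
#' @return a [GeneProfile-class] with `normalization = "coverage"`.
#' @examples
#' \dontrun{normalizeCoverage(cnt, cat, read_length = 80)}
#' @export
normalizeCoverage <- function(counts, catalogue, read_length = 80,
                              correction = c("effective", "none")) {
    correction <- match.arg(correction)
    stopifnot(is(counts, "GeneCounts"), is(catalogue, "GeneCatalogue"),
              read_length > 0)
    lens <- geneLengths(catalogue)
    unknown <- setdiff(names(counts(counts)), names(lens))
    if (length(unknown))
        stop(sprintf("counts for genes absent from the catalogue: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             call. = FALSE)
    cnt <- counts(counts)
    L <- lens[names(cnt)]
    L_eff <- if (correction == "effective") pmax(L - read_length + 1, 1)
             else L
    vals <- cnt / L_eff * 100
    new("GeneProfile", sample_id = counts@sample_id,
        values = vals, normalization = "coverage")
}

#' FPKM normalization of gene counts
#'
#' Fragments per kilobase of gene per million retained fragments:
#' `count / (length_kb * total_fragments / 1e6)`.
#'
#' @param counts a [GeneCounts-class].
#' @param catalogue a [GeneCatalogue-class].
#' @param total_fragments library size; defaults to the retained read
#'   count stored in `counts`. Must be positive.
#' @return a [GeneProfile-class] with `normalization = "fpkm"`.
#' @export
normalizeFPKM <- function(counts, catalogue, total_fragments = NULL) {
    stopifnot(is(counts, "GeneCounts"), is(catalogue, "GeneCatalogue"))
    if (is.null(total_fragments))
        total_fragments <- counts@n_reads_retained
    if (is.na(total_fragments) || total_fragments <= 0)
        stop("total fragment count must be positive for FPKM", call. = FALSE)
    lens <- geneLengths(catalogue)
    unknown <- setdiff(names(counts(counts)), names(lens))
    if (length(unknown))
        stop(sprintf("counts for genes absent from the catalogue: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             call. = FALSE)
    cnt <- counts(counts)
    L_kb <- lens[names(cnt)] / 1000
    vals <- cnt / (L_kb * total_fragments / 1e6)
    new("GeneProfile", sample_id = counts@sample_id,
        values = vals, normalization = "fpkm")
}

#' Reduce a gene profile to MSP abundances via signature genes
#'
#' For each MSP, the top `n_signature` signature genes (by centrality
#' rank) are taken; an MSP is called detected when at least
#' `detection_fraction` of them have non-zero abundance, and its
#' abundance is then the arithmetic mean of the normalized abundances of
#' all those signature genes, zeros included. Undetected MSPs get
#' abundance 0. The default detection fraction is 0.10; fast mode uses
#' 0.20 to guard against the higher misalignment risk of the reduced
#' catalogue.
#'
#' @param profile a [GeneProfile-class].
#' @param catalogue a [GeneCatalogue-class].
#' @param n_signature signature genes per MSP to use (default 100,
#'   capped at the number available).
#' @param detection_fraction fraction of the used signature genes that
#'   must be detected; `NULL` picks 0.10/0.20 from the catalogue mode.
#' @param mean_detected_only if `TRUE`, average only over detected
#'   signature genes instead of all used ones (non-default variant).
#' @return an [MSPProfile-class] covering every catalogue MSP.
#' @export
mspAbundance <- function(profile, catalogue, n_signature = 100L,
                         detection_fraction = NULL,
                         mean_detected_only = FALSE) {
    stopifnot(is(profile, "GeneProfile"), is(catalogue, "GeneCatalogue"))
    if (is.null(detection_fraction))
        detection_fraction <-
            if (catalogueMode(catalogue) == "fast") 0.20 else 0.10
    vals <- profileValues(profile)
    msp_ids <- mspIds(catalogue)
    ab <- setNames(numeric(length(msp_ids)), msp_ids)
    n_used_min <- NA_integer_
    for (m in msp_ids) {
        sig <- signatureGenes(catalogue, m, n = n_signature)
        if (!length(sig)) {
            warning(sprintf("MSP '%s' has no signature genes; abundance 0", m),
                    call. = FALSE)
            next
        }
        v <- ifelse(sig %in% names(vals), vals[sig], 0)
        n_used <- length(sig)
        detected <- sum(v > 0)
        if (detected < detection_fraction * n_used) next
        ab[m] <- if (mean_detected_only) mean(v[v > 0]) else mean(v)
    }
    new("MSPProfile", sample_id = profile@sample_id, abundances = ab,
        detection_fraction = detection_fraction,
        n_signature = as.integer(n_signature))
}

#' Convert an MSP profile to relative abundances
#'
#' @param msp an [MSPProfile-class] with at least one detected MSP.
#' @return an [MSPProfile-class] whose abundances sum to 1 (zeros kept).
#' @export
relativeAbundance <- function(msp) {
    stopifnot(is(msp, "MSPProfile"))
    tot <- sum(msp@abundances)
    if (tot <= 0)
        stop("cannot compute relative abundances of an all-zero profile",
             call. = FALSE)
    initialize(msp, abundances = msp@abundances / tot)
}

#' Species richness of an MSP profile
#'
#' Number of MSPs with non-zero abundance (alpha diversity as richness).
#'
#' @param msp an [MSPProfile-class].
#' @return integer count.
#' @export
mspRichness <- function(msp) {
    stopifnot(is(msp, "MSPProfile"))
    sum(msp@abundances > 0)
}

#' Merge per-sample MSP profiles into a matrix
#'
#' @param profiles list of [MSPProfile-class] objects over the same
#'   catalogue.
#' @return numeric matrix, MSPs in rows, samples in columns.
#' @export
mergeMSPProfiles <- function(profiles) {
    stopifnot(length(profiles) >= 1)
    ids <- names(abundances(profiles[[1]]))
    mat <- vapply(profiles, function(p) abundances(p)[ids],
                  numeric(length(ids)))
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(profiles))
    rownames(mat) <- ids
    colnames(mat) <- vapply(profiles, sampleId, character(1))
    mat
}

#' Write an MSP profile
#'
#' @param x an [MSPProfile-class].
#' @param path output TSV path.
#' @param header optional named list written as `# key: value` comments.
#' @return `path`, invisibly.
#' @export
writeMSPProfile <- function(x, path, header = list()) {
    stopifnot(is(x, "MSPProfile"))
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(header))
        writeLines(sprintf("# %s: %s", k, header[[k]]), con)
    df <- data.frame(msp_id = names(x@abundances),
                     abundance = signif(x@abundances, 6))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
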
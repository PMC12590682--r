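#' @importFrom data.table data.table setkey := .N .SD setnames rbindlist
NULL

## Reads a SAM or BAM into a data.table of alignment records.
## SAM input is converted on the fly with Rsamtools::asBam.
.readAlignmentTable <- function(path, with_seq = FALSE) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        bam <- Rsamtools::asBam(path,
                                destination = tempfile(fileext = ""),
                                overwrite = TRUE, indexDestination = FALSE)
    } else bam <- path
    what <- c("qname", "flag", "rname", "pos", "cigar")
    if (with_seq) what <- c(what, "seq", "qual")
    param <- Rsamtools::ScanBamParam(what = what, tag = c("NM"))
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    n <- length(res$qname)
    dt <- data.table(
        read_id = res$qname,
        flag = res$flag,
        gene_id = as.character(res$rname),
        pos = res$pos,
        cigar = res$cigar,
        edit_distance = if (is.null(res$tag$NM)) rep(NA_integer_, n)
                        else res$tag$NM
    )
    if (with_seq) {
        dt$seq <- as.character(res$seq)
        dt$qual <- as.character(res$qual)
    }
    dt
}

## Expands a raw alignment table: drops unmapped and duplicate-flagged
## records, derives mate index and aligned length, computes identity.
## Records with a missing NM tag are dropped with a warning counter.
.prepareAlignments <- function(dt) {
    n_total_records <- nrow(dt)
    mapped <- bitwAnd(dt$flag, 0x4L) == 0L & !is.na(dt$gene_id)
    dup <- bitwAnd(dt$flag, 0x400L) != 0L
    dt <- dt[mapped & !dup]
    n_missing_nm <- sum(is.na(dt$edit_distance))
    if (n_missing_nm > 0L) {
        warning(sprintf("%d alignment record(s) without NM tag dropped",
                        n_missing_nm), call. = FALSE)
        dt <- dt[!is.na(dt$edit_distance)]
    }
    mate <- ifelse(bitwAnd(dt$flag, 0x80L) != 0L, 2L, 1L)
    aligned_length <- GenomicAlignments::cigarWidthAlongQuerySpace(
        dt$cigar, after.soft.clipping = TRUE)
    dt[, `:=`(mate = mate, aligned_length = aligned_length)]
    dt[, identity := (aligned_length - edit_distance) / aligned_length]
    # each mate of a pair is an independent read for counting purposes
    dt[, read_key := paste0(read_id, "/", mate)]
    attr(dt, "n_missing_nm") <- n_missing_nm
    dt
}

#' Alignment identity
#'
#' Fraction of aligned bases matching the reference, computed from the
#' aligned length and the edit distance (SAM `NM` tag):
#' `(aligned_length - edit_distance) / aligned_length`. Alignments are
#' retained when identity reaches 0.95 (complete mode) or 0.98 (fast
#' mode).
#'
#' @param aligned_length number of aligned query bases.
#' @param edit_distance SAM NM tag value.
#' @return identity fraction in \[0, 1\] (vectorized).
#' @examples
#' alignmentIdentity(80, 4)  # 0.95, the complete-mode threshold
#' @export
alignmentIdentity <- function(aligned_length, edit_distance) {
    stopifnot(all(aligned_length > 0), all(edit_distance >= 0))
    (aligned_length - edit_distance) / aligned_length
}

#' Read and filter alignments into per-read groups
#'
#' Parses a SAM/BAM file aligned against the catalogue, drops unmapped,
#' duplicate-flagged and NM-less records, applies the identity filter and
#' groups the surviving records by read. Within a group, multiple
#' alignments of the same read to the same gene are collapsed to the best
#' (highest-identity) record, so multi-mapping always means distinct
#' genes. Secondary and supplementary alignments participate normally:
#' multi-mapping is the point of shared counting. For paired data each
#' mate is an independent read.
#'
#' @param path SAM or BAM file (name-sorted or name-grouped).
#' @param catalogue a [GeneCatalogue-class]; alignments to genes absent
#'   from it are an error.
#' @param min_identity identity threshold; default 0.95, use 0.98 for
#'   fast mode.
#' @param n_reads_total optional total read count of the sample (for the
#'   mapping rate); defaults to the number of distinct reads seen in the
#'   file, mapped or not.
#' @return an `AlignmentGroups` object: a list with `groups` (data.table
#'   of read_key/gene_id/identity), `n_reads_retained`, `n_reads_total`
#'   and `n_reads_dropped` (reads whose every alignment failed a filter).
#' @seealso [countReads()]
#' @export
filterAlignments <- function(path, catalogue, min_identity = 0.95,
                             n_reads_total = NULL) {
    stopifnot(is(catalogue, "GeneCatalogue"))
    raw <- .readAlignmentTable(path)
    seen_reads <- length(unique(raw$read_id[bitwAnd(raw$flag, 0x80L) == 0L]))
    seen_reads <- seen_reads +
        length(unique(raw$read_id[bitwAnd(raw$flag, 0x80L) != 0L]))
    dt <- .prepareAlignments(raw)
    unknown <- setdiff(unique(dt$gene_id), geneIds(catalogue))
    if (length(unknown))
        stop(sprintf("alignments reference genes absent from the catalogue: %s",
                     paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
    n_candidates <- length(unique(dt$read_key))
    dt <- dt[identity >= min_identity]
    # best record per (read, gene)
    dt <- dt[order(read_key, gene_id, -identity)]
    dt <- dt[!duplicated(dt[, c("read_key", "gene_id")])]
    groups <- dt[, c("read_key", "gene_id", "identity")]
    n_retained <- length(unique(groups$read_key))
    structure(list(
        groups = groups,
        n_reads_retained = n_retained,
        n_reads_dropped = n_candidates - n_retained,
        n_reads_total = if (is.null(n_reads_total)) seen_reads
                        else as.integer(n_reads_total)
    ), class = "AlignmentGroups")
}

#' @export
print.AlignmentGroups <- function(x, ...) {
    cat("AlignmentGroups:", x$n_reads_retained, "reads retained (",
        x$n_reads_dropped, "dropped by filters ) over",
        length(unique(x$groups$gene_id)), "genes\n")
    invisible(x)
}

.countUnique <- function(groups) {
    dt <- groups$groups
    if (!nrow(dt)) return(numeric())
    sizes <- dt[, .N, by = read_key]
    uni <- dt[dt$read_key %in% sizes$read_key[sizes$N == 1L]]
    tab <- uni[, .N, by = gene_id]
    setNames(as.numeric(tab$N), tab$gene_id)
}

.countTotal <- function(groups) {
    dt <- groups$groups
    if (!nrow(dt)) return(numeric())
    tab <- dt[, .N, by = gene_id]
    setNames(as.numeric(tab$N), tab$gene_id)
}

.countShared <- function(groups) {
    dt <- data.table::copy(groups$groups)
    if (!nrow(dt)) return(numeric())
    u <- .countUnique(groups)
    dt[, n_genes := .N, by = read_key]
    dt[, u_gene := ifelse(gene_id %in% names(u), u[gene_id], 0)]
    dt[, u_sum := sum(u_gene), by = read_key]
    dt[, w := ifelse(n_genes == 1L, 1,
              ifelse(u_sum > 0, u_gene / u_sum, 1 / n_genes))]
    # weights are summed in sorted order so results are bit-identical
    # under any permutation of the input reads
    tab <- dt[, list(count = sum(sort(w))), by = gene_id]
    cnt <- setNames(tab$count, tab$gene_id)
    cnt[cnt > 0]
}

#' Count reads per gene
#'
#' Reduces filtered alignment groups to a per-gene count table under one
#' of three modes. `unique` counts only reads aligning to a single gene.
#' `total` credits every gene a read aligns to with 1. `shared` (the
#' default) apportions each multi-mapped read across the n genes it
#' aligns to in proportion to each gene's unique-read count; when all
#' those unique counts are zero the read is split evenly (1/n each).
#' Shared counting conserves read mass: the counts sum to the number of
#' retained reads.
#'
#' @param groups an `AlignmentGroups` object from [filterAlignments()].
#' @param mode `"shared"` (default), `"unique"` or `"total"`.
#' @param sample_id sample identifier stored in the result.
#' @return a [GeneCounts-class].
#' @examples
#' \dontrun{
#' grp <- filterAlignments("sample1.sam", cat)
#' counts(countReads(grp, "shared", "sample1"))
#' }
#' @export
countReads <- function(groups, mode = c("shared", "unique", "total"),
                       sample_id = "sample") {
    mode <- match.arg(mode)
    stopifnot(inherits(groups, "AlignmentGroups"))
    cnt <- switch(mode,
        unique = .countUnique(groups),
        total  = .countTotal(groups),
        shared = .countShared(groups))
    if (length(cnt)) cnt <- cnt[order(names(cnt))]
    new("GeneCounts", sample_id = sample_id, counts = cnt, mode = mode,
        n_reads_retained = as.integer(groups$n_reads_retained),
        n_reads_total = as.integer(groups$n_reads_total))
}

#' Write a gene count table
#'
#' @param x a [GeneCounts-class].
#' @param path output TSV path.
#' @param header optional named list written as `# key: value` comments.
#' @return `path`, invisibly.
#' @export
writeGeneCounts <- function(x, path, header = list()) {
    stopifnot(is(x, "GeneCounts"))
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(header))
        writeLines(sprintf("# %s: %s", k, header[[k]]), con)
    writeLines(sprintf("# sample: %s\n# mode: %s\n# reads_retained: %d",
                       x@sample_id, x@mode, x@n_reads_retained), con)
    df <- data.frame(gene_id = names(x@counts),
                     count = formatC(x@counts, format = "g", digits = 10))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
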
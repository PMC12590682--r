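#' Generate a synthetic gene catalogue with known ground truth
#'
#' Builds a random but fully structured catalogue: `n_msps` MSPs of
#' `genes_per_msp` random DNA genes each (uniform base composition),
#' plus `n_unclustered` genes outside any MSP. The first
#' `min(n_signature, genes_per_msp)` genes of each MSP are its signature
#' genes, ranked by index (rank 1 most central). Genes are annotated
#' with KEGG-ortholog-like terms at `annotation_density`, a smaller
#' fraction with CAZyme families and ARG labels, and a handful of
#' multi-step module definitions referencing the sampled KO terms are
#' included. Within each MSP a few pairs of accessory (non-signature)
#' genes are generated as near-identical homologous copies
#' (`homolog_divergence` substitutions per site) so that read simulation
#' can place reads ambiguously and exercise shared counting; signature
#' genes are never homologs, keeping taxonomic quantification clean.
#'
#' The same seed reproduces the catalogue byte-for-byte.
#'
#' @param n_msps number of MSPs.
#' @param genes_per_msp genes per MSP.
#' @param gene_length_range inclusive range of gene lengths (nt).
#' @param n_unclustered genes outside any MSP.
#' @param annotation_density fraction of genes carrying a KO term.
#' @param n_signature signature genes per MSP (capped at genes_per_msp).
#' @param n_homolog_pairs near-identical accessory gene pairs per MSP.
#' @param homolog_divergence per-site divergence between homolog copies.
#' @param seed integer seed.
#' @param directory if non-NULL, the catalogue is also written there via
#'   [writeCatalogue()].
#' @return list with `catalogue` (a [GeneCatalogue-class]) and `truth`
#'   (list with `homolog_partner`, a named map used by
#'   [simulateSample()], and the seed).
#' @export
generateCatalogue <- function(n_msps = 5L, genes_per_msp = 120L,
                              gene_length_range = c(300L, 1500L),
                              n_unclustered = 20L,
                              annotation_density = 0.6,
                              n_signature = 100L,
                              n_homolog_pairs = 5L,
                              homolog_divergence = 0.02,
                              seed = 1L, directory = NULL) {
    stopifnot(n_msps >= 1, genes_per_msp >= 1, n_unclustered >= 0)
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(L) paste(sample(bases, L, replace = TRUE),
                                  collapse = "")
    msp_ids <- sprintf("msp_%03d", seq_len(n_msps))
    gene_rows <- list()
    msp_rows <- list()
    seqs <- character()
    homolog_partner <- character()
    n_sig <- min(n_signature, genes_per_msp)
    for (m in seq_len(n_msps)) {
        ids <- sprintf("%s_gene_%04d", msp_ids[m], seq_len(genes_per_msp))
        lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                       genes_per_msp, replace = TRUE)
        sq <- vapply(lens, rand_seq, character(1))
        # accessory homolog pairs: B is a slightly diverged copy of A
        acc <- which(seq_len(genes_per_msp) > n_sig)
        n_pairs <- min(n_homolog_pairs, floor(length(acc) / 2))
        if (n_pairs > 0) {
            for (k in seq_len(n_pairs)) {
                a <- acc[2 * k - 1]; b <- acc[2 * k]
                lens[b] <- lens[a]
                sq[b] <- .mutateSequence(sq[a], homolog_divergence)
                homolog_partner[ids[a]] <- ids[b]
                homolog_partner[ids[b]] <- ids[a]
            }
        }
        gene_rows[[m]] <- data.frame(gene_id = ids, length = lens)
        msp_rows[[m]] <- data.frame(
            msp_id = msp_ids[m], gene_id = ids,
            signature_rank = c(seq_len(n_sig),
                               rep(NA_integer_, genes_per_msp - n_sig)))
        seqs <- c(seqs, setNames(sq, ids))
    }
    if (n_unclustered > 0) {
        ids <- sprintf("unclustered_gene_%04d", seq_len(n_unclustered))
        lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                       n_unclustered, replace = TRUE)
        sq <- vapply(lens, rand_seq, character(1))
        gene_rows[[n_msps + 1L]] <- data.frame(gene_id = ids, length = lens)
        seqs <- c(seqs, setNames(sq, ids))
    }
    genes <- do.call(rbind, gene_rows)
    msps <- do.call(rbind, msp_rows)

    ko_pool <- sprintf("K%05d", seq_len(40))
    caz_pool <- c("GH13", "GH2", "GT4", "PL1", "CE1", "AA3")
    ann <- list()
    ko_sel <- stats::runif(nrow(genes)) < annotation_density
    if (any(ko_sel))
        ann$ko <- data.frame(namespace = "KO",
                             gene_id = genes$gene_id[ko_sel],
                             term = sample(ko_pool, sum(ko_sel),
                                           replace = TRUE))
    caz_sel <- stats::runif(nrow(genes)) < 0.15
    if (any(caz_sel))
        ann$caz <- data.frame(namespace = "CAZyme",
                              gene_id = genes$gene_id[caz_sel],
                              term = sample(caz_pool, sum(caz_sel),
                                            replace = TRUE))
    arg_sel <- stats::runif(nrow(genes)) < 0.02
    if (any(arg_sel))
        ann$arg <- data.frame(namespace = "ARG_resfinder",
                              gene_id = genes$gene_id[arg_sel],
                              term = "resistance")
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL

    mod_defs <- c(
        mod_001 = sprintf("%s (%s,%s)", ko_pool[1], ko_pool[2], ko_pool[3]),
        mod_002 = sprintf("%s %s %s %s", ko_pool[4], ko_pool[5],
                          ko_pool[6], ko_pool[7]),
        mod_003 = sprintf("%s+%s (%s,%s+%s)", ko_pool[8], ko_pool[9],
                          ko_pool[10], ko_pool[11], ko_pool[12]))
    modules <- lapply(names(mod_defs), function(id)
        parseModuleDefinition(mod_defs[[id]], module_id = id))
    names(modules) <- names(mod_defs)

    cat <- GeneCatalogue(
        genes = genes,
        sequences = Biostrings::DNAStringSet(seqs),
        msps = msps, annotations = annotations, modules = modules,
        mode = "complete")
    if (!is.null(directory)) writeCatalogue(cat, directory)
    list(catalogue = cat,
         truth = list(homolog_partner = homolog_partner, seed = seed))
}

## Substitute each base independently with probability `rate` (uniform
## choice among the three other bases). Returns the mutated string.
.mutateSequence <- function(s, rate) {
    if (rate <= 0) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        chars[hit] <- vapply(chars[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
    }
    paste(chars, collapse = "")
}

#' Plant a strain of an MSP by mutating its genes
#'
#' Returns a per-site mutated copy of one MSP's gene sequences, the
#' sample-specific "strain" used by [simulateSample()]. Substitutions
#' are uniform; no indels are introduced (the strain stage's site model
#' considers substitutions only).
#'
#' @param catalogue a [GeneCatalogue-class] with sequences.
#' @param msp_id MSP whose genes to mutate.
#' @param rate per-site substitution probability.
#' @param seed integer seed.
#' @return list with `sequences` ([Biostrings::DNAStringSet] named by
#'   gene_id), `n_substitutions` and `realized_rate`.
#' @export
mutateStrain <- function(catalogue, msp_id, rate, seed = 1L) {
    stopifnot(is(catalogue, "GeneCatalogue"))
    set.seed(seed)
    genes <- mspMembers(catalogue, msp_id)
    ref <- geneSequences(catalogue)[genes]
    out <- vapply(as.character(ref), .mutateSequence, character(1),
                  rate = rate, USE.NAMES = FALSE)
    n_sub <- sum(mapply(function(a, b)
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
        as.character(ref), out))
    total <- sum(Biostrings::width(ref))
    seqs <- Biostrings::DNAStringSet(out)
    names(seqs) <- genes
    list(sequences = seqs, n_substitutions = n_sub,
         realized_rate = n_sub / total)
}

#' Simulate a metagenomic sample as a name-sorted SAM file
#'
#' Draws single-end reads from the catalogue genes in proportion to MSP
#' relative abundance times the gene's effective length (so expected
#' depth coverage is uniform within an MSP and proportional to its
#' abundance), optionally from planted strain sequences
#' ([mutateStrain()]), applies uniform substitution sequencing errors,
#' and writes the alignments with correct positions and `NM` tags
#' (computed against the catalogue reference). A fraction of reads from
#' homologous accessory gene copies is additionally reported on the
#' partner copy (secondary alignment) when the alignment identity there
#' reaches the reporting floor, exercising multi-mapped counting.
#'
#' @param catalogue a [GeneCatalogue-class] with sequences.
#' @param msp_abundances named numeric of true relative abundances
#'   (must sum to 1); MSPs absent from the vector get no reads.
#' @param n_reads number of reads.
#' @param read_length read length in nt (default 80, matching the
#'   trimmed-read alignment convention).
#' @param error_rate per-base sequencing substitution rate.
#' @param multimap_fraction probability that a read from a
#'   homolog-paired gene is also reported on its partner copy.
#' @param strain_sequences optional named list `msp_id ->` DNAStringSet
#'   (as from [mutateStrain()]) replacing that MSP's reference for read
#'   generation.
#' @param homolog_partner named character map gene -> partner gene (from
#'   [generateCatalogue()] truth).
#' @param sam_path output SAM path.
#' @param sample_id read-name prefix.
#' @param seed integer seed.
#' @return list with `sam` (path) and `truth` (data.frame read_id,
#'   gene_id, msp_id, pos; plus the input abundances as attribute).
#' @export
simulateSample <- function(catalogue, msp_abundances, n_reads = 10000L,
                           read_length = 80L, error_rate = 0.001,
                           multimap_fraction = 0.1,
                           strain_sequences = NULL,
                           homolog_partner = character(),
                           sam_path = tempfile(fileext = ".sam"),
                           sample_id = "sample", seed = 1L) {
    stopifnot(is(catalogue, "GeneCatalogue"),
              abs(sum(msp_abundances) - 1) < 1e-8)
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    lens <- geneLengths(catalogue)
    memb <- catalogue@msps
    memb <- memb[memb$msp_id %in% names(msp_abundances), , drop = FALSE]
    gene_msp <- setNames(memb$msp_id, memb$gene_id)
    pool <- memb$gene_id[lens[memb$gene_id] >= read_length]
    if (!length(pool))
        stop("no gene long enough for the requested read length",
             call. = FALSE)
    eff <- pmax(lens[pool] - read_length + 1, 1)
    w <- msp_abundances[gene_msp[pool]] * eff
    if (any(w > 0)) w <- w / sum(w)
    dropped <- setdiff(names(msp_abundances)[msp_abundances > 0],
                       unique(gene_msp[pool]))
    if (length(dropped))
        warning(sprintf("MSPs with no eligible gene dropped: %s",
                        paste(dropped, collapse = ", ")), call. = FALSE)

    ref_chars <- lapply(as.character(geneSequences(catalogue)),
                        function(s) strsplit(s, "", fixed = TRUE)[[1]])
    src_chars <- ref_chars
    if (!is.null(strain_sequences)) {
        for (m in names(strain_sequences)) {
            ss <- strain_sequences[[m]]
            for (g in names(ss))
                src_chars[[g]] <- strsplit(as.character(ss[[g]]), "",
                                           fixed = TRUE)[[1]]
        }
    }

    origin <- sample(pool, n_reads, replace = TRUE, prob = w)
    low_repr <- names(msp_abundances)[msp_abundances > 0 &
        !names(msp_abundances) %in% gene_msp[origin]]
    if (length(low_repr))
        warning(sprintf("n_reads too small to represent MSP(s): %s",
                        paste(low_repr, collapse = ", ")), call. = FALSE)

    qual <- paste(rep("I", read_length), collapse = "")
    cigar <- paste0(read_length, "M")
    con <- file(sam_path, "w")
    on.exit(close(con))
    hdr <- c("@HD\tVN:1.6\tSO:queryname",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
    writeLines(hdr, con)

    read_ids <- sprintf("%s_read_%06d", sample_id, seq_len(n_reads))
    positions <- 1L + floor(stats::runif(n_reads) *
                            (lens[origin] - read_length + 1L))
    out <- vector("character", 2L * n_reads)
    k <- 0L
    for (i in seq_len(n_reads)) {
        g <- origin[i]
        p <- positions[i]
        rd <- src_chars[[g]][p:(p + read_length - 1L)]
        err <- which(stats::runif(read_length) < error_rate)
        if (length(err))
            rd[err] <- vapply(rd[err], function(b)
                sample(setdiff(bases, b), 1L), character(1))
        nm <- sum(rd != ref_chars[[g]][p:(p + read_length - 1L)])
        seq_str <- paste(rd, collapse = "")
        k <- k + 1L
        out[k] <- sprintf("%s\t0\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                          read_ids[i], g, p, cigar, seq_str, qual, nm)
        partner <- if (g %in% names(homolog_partner))
            homolog_partner[[g]] else NA_character_
        if (!is.na(partner) && stats::runif(1) < multimap_fraction) {
            Lp <- lens[[partner]]
            pp <- min(p, Lp - read_length + 1L)
            nm2 <- sum(rd != ref_chars[[partner]][pp:(pp + read_length - 1L)])
            if ((read_length - nm2) / read_length >= 0.9) {
                k <- k + 1L
                out[k] <- sprintf(
                    "%s\t256\t%s\t%d\t0\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                    read_ids[i], partner, pp, cigar, seq_str, qual, nm2)
            }
        }
    }
    writeLines(out[seq_len(k)], con)
    truth <- data.frame(read_id = read_ids,
                        gene_id = origin,
                        msp_id = unname(gene_msp[origin]),
                        pos = positions)
    attr(truth, "msp_abundances") <- msp_abundances
    list(sam = sam_path, truth = truth)
}

#' Evaluate an estimated MSP profile against ground truth
#'
#' Presence/absence metrics (sensitivity, specificity, F1), richness
#' error and Bray-Curtis dissimilarity between log10-transformed
#' relative-abundance profiles. The log transform is
#' `log10(1 + x / pseudo)` with pseudocount `pseudo` set to one tenth of
#' the smallest positive abundance across both profiles, which keeps the
#' transformed values non-negative and gives 0 dissimilarity for a
#' perfect profile.
#'
#' @param estimated an [MSPProfile-class] (relative or raw; converted to
#'   relative internally).
#' @param truth named numeric vector of true relative abundances
#'   (absent MSPs count as 0).
#' @return list: `sensitivity`, `specificity`, `f1`, `richness_delta`,
#'   `bray_curtis_log10`.
#' @export
evaluateProfile <- function(estimated, truth) {
    stopifnot(is(estimated, "MSPProfile"))
    est <- abundances(relativeAbundance(estimated))
    ids <- names(est)
    tr <- setNames(numeric(length(ids)), ids)
    tr[intersect(names(truth), ids)] <- truth[intersect(names(truth), ids)]
    if (sum(tr) > 0) tr <- tr / sum(tr)
    tp <- sum(est > 0 & tr > 0)
    fp <- sum(est > 0 & tr == 0)
    fn <- sum(est == 0 & tr > 0)
    tn <- sum(est == 0 & tr == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    pos <- c(est[est > 0], tr[tr > 0])
    pseudo <- if (length(pos)) min(pos) * 0.1 else 1e-6
    le <- log10(1 + est / pseudo)
    lt <- log10(1 + tr / pseudo)
    bc <- as.numeric(vegan::vegdist(rbind(le, lt), method = "bray"))
    list(sensitivity = sens, specificity = spec, f1 = f1,
         richness_delta = sum(est > 0) - sum(tr > 0),
         bray_curtis_log10 = bc)
}
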
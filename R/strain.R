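## IUPAC ambiguity code <-> base-set lookup used throughout the strain
## stage ('N' is a mask, never an allele).
.IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"))

## code for a sorted, unique base combination (key: concatenated bases)
.IUPAC_CODES <- c(
    A = "A", C = "C", G = "G", T = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
    CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")

.iupacCode <- function(bases) {
    if (length(bases) == 1L) return(bases)
    .IUPAC_CODES[[paste(sort(bases), collapse = "")]]
}

#' Read alignments for strain analysis
#'
#' Like [filterAlignments()] but retains read sequences and base
#' qualities, which the pileup needs. Returns the filtered per-record
#' table (best record per read/gene pair).
#'
#' @param path SAM or BAM file.
#' @param catalogue a [GeneCatalogue-class].
#' @param min_identity identity threshold (0.95 complete / 0.98 fast).
#' @return data.table of records: read_key, gene_id, pos, cigar, seq,
#'   qual, identity.
#' @export
readStrainAlignments <- function(path, catalogue, min_identity = 0.95) {
    stopifnot(is(catalogue, "GeneCatalogue"))
    raw <- .readAlignmentTable(path, with_seq = TRUE)
    dt <- .prepareAlignments(raw)
    unknown <- setdiff(unique(dt$gene_id), geneIds(catalogue))
    if (length(unknown))
        stop(sprintf("alignments reference genes absent from the catalogue: %s",
                     paste(head(unknown, 5), collapse = ", ")), call. = FALSE)
    dt <- dt[identity >= min_identity]
    dt <- dt[order(read_key, gene_id, -identity)]
    dt <- dt[!duplicated(dt[, c("read_key", "gene_id")])]
    dt
}

## Per-gene pileup: 4 x L matrix of base counts from alignment records
## restricted to one gene. Bases below the quality floor are not counted;
## insertions are skipped and deletions contribute nothing (indels are
## outside the site model).
.pileupGene <- function(dt, gene_length, min_base_quality = 13L) {
    if (!nrow(dt))
        return(matrix(0L, nrow = 4L, ncol = gene_length,
                      dimnames = list(c("A", "C", "G", "T"), NULL)))
    if (all(grepl("^[0-9]+M$", dt$cigar))) {
        # plain gapless alignments: query space == reference space
        laid <- dt$seq
        laidq <- dt$qual
    } else {
        laid <- as.character(GenomicAlignments::sequenceLayer(
            Biostrings::DNAStringSet(dt$seq), dt$cigar))
        laidq <- as.character(GenomicAlignments::sequenceLayer(
            Biostrings::BStringSet(dt$qual), dt$cigar))
    }
    nch <- nchar(laid)
    base <- strsplit(paste(laid, collapse = ""), "", fixed = TRUE)[[1]]
    q <- utf8ToInt(paste(laidq, collapse = "")) - 33L
    p <- rep(dt$pos, nch) + sequence(nch) - 1L
    bi <- match(base, c("A", "C", "G", "T"))
    keep <- !is.na(bi) & q >= min_base_quality & p >= 1L & p <= gene_length
    idx <- (p[keep] - 1L) * 4L + bi[keep]
    matrix(tabulate(idx, nbins = 4L * gene_length), nrow = 4L,
           dimnames = list(c("A", "C", "G", "T"), NULL))
}

## Site-level consensus rules applied to a 4 x L count matrix.
## Returns the consensus character vector.
.consensusFromCounts <- function(cnt, ref_chars, f, min_depth) {
    L <- ncol(cnt)
    depth <- colSums(cnt)
    cons <- rep("N", L)
    covered <- which(depth >= min_depth)
    if (!length(covered)) return(cons)
    n_alleles <- colSums(cnt > 0)
    mono <- covered[n_alleles[covered] == 1L]
    if (length(mono)) {
        best <- max.col(t(cnt[, mono, drop = FALSE]), ties.method = "first")
        cons[mono] <- rownames(cnt)[best]
    }
    poly <- covered[n_alleles[covered] > 1L]
    for (p in poly) {
        cvec <- cnt[, p]
        d <- depth[p]
        if (f >= 0.5) {
            # dominant configuration: major allele, ties become ambiguity
            mx <- max(cvec)
            set <- rownames(cnt)[cvec == mx]
        } else {
            ref <- ref_chars[p]
            set <- rownames(cnt)[cvec / d >= f & rownames(cnt) != ref]
            if (ref %in% rownames(cnt) && cvec[ref] > 0)
                set <- c(ref, set)
            if (!length(set)) {
                mx <- max(cvec)
                set <- rownames(cnt)[cvec == mx]
            }
        }
        cons[p] <- .iupacCode(set)
    }
    cons
}

#' Pileup consensus for one gene
#'
#' Calls a per-position consensus for one catalogue gene from filtered
#' alignments, applying the site model: positions with depth below
#' `min_depth` (default 3) are masked `N`; otherwise the allele set is
#' the reference base (when it has read support) plus every non-reference
#' base at frequency at least `f`, encoded as the IUPAC code of the set
#' (with a majority-base fallback if the set comes out empty). The
#' dominant configuration `f = 0.5` keeps only the major allele, ties
#' becoming the IUPAC code of the tied set; the mixed configuration
#' `f = 0.1` encodes strain mixtures as ambiguity codes. Each site is
#' evaluated independently and indels are ignored.
#'
#' @param alignments data.table from [readStrainAlignments()].
#' @param catalogue a [GeneCatalogue-class] with sequences.
#' @param gene_id gene to call.
#' @param f minimum non-reference allele frequency in (0, 1].
#' @param min_depth minimum depth below which a site is masked.
#' @param min_base_quality Phred floor for counted bases.
#' @return list with `consensus` (single string), `depth` (integer
#'   vector), `counts` (4 x L matrix) and `breadth` (fraction of
#'   positions with depth >= `min_depth`).
#' @export
pileupConsensus <- function(alignments, catalogue, gene_id, f = 0.1,
                            min_depth = 3L, min_base_quality = 13L) {
    stopifnot(is(catalogue, "GeneCatalogue"), f > 0, f <= 1)
    if (!gene_id %in% geneIds(catalogue))
        stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
    if (!gene_id %in% names(geneSequences(catalogue)))
        stop(sprintf("gene '%s' has no sequence in the catalogue", gene_id),
             call. = FALSE)
    L <- unname(geneLengths(catalogue)[gene_id])
    sel <- which(alignments[["gene_id"]] == gene_id)
    sub <- alignments[sel]
    cnt <- .pileupGene(sub, L, min_base_quality)
    ref_chars <- strsplit(as.character(geneSequences(catalogue)[[gene_id]]),
                          "", fixed = TRUE)[[1]]
    cons <- .consensusFromCounts(cnt, ref_chars, f, min_depth)
    depth <- colSums(cnt)
    list(consensus = paste(cons, collapse = ""),
         depth = depth,
         counts = cnt,
         breadth = mean(depth >= min_depth))
}

#' Breadth filter for a consensus genotype
#'
#' A sample-specific MSP genotype is retained when enough of its
#' signature genes are well covered: at least `min_genes` out of
#' `of_genes` signature genes (80 of 100 by default) must have breadth
#' coverage of at least `min_breadth` (0.5). For MSPs with fewer than
#' `of_genes` signature genes the requirement scales proportionally
#' (rounded up).
#'
#' @param breadth named numeric vector of per-signature-gene breadths.
#' @param min_genes,of_genes the `min_genes`-out-of-`of_genes` rule.
#' @param min_breadth per-gene breadth threshold.
#' @return logical flag.
#' @export
breadthFilter <- function(breadth, min_genes = 80L, of_genes = 100L,
                          min_breadth = 0.5) {
    n_sig <- length(breadth)
    if (!n_sig) return(FALSE)
    required <- if (n_sig >= of_genes) min_genes
                else ceiling(min_genes / of_genes * n_sig)
    sum(breadth >= min_breadth) >= required
}

#' Sample-specific MSP consensus genotype
#'
#' Calls the consensus of every signature gene of one MSP in one sample
#' and applies the breadth filter.
#'
#' @param alignments data.table from [readStrainAlignments()].
#' @param catalogue a [GeneCatalogue-class] with gene sequences.
#' @param msp_id MSP to genotype.
#' @param sample_id sample identifier.
#' @param f,min_depth,min_base_quality site model parameters, see
#'   [pileupConsensus()].
#' @param n_signature number of top signature genes to use.
#' @param min_genes,of_genes,min_breadth breadth filter parameters, see
#'   [breadthFilter()].
#' @return a [ConsensusGenotype-class].
#' @export
consensusGenotype <- function(alignments, catalogue, msp_id, sample_id,
                              f = 0.1, min_depth = 3L,
                              min_base_quality = 13L, n_signature = 100L,
                              min_genes = 80L, of_genes = 100L,
                              min_breadth = 0.5) {
    stopifnot(is(catalogue, "GeneCatalogue"))
    sig <- signatureGenes(catalogue, msp_id, n = n_signature)
    if (!length(sig))
        stop(sprintf("MSP '%s' has no signature genes", msp_id),
             call. = FALSE)
    cons <- character(length(sig))
    breadth <- numeric(length(sig))
    lens <- geneLengths(catalogue)
    seqs_ref <- geneSequences(catalogue)
    by_gene <- split(seq_len(nrow(alignments)), alignments$gene_id)
    for (i in seq_along(sig)) {
        gid <- sig[i]
        if (!gid %in% names(seqs_ref))
            stop(sprintf("gene '%s' has no sequence in the catalogue", gid),
                 call. = FALSE)
        sub <- alignments[by_gene[[gid]] %||% integer()]
        cnt <- .pileupGene(sub, lens[[gid]], min_base_quality)
        ref_chars <- strsplit(as.character(seqs_ref[[gid]]), "",
                              fixed = TRUE)[[1]]
        cons[i] <- paste(.consensusFromCounts(cnt, ref_chars, f, min_depth),
                         collapse = "")
        breadth[i] <- mean(colSums(cnt) >= min_depth)
    }
    names(breadth) <- sig
    seqs <- Biostrings::DNAStringSet(cons)
    names(seqs) <- sig
    new("ConsensusGenotype", sample_id = sample_id, msp_id = msp_id,
        sequences = seqs, breadth = breadth,
        passed_filter = breadthFilter(breadth, min_genes, of_genes,
                                      min_breadth))
}

## ---- GTR pairwise distance ----------------------------------------------

## Divergence matrix over informative sites. Ambiguity handling:
## "intersect" (default) treats a site whose two allele sets overlap as
## a match distributed over the shared bases -- an ambiguous call is
## compatible with identity, as in a likelihood treatment of IUPAC codes
## as partially missing data -- and only disjoint sets contribute
## mismatches (spread uniformly over the Cartesian product).
## "cartesian" spreads every site pair 1/(|setA|*|setB|) over the full
## Cartesian product, so ambiguity always contributes some divergence.
.divergenceMatrix <- function(a_chars, b_chars,
                              ambiguity = c("intersect", "cartesian")) {
    ambiguity <- match.arg(ambiguity)
    F <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
    pair <- paste0(a_chars, b_chars)
    tab <- table(pair)
    for (k in seq_along(tab)) {
        pp <- names(tab)[k]
        sa <- .IUPAC_SETS[[substr(pp, 1, 1)]]
        sb <- .IUPAC_SETS[[substr(pp, 2, 2)]]
        n <- as.numeric(tab[k])
        shared <- intersect(sa, sb)
        if (ambiguity == "intersect" && length(shared)) {
            w <- n / length(shared)
            for (x in shared) F[x, x] <- F[x, x] + w
        } else {
            F[sa, sb] <- F[sa, sb] + n / (length(sa) * length(sb))
        }
    }
    F
}

#' General Time Reversible pairwise distance
#'
#' Closed-form GTR evolutionary distance between two inherently aligned
#' consensus sequences (substitutions only, no indels). Sites that are
#' `N` in either sequence are excluded; the remaining informative sites
#' build a 4 x 4 divergence matrix F. IUPAC ambiguity is handled by
#' `ambiguity`: `"intersect"` (default) counts a site whose two allele
#' sets overlap as a match on the shared bases — an ambiguous call is
#' compatible with identity, as in a likelihood treatment of ambiguity
#' as partially missing data — and only disjoint sets contribute
#' mismatches (uniformly over their Cartesian product); `"cartesian"`
#' spreads every site uniformly over the Cartesian product of the two
#' sets, so ambiguity always adds divergence. With the symmetrized, normalized
#' divergence matrix F-hat and Pi the diagonal matrix of empirical
#' equilibrium frequencies, the distance is
#' `d = -sum_i pi_i * log(Pi^-1 F-hat)_ii`, the standard
#' paralinear/log-det form of the GTR distance with empirical
#' frequencies. Identical sequences give exactly 0. When the matrix
#' logarithm does not exist (saturation) or fewer than `min_informative`
#' sites are available the distance is missing (`NA`).
#'
#' @param a,b character strings over the IUPAC + N alphabet, same length.
#' @param min_informative minimum number of informative (non-N in both)
#'   sites.
#' @param ambiguity IUPAC handling, `"intersect"` or `"cartesian"` (see
#'   Details).
#' @return list with `mutation_rate` (numeric or NA), `informative_sites`
#'   and `reason` (`"ok"`, `"too_few_informative_sites"`,
#'   `"saturated"`).
#' @examples
#' gtrDistance("ACGTACGTACGTA", "ACGTACGTACGTA", min_informative = 10)
#' @export
gtrDistance <- function(a, b, min_informative = 10L,
                        ambiguity = c("intersect", "cartesian")) {
    ambiguity <- match.arg(ambiguity)
    stopifnot(nchar(a) == nchar(b))
    a_chars <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
    b_chars <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
    informative <- a_chars != "N" & b_chars != "N"
    n_inf <- sum(informative)
    if (n_inf < min_informative)
        return(list(mutation_rate = NA_real_, informative_sites = n_inf,
                    reason = "too_few_informative_sites"))
    F <- .divergenceMatrix(a_chars[informative], b_chars[informative],
                           ambiguity = ambiguity)
    F <- F / sum(F)
    Fhat <- (F + t(F)) / 2
    pi <- rowSums(Fhat)
    keep <- pi > 0
    M <- diag(1 / pi[keep], sum(keep)) %*% Fhat[keep, keep, drop = FALSE]
    eig <- eigen(M)
    if (any(Re(eig$values) <= 0) ||
        any(abs(Im(eig$values)) > 1e-8 * pmax(abs(Re(eig$values)), 1)))
        return(list(mutation_rate = NA_real_, informative_sites = n_inf,
                    reason = "saturated"))
    logM <- eig$vectors %*% diag(log(Re(eig$values)), sum(keep)) %*%
        solve(eig$vectors)
    if (any(abs(Im(logM)) > 1e-8))
        return(list(mutation_rate = NA_real_, informative_sites = n_inf,
                    reason = "saturated"))
    d <- -sum(pi[keep] * Re(diag(logM)))
    list(mutation_rate = max(d, 0), informative_sites = n_inf,
         reason = "ok")
}

#' Pairwise mutation rate between two consensus genotypes
#'
#' Concatenates the signature-gene consensus sequences of two
#' sample-specific genotypes of the same MSP and computes their GTR
#' distance ([gtrDistance()]). Both genotypes must have passed the
#' breadth filter; the consensus sequences are inherently aligned since
#' variation is restricted to substitutions.
#'
#' @param a,b [ConsensusGenotype-class] objects with the same `msp_id`.
#' @param min_informative minimum informative sites (default 10).
#' @param ambiguity IUPAC handling, see [gtrDistance()].
#' @return one-row data.frame: `msp_id`, `sample_a`, `sample_b`,
#'   `informative_sites`, `mutation_rate` (NA when not computable),
#'   `reason`.
#' @export
pairwiseMutationRate <- function(a, b, min_informative = 10L,
                                 ambiguity = c("intersect", "cartesian")) {
    ambiguity <- match.arg(ambiguity)
    stopifnot(is(a, "ConsensusGenotype"), is(b, "ConsensusGenotype"))
    if (a@msp_id != b@msp_id)
        stop("genotypes belong to different MSPs", call. = FALSE)
    if (!a@passed_filter || !b@passed_filter)
        stop("both genotypes must pass the breadth filter", call. = FALSE)
    genes <- intersect(names(a@sequences), names(b@sequences))
    ca <- paste(as.character(a@sequences[genes]), collapse = "")
    cb <- paste(as.character(b@sequences[genes]), collapse = "")
    res <- gtrDistance(ca, cb, min_informative = min_informative,
                       ambiguity = ambiguity)
    data.frame(msp_id = a@msp_id, sample_a = a@sample_id,
               sample_b = b@sample_id,
               informative_sites = res$informative_sites,
               mutation_rate = res$mutation_rate,
               reason = res$reason, stringsAsFactors = FALSE)
}

#' Pairwise distance matrix for one MSP across samples
#'
#' Computes all pairwise mutation rates between the passing genotypes of
#' one MSP. MSPs present (passing) in fewer than 2 samples yield an
#' empty result with a message.
#'
#' @param genotypes list of [ConsensusGenotype-class] for one MSP.
#' @param min_informative see [pairwiseMutationRate()].
#' @param ambiguity IUPAC handling, see [gtrDistance()].
#' @return list with `matrix` (symmetric, zero diagonal, NA where not
#'   computable), `informative_sites` matrix, and `pairs` (long-format
#'   data.frame of the pairwise results).
#' @export
distanceMatrix <- function(genotypes, min_informative = 10L,
                           ambiguity = c("intersect", "cartesian")) {
    ambiguity <- match.arg(ambiguity)
    genotypes <- Filter(function(g) g@passed_filter, genotypes)
    if (length(genotypes) < 2L) {
        message("fewer than 2 samples with a passing genotype; ",
                "no distances computed")
        return(list(matrix = matrix(numeric(), 0, 0),
                    informative_sites = matrix(integer(), 0, 0),
                    pairs = data.frame()))
    }
    ids <- vapply(genotypes, sampleId, character(1))
    n <- length(ids)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    I <- matrix(0L, n, n, dimnames = list(ids, ids))
    rows <- list()
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        r <- pairwiseMutationRate(genotypes[[i]], genotypes[[j]],
                                  min_informative, ambiguity = ambiguity)
        D[i, j] <- D[j, i] <- r$mutation_rate
        I[i, j] <- I[j, i] <- r$informative_sites
        rows[[length(rows) + 1L]] <- r
    }
    list(matrix = D, informative_sites = I, pairs = do.call(rbind, rows))
}

#' Complete-linkage strain clustering
#'
#' Agglomerative clustering of samples from a pairwise mutation-rate
#' matrix, cut at `cutoff` (a mutation rate of 5e-3 corresponds to about
#' 99% nucleotide identity). Samples with any missing pairwise value are
#' reported unclustered (`NA`).
#'
#' @param mat symmetric mutation-rate matrix from [distanceMatrix()].
#' @param cutoff tree cut height (mutation rate).
#' @param linkage agglomeration method (default `"complete"`).
#' @return named integer vector of cluster ids; NA marks unclustered
#'   samples.
#' @export
strainClusters <- function(mat, cutoff, linkage = "complete") {
    stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
    out <- setNames(rep(NA_integer_, nrow(mat)), rownames(mat))
    offdiag_na <- apply(mat, 1, function(r) any(is.na(r)))
    ok <- !offdiag_na
    if (sum(ok) == 1L) {
        out[ok] <- 1L
        return(out)
    }
    if (sum(ok) >= 2L) {
        sub <- mat[ok, ok, drop = FALSE]
        hc <- stats::hclust(stats::as.dist(sub), method = linkage)
        out[ok] <- stats::cutree(hc, h = cutoff)
    }
    out
}

#' Donor-recipient strain engraftment rate
#'
#' The engraftment rate is the fraction of identical strains among all
#' pairs of conspecific strains identified in both a recipient and its
#' donor: for every MSP with a computed mutation rate between a
#' recipient sample and its paired donor sample, the pair counts as
#' identical when the mutation rate is at or below `identical_cutoff`
#' (default 1e-4).
#'
#' @param distances long-format data.frame of pairwise results (columns
#'   `msp_id`, `sample_a`, `sample_b`, `mutation_rate`), e.g. rbind of
#'   `distanceMatrix()$pairs` across MSPs.
#' @param pairs data.frame with columns `recipient_sample`,
#'   `donor_sample` (one row per recipient/timepoint).
#' @param identical_cutoff mutation rate at or below which two strains
#'   are called identical.
#' @return list with `rate` (fraction, or NA when no eligible pair),
#'   `n_identical`, `n_pairs`, and the eligible pair table.
#' @export
engraftmentRate <- function(distances, pairs, identical_cutoff = 1e-4) {
    stopifnot(all(c("msp_id", "sample_a", "sample_b", "mutation_rate") %in%
                  names(distances)),
              all(c("recipient_sample", "donor_sample") %in% names(pairs)))
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    want <- key(pairs$recipient_sample, pairs$donor_sample)
    have <- key(distances$sample_a, distances$sample_b)
    elig <- distances[have %in% want & !is.na(distances$mutation_rate), ,
                      drop = FALSE]
    if (!nrow(elig)) {
        message("no conspecific donor-recipient strain pair with a ",
                "computed distance")
        return(list(rate = NA_real_, n_identical = 0L, n_pairs = 0L,
                    pairs = elig))
    }
    ident <- elig$mutation_rate <= identical_cutoff
    list(rate = sum(ident) / nrow(elig), n_identical = sum(ident),
         n_pairs = nrow(elig), pairs = elig)
}

#' Write consensus genotypes as multi-FASTA
#'
#' One record per sample: the concatenated signature-gene consensus
#' (IUPAC + N alphabet) of one MSP.
#'
#' @param genotypes list of [ConsensusGenotype-class] for one MSP.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(genotypes, path) {
    seqs <- Biostrings::DNAStringSet(vapply(genotypes, function(g)
        paste(as.character(g@sequences), collapse = ""), character(1)))
    names(seqs) <- vapply(genotypes, sampleId, character(1))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
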
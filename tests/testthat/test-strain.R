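## Builds an alignment table covering one gene with a prescribed base
## column at one site: `depth` reads, `alt` of them carrying `alt_base`
## at position `site`. Reads span the whole (short) gene.
siteFixture <- function(ct, gene, site, depth, alt, alt_base,
                        ref_base = NULL) {
    L <- unname(geneLengths(ct)[gene])
    ref <- strsplit(as.character(geneSequences(ct)[[gene]]), "")[[1]]
    rows <- lapply(seq_len(depth), function(i) {
        rd <- ref
        if (i <= alt) rd[site] <- alt_base
        data.table::data.table(
            read_key = sprintf("r%03d/1", i), gene_id = gene, pos = 1L,
            cigar = paste0(L, "M"), seq = paste(rd, collapse = ""),
            qual = paste(rep("I", L), collapse = ""), identity = 1)
    })
    data.table::rbindlist(rows)
}

shortGeneCatalogue <- function(L = 30L) {
    set.seed(55)
    sq <- Biostrings::DNAStringSet(setNames(
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), "g1"))
    GeneCatalogue(data.frame(gene_id = "g1", length = L),
                  sequences = sq,
                  msps = data.frame(msp_id = "m1", gene_id = "g1",
                                    signature_rank = 1L))
}

test_that("consensus site rules: masking, mixed IUPAC, dominant allele", {
    ct <- shortGeneCatalogue()
    ref <- strsplit(as.character(geneSequences(ct)[["g1"]]), "")[[1]]
    site <- 10L
    alt_base <- setdiff(c("A", "C", "G", "T"), ref[site])[1]

    # depth 2 -> N regardless of agreement
    aln <- siteFixture(ct, "g1", site, depth = 2, alt = 0, alt_base)
    pc <- pileupConsensus(aln, ct, "g1", f = 0.1, min_depth = 3)
    expect_equal(substr(pc$consensus, site, site), "N")

    # depth 10, ref:alt = 9:1, f = 0.1 -> IUPAC code of {ref, alt}
    aln <- siteFixture(ct, "g1", site, depth = 10, alt = 1, alt_base)
    pc <- pileupConsensus(aln, ct, "g1", f = 0.1)
    want <- as.character(Biostrings::mergeIUPACLetters(
        paste(sort(c(ref[site], alt_base)), collapse = "")))
    expect_equal(substr(pc$consensus, site, site), want)

    # same counts, f = 0.5 (dominant) -> major allele only
    pc <- pileupConsensus(aln, ct, "g1", f = 0.5)
    expect_equal(substr(pc$consensus, site, site), ref[site])

    # non-reference majority without reference support -> alt base
    aln <- siteFixture(ct, "g1", site, depth = 10, alt = 10, alt_base)
    pc <- pileupConsensus(aln, ct, "g1", f = 0.1)
    expect_equal(substr(pc$consensus, site, site), alt_base)

    # alt below f stays reference
    aln <- siteFixture(ct, "g1", site, depth = 30, alt = 2, alt_base)
    pc <- pileupConsensus(aln, ct, "g1", f = 0.1)
    expect_equal(substr(pc$consensus, site, site), ref[site])
})

test_that("pileup base counts agree with Rsamtools::pileup", {
    g <- generateCatalogue(n_msps = 1, genes_per_msp = 5, n_unclustered = 0,
                           gene_length_range = c(300, 500),
                           n_signature = 5, seed = 13)
    ct <- g$catalogue
    sim <- simulateSample(ct, c(msp_001 = 1), n_reads = 1500,
                          error_rate = 0.01, multimap_fraction = 0,
                          seed = 14, sample_id = "px")
    aln <- readStrainAlignments(sim$sam, ct, min_identity = 0)
    bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
    pp <- Rsamtools::pileup(bam, pileupParam = Rsamtools::PileupParam(
        max_depth = 10000, min_base_quality = 13, min_mapq = 0,
        min_nucleotide_depth = 1, distinguish_strands = FALSE,
        include_insertions = FALSE))
    for (gid in geneIds(ct)[1:2]) {
        pc <- pileupConsensus(aln, ct, gid)
        sub <- pp[pp$seqnames == gid, ]
        for (b in c("A", "C", "G", "T")) {
            ours <- pc$counts[b, ]
            theirs <- integer(length(ours))
            rows <- sub[sub$nucleotide == b, ]
            theirs[rows$pos] <- rows$count
            expect_equal(unname(ours), theirs)
        }
    }
})

test_that("breadth filter applies the 80-of-100 rule with scaling", {
    expect_true(breadthFilter(c(rep(0.6, 80), rep(0.1, 20))))
    expect_false(breadthFilter(c(rep(0.6, 79), rep(0.1, 21))))
    # 50 signature genes -> scaled requirement 40
    expect_true(breadthFilter(c(rep(0.9, 41), rep(0, 9))))
    expect_true(breadthFilter(c(rep(0.9, 40), rep(0, 10))))
    expect_false(breadthFilter(c(rep(0.9, 39), rep(0, 11))))
    # breadth exactly at min_breadth counts
    expect_true(breadthFilter(rep(0.5, 100)))
    expect_false(breadthFilter(numeric()))
})

test_that("GTR distance: zero for identical, missing below informative floor", {
    p <- divergedPair(2000, 0, seed = 1)
    r <- gtrDistance(p$a, p$a)
    expect_identical(r$mutation_rate, 0)
    expect_equal(r$reason, "ok")
    # 9 informative sites -> missing
    a <- paste0(strrep("A", 9), strrep("N", 5))
    b <- paste0(strrep("A", 9), strrep("N", 5))
    r2 <- gtrDistance(a, b)
    expect_true(is.na(r2$mutation_rate))
    expect_equal(r2$informative_sites, 9)
    expect_equal(r2$reason, "too_few_informative_sites")
})

test_that("GTR distance recovers simulated divergence and the JC69 form", {
    for (d in c(0.005, 0.02)) {
        p <- divergedPair(60000, d, seed = round(1000 * d))
        jc <- -3 / 4 * log(1 - 4 * p$p_realized / 3)
        est <- gtrDistance(p$a, p$b)
        expect_equal(est$mutation_rate, jc, tolerance = 1e-3)
        expect_lt(abs(est$mutation_rate - d) / d, 0.2)
    }
})

test_that("ambiguity conventions differ as documented", {
    # A vs R: compatible under intersect (distance 0), half-mismatch
    # under cartesian (positive distance)
    a <- paste0(strrep("ACGT", 20), "A")
    b <- paste0(strrep("ACGT", 20), "R")
    expect_equal(gtrDistance(a, b, ambiguity = "intersect")$mutation_rate, 0)
    expect_gt(gtrDistance(a, b, ambiguity = "cartesian")$mutation_rate, 0)
})

test_that("raising min_depth never increases informative sites", {
    ct <- shortGeneCatalogue()
    aln <- siteFixture(ct, "g1", 5L, depth = 4, alt = 0, "A")
    n_inf <- function(md) {
        pc <- pileupConsensus(aln, ct, "g1", min_depth = md)
        sum(strsplit(pc$consensus, "")[[1]] != "N")
    }
    vals <- vapply(c(1L, 3L, 5L), n_inf, numeric(1))
    expect_true(all(diff(vals) <= 0))
})

test_that("dominant equals mixed on a pure single-strain fixture", {
    g <- generateCatalogue(n_msps = 1, genes_per_msp = 6, n_unclustered = 0,
                           gene_length_range = c(300, 500),
                           n_signature = 6, seed = 21)
    ct <- g$catalogue
    sim <- simulateSample(ct, c(msp_001 = 1), n_reads = 3000,
                          error_rate = 0, multimap_fraction = 0,
                          seed = 22, sample_id = "pure")
    aln <- readStrainAlignments(sim$sam, ct)
    gm <- consensusGenotype(aln, ct, "msp_001", "pure", f = 0.1)
    gd <- consensusGenotype(aln, ct, "msp_001", "pure", f = 0.5)
    expect_identical(as.character(genotypeSequences(gm)),
                     as.character(genotypeSequences(gd)))
})

test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
    set.seed(33)
    seqs <- replicate(4, divergedPair(3000, 0.01, seed = sample(1e6, 1)))
    gts <- lapply(1:4, function(i)
        makeGenotype(paste0("s", i), "m1",
                     divergedPair(3000, 0.003 * i, seed = i)$b))
    dm <- distanceMatrix(gts)
    expect_equal(dm$matrix, t(dm$matrix))
    expect_equal(unname(diag(dm$matrix)), rep(0, 4))
    expect_equal(nrow(dm$pairs), 6)
    dm2 <- distanceMatrix(rev(gts))
    for (i in 1:3) for (j in (i + 1):4) {
        si <- paste0("s", i); sj <- paste0("s", j)
        expect_equal(dm$matrix[si, sj], dm2$matrix[si, sj])
    }
    # fewer than 2 passing genotypes -> empty with message
    expect_message(empty <- distanceMatrix(gts[1]), "fewer than 2")
    expect_equal(nrow(empty$matrix), 0)
})

test_that("pairwise distance requires matching MSP and passing filters", {
    a <- makeGenotype("s1", "m1", "ACGTACGTACGTACGT")
    b <- makeGenotype("s2", "m2", "ACGTACGTACGTACGT")
    expect_error(pairwiseMutationRate(a, b), "different MSPs")
    c <- makeGenotype("s3", "m1", "ACGTACGTACGTACGT")
    c@passed_filter <- FALSE
    expect_error(pairwiseMutationRate(a, c), "breadth")
})

test_that("complete-linkage clustering recovers planted structure", {
    # two tight groups, intra 1e-4, inter 2e-2, cutoff 5e-3 -> 2 clusters
    ids <- paste0("s", 1:6)
    m <- matrix(2e-2, 6, 6, dimnames = list(ids, ids))
    m[1:3, 1:3] <- 1e-4; m[4:6, 4:6] <- 1e-4
    diag(m) <- 0
    cl <- strainClusters(m, cutoff = 5e-3)
    expect_equal(length(unique(cl)), 2)
    expect_equal(length(unique(cl[1:3])), 1)
    expect_equal(length(unique(cl[4:6])), 1)
    expect_false(cl[["s1"]] == cl[["s4"]])
    # cutoff above max -> single cluster
    expect_equal(length(unique(strainClusters(m, cutoff = 1))), 1)
    # cutoff 0 with distinct positive distances -> all singletons
    set.seed(4)
    d <- matrix(0, 4, 4, dimnames = list(ids[1:4], ids[1:4]))
    d[upper.tri(d)] <- runif(6, 0.01, 0.05)
    d <- d + t(d)
    expect_equal(length(unique(strainClusters(d, cutoff = 0))), 4)
    # samples with missing pairwise values are unclustered
    m2 <- m; m2["s1", "s2"] <- m2["s2", "s1"] <- NA
    cl2 <- strainClusters(m2, cutoff = 5e-3)
    expect_true(all(is.na(cl2[c("s1", "s2")])))
    expect_false(anyNA(cl2[3:6]))
})

test_that("engraftment rate is identical pairs over conspecific pairs", {
    distances <- data.frame(
        msp_id = sprintf("m%d", 1:10),
        sample_a = "donor", sample_b = "recip",
        mutation_rate = c(rep(0, 3), rep(0.01, 7)))
    pairs <- data.frame(recipient_sample = "recip", donor_sample = "donor")
    er <- engraftmentRate(distances, pairs)
    expect_equal(er$rate, 0.3)
    expect_equal(er$n_pairs, 10L)
    # boundary: rate exactly at cutoff counts as identical
    d2 <- distances; d2$mutation_rate[4] <- 1e-4
    expect_equal(engraftmentRate(d2, pairs)$rate, 0.4)
    # no shared species -> missing
    none <- data.frame(msp_id = "m1", sample_a = "x", sample_b = "y",
                       mutation_rate = 0)
    expect_message(er0 <- engraftmentRate(none, pairs), "no conspecific")
    expect_true(is.na(er0$rate))
})
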
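test_that("catalogue generation is seed-deterministic with exact counts", {
    g1 <- generateCatalogue(n_msps = 5, genes_per_msp = 120,
                            gene_length_range = c(300, 1500),
                            n_unclustered = 20, seed = 7)
    g2 <- generateCatalogue(n_msps = 5, genes_per_msp = 120,
                            gene_length_range = c(300, 1500),
                            n_unclustered = 20, seed = 7)
    expect_length(geneIds(g1$catalogue), 620)
    expect_identical(as.character(geneSequences(g1$catalogue)),
                     as.character(geneSequences(g2$catalogue)))
    expect_identical(g1$truth$homolog_partner, g2$truth$homolog_partner)
    # different seed differs
    g3 <- generateCatalogue(n_msps = 5, genes_per_msp = 120,
                            n_unclustered = 20, seed = 8)
    expect_false(identical(as.character(geneSequences(g1$catalogue)),
                           as.character(geneSequences(g3$catalogue))))
    # zero unclustered: every gene belongs to an MSP
    g0 <- generateCatalogue(n_msps = 2, genes_per_msp = 30,
                            n_unclustered = 0, seed = 1)
    expect_equal(sort(geneIds(g0$catalogue)),
                 sort(g0$catalogue@msps$gene_id))
})

test_that("simulated reads follow the requested composition", {
    g <- generateCatalogue(seed = 7)
    ab <- setNames(c(0.8, 0.2, 0, 0, 0), mspIds(g$catalogue))
    sim <- simulateSample(g$catalogue, ab, n_reads = 10000, seed = 3,
                          multimap_fraction = 0)
    frac <- table(sim$truth$msp_id) / nrow(sim$truth)
    expect_equal(as.numeric(frac["msp_001"]), 0.8, tolerance = 0.02)
    expect_equal(as.numeric(frac["msp_002"]), 0.2, tolerance = 0.1)
    expect_false(any(c("msp_003", "msp_004", "msp_005") %in%
                     sim$truth$msp_id))
    # same seed -> byte-identical SAM
    sim2 <- simulateSample(g$catalogue, ab, n_reads = 10000, seed = 3,
                           multimap_fraction = 0)
    expect_identical(readLines(sim$sam), readLines(sim2$sam))
})

test_that("multimap fraction 0 yields only singleton alignment groups", {
    g <- generateCatalogue(seed = 7)
    ab <- setNames(rep(0.2, 5), mspIds(g$catalogue))
    sim <- simulateSample(g$catalogue, ab, n_reads = 2000, seed = 5,
                          multimap_fraction = 0,
                          homolog_partner = g$truth$homolog_partner)
    grp <- filterAlignments(sim$sam, g$catalogue)
    sizes <- table(grp$groups$read_key)
    expect_true(all(sizes == 1))
    # with multimapping enabled some groups have 2 genes
    sim2 <- simulateSample(g$catalogue, ab, n_reads = 5000, seed = 5,
                           multimap_fraction = 1,
                           homolog_partner = g$truth$homolog_partner)
    grp2 <- filterAlignments(sim2$sam, g$catalogue)
    expect_gt(max(table(grp2$groups$read_key)), 1)
})

test_that("planted strain substitutions are recorded and proportional", {
    g <- generateCatalogue(n_msps = 2, genes_per_msp = 12,
                           gene_length_range = c(400, 800),
                           n_unclustered = 0, n_signature = 10, seed = 5)
    st <- mutateStrain(g$catalogue, "msp_001", 0.01, seed = 2)
    expect_equal(st$realized_rate, 0.01, tolerance = 0.3)
    expect_equal(names(st$sequences), mspMembers(g$catalogue, "msp_001"))
    expect_identical(
        as.character(mutateStrain(g$catalogue, "msp_001", 0.01,
                                  seed = 2)$sequences),
        as.character(st$sequences))
    st0 <- mutateStrain(g$catalogue, "msp_001", 0, seed = 2)
    expect_equal(st0$n_substitutions, 0)
})

test_that("profile evaluation metrics match their definitions", {
    mk <- function(est) new("MSPProfile", sample_id = "s",
        abundances = est, detection_fraction = 0.1, n_signature = 100L)
    truth <- c(A = 0.5, B = 0.3, C = 0.2)
    # perfect recovery (up to scaling)
    perfect <- evaluateProfile(mk(c(A = 5, B = 3, C = 2, D = 0)), truth)
    expect_equal(perfect$f1, 1.0)
    expect_equal(perfect$bray_curtis_log10, 0, tolerance = 1e-12)
    expect_equal(perfect$richness_delta, 0)
    # half the species missed, none invented (E, F are true negatives)
    half <- evaluateProfile(mk(c(A = 5, B = 0, C = 2, D = 0, E = 0, F = 0)),
                            c(A = 0.4, B = 0.3, C = 0.2, D = 0.1))
    expect_equal(half$sensitivity, 0.5)
    expect_equal(half$specificity, 1.0)
    expect_equal(half$richness_delta, -2)
    # random profile: metrics equal direct formula evaluation
    set.seed(9)
    est <- setNames(runif(6) * rbinom(6, 1, 0.6), LETTERS[1:6])
    tr <- setNames(c(0.3, 0.3, 0.2, 0.2, 0, 0), LETTERS[1:6])
    ev <- evaluateProfile(mk(est), tr)
    tp <- sum(est > 0 & tr > 0); fp <- sum(est > 0 & tr == 0)
    fn <- sum(est == 0 & tr > 0); tn <- sum(est == 0 & tr == 0)
    expect_equal(ev$sensitivity, tp / (tp + fn))
    expect_equal(ev$specificity, tn / (tn + fp))
    expect_equal(ev$f1, 2 * tp / (2 * tp + fp + fn))
    rel <- est / sum(est)
    pseudo <- 0.1 * min(c(rel[rel > 0], tr[tr > 0]))
    bc <- vegan::vegdist(rbind(log10(1 + rel / pseudo),
                               log10(1 + tr / pseudo)), "bray")
    expect_equal(ev$bray_curtis_log10, as.numeric(bc))
})

test_that("simulation to profile recovers the truth end to end", {
    g <- generateCatalogue(seed = 7)
    ct <- g$catalogue
    ab <- setNames(c(0.4, 0.25, 0.15, 0.12, 0.08), mspIds(ct))
    sim <- simulateSample(ct, ab, n_reads = 10000, seed = 11,
                          homolog_partner = g$truth$homolog_partner)
    grp <- filterAlignments(sim$sam, ct)
    mp <- mspAbundance(normalizeCoverage(countReads(grp), ct), ct)
    ev <- evaluateProfile(mp, ab)
    expect_gte(ev$f1, 0.95)
    expect_lte(abs(ev$richness_delta), 1)
    rho <- cor(abundances(mp)[names(ab)], ab, method = "spearman")
    expect_gte(rho, 0.95)
})

test_that("sensitivity degrades with 10x fewer reads on average", {
    g <- generateCatalogue(seed = 7)
    ct <- g$catalogue
    ab <- setNames(c(0.55, 0.25, 0.14, 0.04, 0.02), mspIds(ct))
    sens <- function(n, seed) {
        sim <- simulateSample(ct, ab, n_reads = n, seed = seed,
                              multimap_fraction = 0)
        mp <- mspAbundance(normalizeCoverage(
            countReads(filterAlignments(sim$sam, ct)), ct), ct)
        evaluateProfile(mp, ab)$sensitivity
    }
    hi <- mean(vapply(1:3, function(s) sens(4000, s), numeric(1)))
    lo <- mean(vapply(1:3, function(s) sens(400, s), numeric(1)))
    expect_lte(lo, hi)
})
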
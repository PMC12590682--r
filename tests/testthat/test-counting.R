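test_that("alignment identity follows (aligned - NM) / aligned", {
    expect_equal(alignmentIdentity(80, 0), 1.0)
    expect_equal(alignmentIdentity(80, 4), 0.95)
    expect_equal(alignmentIdentity(80, 5), 0.9375)
    expect_error(alignmentIdentity(0, 0))
})

test_that("identity filtering keeps records at or above the threshold", {
    ct <- tinyCatalogue()
    lens <- geneLengths(ct)
    # read r1: identities 0.99 (NM 1) and 0.93 (NM 7 of 100) -> 1 record
    # read r2: only 0.93 -> dropped entirely
    # read r3: exactly 0.95 (NM 4 of 80) -> kept
    rec <- data.frame(
        qname = c("r1", "r1", "r2", "r3"),
        flag = 0L,
        rname = c("mspA_g1", "mspB_g1", "mspA_g3", "mspA_g4"),
        pos = 1L,
        cigar = c("100M", "100M", "100M", "80M"),
        nm = c(1L, 7L, 7L, 4L))
    sam <- writeSam(rec, lens)
    grp <- filterAlignments(sam, ct, min_identity = 0.95)
    expect_equal(grp$n_reads_retained, 2L)
    expect_equal(grp$n_reads_dropped, 1L)
    r1 <- grp$groups[grp$groups$read_key == "r1/1", ]
    expect_equal(r1$gene_id, "mspA_g1")

    # fast mode threshold: identity 0.96 dropped at 0.98
    rec2 <- data.frame(qname = "r1", flag = 0L, rname = "mspA_g1", pos = 1L,
                       cigar = "100M", nm = 4L)  # identity 0.96
    grp2 <- filterAlignments(writeSam(rec2, lens), ct, min_identity = 0.98)
    expect_equal(grp2$n_reads_retained, 0L)
    # identity exactly 0.98 retained
    rec3 <- data.frame(qname = "r1", flag = 0L, rname = "mspA_g1", pos = 1L,
                       cigar = "100M", nm = 2L)
    grp3 <- filterAlignments(writeSam(rec3, lens), ct, min_identity = 0.98)
    expect_equal(grp3$n_reads_retained, 1L)
})

test_that("duplicate-flagged records are excluded, secondaries kept, NM required", {
    ct <- tinyCatalogue()
    lens <- geneLengths(ct)
    rec <- data.frame(
        qname = c("r1", "r1", "r2"),
        flag = c(0L, 256L, 1024L),     # primary, secondary, duplicate
        rname = c("mspA_g1", "mspB_g1", "mspA_g1"),
        pos = 1L, cigar = "80M", nm = 0L)
    grp <- filterAlignments(writeSam(rec, lens), ct)
    expect_equal(nrow(grp$groups), 2L)  # r1 on both genes; r2 gone
    expect_setequal(grp$groups$gene_id, c("mspA_g1", "mspB_g1"))

    # record without NM dropped with a warning
    sam <- writeSam(data.frame(qname = "r1", flag = 0L, rname = "mspA_g1",
                               pos = 1L, cigar = "80M", nm = 0L), lens)
    txt <- readLines(sam)
    txt[length(txt)] <- sub("\tNM:i:0", "", txt[length(txt)])
    writeLines(txt, sam)
    expect_warning(grp2 <- filterAlignments(sam, ct), "NM")
    expect_equal(grp2$n_reads_retained, 0L)
})

test_that("unique and total counting follow their definitions", {
    grp <- makeGroups(c(rep(list("g1"), 3), list(c("g1", "g2"))))
    u <- counts(countReads(grp, "unique"))
    expect_equal(u, c(g1 = 3))
    t <- counts(countReads(grp, "total"))
    expect_equal(t, c(g1 = 4, g2 = 1))
    # all multi-mapped -> unique all zero (empty)
    grp2 <- makeGroups(rep(list(c("g1", "g2")), 10))
    expect_length(counts(countReads(grp2, "unique")), 0)
    # empty input
    grp3 <- makeGroups(list())
    expect_length(counts(countReads(grp3, "shared")), 0)
})

test_that("shared counting apportions by unique counts with even fallback", {
    # u(g1)=3, u(g2)=1, one multi-read on {g1,g2}: g1 += 0.75, g2 += 0.25
    grp <- makeGroups(c(rep(list("g1"), 3), list("g2"), list(c("g1", "g2"))))
    s <- counts(countReads(grp, "shared"))
    expect_equal(s, c(g1 = 3.75, g2 = 1.25))
    # no unique anchors: 1/n each
    grp2 <- makeGroups(list(c("g1", "g2", "g3")))
    s2 <- counts(countReads(grp2, "shared"))
    expect_equal(unname(s2), rep(1 / 3, 3))
})

test_that("counting modes match the brute-force oracle on random fixtures", {
    genes <- sprintf("g%02d", 1:12)
    for (seed in 1:5) {
        set.seed(seed)
        reads <- lapply(seq_len(50), function(i)
            sample(genes, sample(c(1, 1, 1, 2, 3), 1)))
        grp <- makeGroups(reads)
        for (mode in c("unique", "total", "shared")) {
            got <- counts(countReads(grp, mode))
            want <- oracleCounts(reads, mode)
            expect_equal(got[order(names(got))], want[order(names(want))],
                         tolerance = 1e-12)
        }
    }
})

test_that("shared counting conserves mass and is bracketed by unique/total", {
    set.seed(99)
    genes <- sprintf("g%02d", 1:8)
    reads <- lapply(seq_len(200), function(i)
        sample(genes, sample(1:3, 1, prob = c(.6, .3, .1))))
    grp <- makeGroups(reads)
    u <- counts(countReads(grp, "unique"))
    s <- counts(countReads(grp, "shared"))
    t <- counts(countReads(grp, "total"))
    expect_lt(abs(sum(s) - length(reads)), 1e-9 * length(reads))
    for (g in names(t)) {
        ug <- if (g %in% names(u)) u[[g]] else 0
        sg <- if (g %in% names(s)) s[[g]] else 0
        expect_gte(sg + 1e-12, ug)
        expect_lte(sg, t[[g]] + 1e-12)
    }
    # every read unique -> shared equals total
    grp1 <- makeGroups(lapply(1:30, function(i) sample(genes, 1)))
    expect_equal(counts(countReads(grp1, "shared")),
                 counts(countReads(grp1, "total")))
})

test_that("counting is invariant to read order", {
    set.seed(7)
    genes <- sprintf("g%02d", 1:6)
    reads <- lapply(seq_len(80), function(i) sample(genes, sample(1:3, 1)))
    a <- counts(countReads(makeGroups(reads), "shared"))
    b <- counts(countReads(makeGroups(rev(reads)), "shared"))
    expect_identical(a, b)
})
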
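## Deterministic in-code fixtures and independent oracles shared by the
## test files. Everything is generated at test time; no data files.

## A tiny hand-specified catalogue: 2 MSPs (4 + 3 genes, all signature),
## one unclustered gene, known annotations and one two-step module.
tinyCatalogue <- function() {
    set.seed(101)
    ids <- c("mspA_g1", "mspA_g2", "mspA_g3", "mspA_g4",
             "mspB_g1", "mspB_g2", "mspB_g3", "orph_g1")
    lens <- c(1000L, 180L, 500L, 400L, 1000L, 800L, 600L, 300L)
    seqs <- Biostrings::DNAStringSet(vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)))
    names(seqs) <- ids
    GeneCatalogue(
        genes = data.frame(gene_id = ids, length = lens),
        sequences = seqs,
        msps = data.frame(
            msp_id = rep(c("mspA", "mspB"), c(4, 3)),
            gene_id = ids[1:7],
            signature_rank = c(1:4, 1:3)),
        annotations = data.frame(
            namespace = c("KO", "KO", "KO", "KO", "ARG_resfinder"),
            gene_id = c("mspA_g1", "mspA_g2", "mspB_g1", "mspB_g2",
                        "mspA_g3"),
            term = c("K1", "K1", "K2", "K3", "resistance")),
        modules = list(m1 = parseModuleDefinition("K1 (K2,K3)", "m1")),
        mode = "complete")
}

## Build an AlignmentGroups object directly from a list of per-read gene
## vectors (bypassing SAM I/O) for counting unit tests.
makeGroups <- function(reads, n_total = NULL) {
    dt <- if (length(reads))
        data.table::rbindlist(lapply(seq_along(reads), function(i)
            data.table::data.table(read_key = sprintf("r%04d/1", i),
                                   gene_id = unique(reads[[i]]),
                                   identity = 1)))
    else data.table::data.table(read_key = character(),
                                gene_id = character(),
                                identity = numeric())
    structure(list(groups = dt,
                   n_reads_retained = length(reads),
                   n_reads_dropped = 0L,
                   n_reads_total = if (is.null(n_total))
                       as.integer(length(reads)) else as.integer(n_total)),
              class = "AlignmentGroups")
}

## Independent brute-force counting oracle: naive per-read apportionment
## following the stated rules, no shared code with the implementation.
oracleCounts <- function(reads, mode) {
    reads <- lapply(reads, unique)
    genes <- sort(unique(unlist(reads)))
    out <- setNames(numeric(length(genes)), genes)
    uniq <- setNames(numeric(length(genes)), genes)
    for (r in reads) if (length(r) == 1) uniq[r] <- uniq[r] + 1
    for (r in reads) {
        if (mode == "unique") {
            if (length(r) == 1) out[r] <- out[r] + 1
        } else if (mode == "total") {
            for (g in r) out[g] <- out[g] + 1
        } else {
            if (length(r) == 1) out[r] <- out[r] + 1
            else {
                s <- sum(uniq[r])
                for (g in r) out[g] <- out[g] +
                    (if (s > 0) uniq[g] / s else 1 / length(r))
            }
        }
    }
    out[out > 0]
}

## Write a SAM file from a record table against given reference lengths.
writeSam <- function(records, ref_lengths, path = tempfile(fileext = ".sam")) {
    hdr <- c("@HD\tVN:1.6\tSO:queryname",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths))
    body <- vapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        len <- as.integer(sub("M.*", "", r$cigar))
        seq <- if (!is.null(r$seq) && !is.na(r$seq)) r$seq
               else paste(rep("A", len), collapse = "")
        qual <- if (!is.null(r$qual) && !is.na(r$qual)) r$qual
                else paste(rep("I", len), collapse = "")
        sprintf("%s\t%d\t%s\t%d\t40\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                r$qname, r$flag, r$rname, r$pos, r$cigar, seq, qual, r$nm)
    }, character(1))
    writeLines(c(hdr, body), path)
    path
}

## Random module structure generator + renderer; the generating structure
## is the oracle for the parser and for completeness.
randomModuleStructure <- function(max_steps = 6, max_alts = 3,
                                  term_pool = sprintf("K%02d", 1:12)) {
    n_steps <- sample(seq_len(max_steps), 1)
    lapply(seq_len(n_steps), function(s) {
        n_alts <- sample(seq_len(max_alts), 1)
        lapply(seq_len(n_alts), function(a)
            sort(sample(term_pool, sample(1:2, 1))))
    })
}

renderModule <- function(steps) {
    paste(vapply(steps, function(st) {
        alts <- vapply(st, paste, character(1), collapse = "+")
        if (length(alts) == 1 && !grepl("\\+", alts)) alts
        else paste0("(", paste(alts, collapse = ","), ")")
    }, character(1)), collapse = " ")
}

## Brute-force completeness from a known structure: max over explicit
## configuration enumeration done here, not via the package.
oracleCompleteness <- function(steps, present) {
    combos <- expand.grid(lapply(steps, seq_along))
    best <- 0
    for (i in seq_len(nrow(combos))) {
        ok <- vapply(seq_along(steps), function(s)
            all(steps[[s]][[combos[i, s]]] %in% present), logical(1))
        best <- max(best, sum(ok) / length(steps))
    }
    best
}

## Construct a passing ConsensusGenotype directly from sequences (for
## distance/cluster/engraftment tests that need no pileup).
makeGenotype <- function(sample_id, msp_id, seqs) {
    sq <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(sq))) names(sq) <- sprintf("g%03d", seq_along(sq))
    new("ConsensusGenotype", sample_id = sample_id, msp_id = msp_id,
        sequences = sq,
        breadth = setNames(rep(1, length(sq)), names(sq)),
        passed_filter = TRUE)
}

## JC69-style sequence pair simulator: returns two strings diverged by
## per-site substitution probability p.
divergedPair <- function(L, p, seed) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, L, replace = TRUE)
    b <- a
    hit <- which(stats::runif(L) < p)
    if (length(hit))
        b[hit] <- vapply(b[hit], function(x)
            sample(setdiff(bases, x), 1), character(1))
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         p_realized = mean(a != b))
}
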
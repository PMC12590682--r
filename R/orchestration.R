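#' Build a run configuration
#'
#' Assembles the tunable parameters of a profiling run with their
#' defaults. Fast mode (signature-genes-only catalogue) forces the more
#' stringent alignment identity threshold (0.98) and detection fraction
#' (0.20) unless those are overridden explicitly.
#'
#' @param mode `"complete"` or `"fast"`.
#' @param counting_mode `"shared"`, `"unique"` or `"total"`.
#' @param normalization `"coverage"` or `"fpkm"`.
#' @param min_identity alignment identity threshold; `NULL` = by mode.
#' @param detection_fraction MSP detection fraction; `NULL` = by mode.
#' @param read_length read length for the effective-length correction.
#' @param f strain non-reference allele frequency (0.1 mixed, 0.5
#'   dominant).
#' @param min_depth pileup masking depth.
#' @param min_informative minimum informative sites for a distance.
#' @param cluster_cutoff complete-linkage cut height (mutation rate).
#' @param identical_cutoff mutation rate at or below which strains are
#'   identical (engraftment).
#' @param seed integer seed recorded in outputs.
#' @return named list (class `profiler_config`).
#' @export
profilerConfig <- function(mode = c("complete", "fast"),
                           counting_mode = c("shared", "unique", "total"),
                           normalization = c("coverage", "fpkm"),
                           min_identity = NULL,
                           detection_fraction = NULL,
                           read_length = 80L,
                           f = 0.1, min_depth = 3L,
                           min_informative = 10L,
                           cluster_cutoff = 5e-3,
                           identical_cutoff = 1e-4,
                           seed = 1L) {
    mode <- match.arg(mode)
    counting_mode <- match.arg(counting_mode)
    normalization <- match.arg(normalization)
    if (is.null(min_identity))
        min_identity <- if (mode == "fast") 0.98 else 0.95
    if (is.null(detection_fraction))
        detection_fraction <- if (mode == "fast") 0.20 else 0.10
    structure(list(mode = mode, counting_mode = counting_mode,
                   normalization = normalization,
                   min_identity = min_identity,
                   detection_fraction = detection_fraction,
                   read_length = read_length, f = f,
                   min_depth = min_depth,
                   min_informative = min_informative,
                   cluster_cutoff = cluster_cutoff,
                   identical_cutoff = identical_cutoff,
                   seed = seed),
              class = "profiler_config")
}

.configHash <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    yaml::write_yaml(unclass(config), tf)
    unname(tools::md5sum(tf))
}

.outputHeader <- function(config) {
    list(tool = paste0("mspprofiler ",
                       as.character(utils::packageVersion("mspprofiler"))),
         config_hash = .configHash(config),
         seed = config$seed)
}

#' Run the taxonomic and functional profiling stage
#'
#' For each sample: filters alignments, counts reads, normalizes,
#' reduces to an MSP profile, aggregates functional term abundances and
#' module potentials, and writes everything under
#' `output_dir/<sample>/`. Failures are isolated per sample; the run
#' summary reports them. Every output file carries header comments with
#' the tool version, a configuration hash and the seed, plus the sample
#' mapping rate in the run log.
#'
#' @param catalogue a [GeneCatalogue-class].
#' @param sam_paths named character vector of SAM/BAM paths (names =
#'   sample ids).
#' @param output_dir output directory.
#' @param config a [profilerConfig()] list.
#' @return invisibly, a list per sample with the in-memory results
#'   (`counts`, `gene_profile`, `msp_profile`, `functions`, `modules`,
#'   `arg_ratio`) or the error; attribute `n_failed` counts failures.
#' @export
runProfile <- function(catalogue, sam_paths, output_dir,
                       config = profilerConfig()) {
    stopifnot(is(catalogue, "GeneCatalogue"), length(sam_paths) >= 1)
    if (is.null(names(sam_paths)))
        names(sam_paths) <- sub("\\.(sam|bam)$", "", basename(sam_paths))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .outputHeader(config)
    results <- list()
    n_failed <- 0L
    for (s in names(sam_paths)) {
        res <- tryCatch({
            sdir <- file.path(output_dir, s)
            dir.create(sdir, showWarnings = FALSE)
            grp <- filterAlignments(sam_paths[[s]], catalogue,
                                    min_identity = config$min_identity)
            cnt <- countReads(grp, mode = config$counting_mode,
                              sample_id = s)
            gp <- if (config$normalization == "coverage")
                normalizeCoverage(cnt, catalogue,
                                  read_length = config$read_length)
            else normalizeFPKM(cnt, catalogue)
            mp <- mspAbundance(gp, catalogue,
                               detection_fraction = config$detection_fraction)
            writeGeneCounts(cnt, file.path(sdir, "gene_counts.tsv"), hdr)
            writeMSPProfile(mp, file.path(sdir, "msp_profile.tsv"), hdr)
            fns <- lapply(setNames(nm = annotationNamespaces(catalogue)),
                          function(ns)
                              geneFunctionAbundance(gp, catalogue, ns))
            for (ns in names(fns)) {
                df <- data.frame(term = names(fns[[ns]]),
                                 abundance = signif(fns[[ns]], 6),
                                 level = "gene")
                .writeTsvWithHeader(df,
                    file.path(sdir, sprintf("functions_%s.tsv", ns)), hdr)
            }
            carriers <- moduleCarriers(mp, cnt, catalogue)
            pot <- modulePotential(carriers, catalogue)
            .writeTsvWithHeader(carriers,
                file.path(sdir, "module_carriers.tsv"), hdr)
            .writeTsvWithHeader(pot, file.path(sdir, "modules.tsv"), hdr)
            ar <- tryCatch(argRatio(cnt, catalogue), error = function(e) NA)
            .writeTsvWithHeader(
                data.frame(arg_ratio = ar),
                file.path(sdir, "arg_ratio.tsv"), hdr)
            log_lines <- c(
                sprintf("sample: %s", s),
                sprintf("reads_retained: %d", retainedReads(cnt)),
                sprintf("mapping_rate: %s",
                        formatC(mappingRate(cnt), digits = 4,
                                format = "f")))
            writeLines(c(sprintf("# %s: %s", names(hdr), unlist(hdr)),
                         log_lines), file.path(sdir, "run_log.txt"))
            list(counts = cnt, gene_profile = gp, msp_profile = mp,
                 functions = fns, modules = pot, arg_ratio = ar)
        }, error = function(e) {
            n_failed <<- n_failed + 1L
            warning(sprintf("sample '%s' failed: %s", s,
                            conditionMessage(e)), call. = FALSE)
            e
        })
        results[[s]] <- res
    }
    attr(results, "n_failed") <- n_failed
    invisible(results)
}

.writeTsvWithHeader <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(header), unlist(header)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the strain profiling stage
#'
#' For each sample, builds consensus genotypes for the MSPs detected in
#' it; then for every MSP passing the breadth filter in at least two
#' samples computes the pairwise mutation-rate matrix, complete-linkage
#' strain clusters at `config$cluster_cutoff`, and — when
#' donor/recipient metadata is supplied — the engraftment rate at
#' `config$identical_cutoff`. Consensus genotypes are written as
#' multi-FASTA per MSP, distances as a long-format TSV and per-MSP
#' square matrices, clusters and engraftment as TSVs.
#'
#' @param catalogue a [GeneCatalogue-class] with gene sequences.
#' @param sam_paths named character vector of SAM/BAM paths.
#' @param output_dir output directory.
#' @param config a [profilerConfig()] list.
#' @param metadata optional data.frame with columns `recipient_sample`,
#'   `donor_sample` and optionally `timepoint` for engraftment; without
#'   donor links the engraftment step is skipped with a notice.
#' @return invisibly, list with `genotypes` (msp -> list of passing
#'   [ConsensusGenotype-class]), `distances` (long data.frame),
#'   `clusters` (msp -> named vector) and `engraftment` (list or NULL).
#' @export
runStrain <- function(catalogue, sam_paths, output_dir,
                      config = profilerConfig(), metadata = NULL) {
    stopifnot(is(catalogue, "GeneCatalogue"), length(sam_paths) >= 1)
    if (is.null(names(sam_paths)))
        names(sam_paths) <- sub("\\.(sam|bam)$", "", basename(sam_paths))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .outputHeader(config)
    genotypes <- list()
    for (s in names(sam_paths)) {
        aln <- readStrainAlignments(sam_paths[[s]], catalogue,
                                    min_identity = config$min_identity)
        seen_msps <- unique(catalogue@msps$msp_id[
            catalogue@msps$gene_id %in% unique(aln$gene_id)])
        for (m in seen_msps) {
            g <- consensusGenotype(aln, catalogue, m, s, f = config$f,
                                   min_depth = config$min_depth)
            if (g@passed_filter)
                genotypes[[m]] <- c(genotypes[[m]], list(g))
        }
    }
    all_pairs <- list()
    clusters <- list()
    for (m in names(genotypes)) {
        if (length(genotypes[[m]]) < 2L) next
        writeGenotypes(genotypes[[m]],
                       file.path(output_dir,
                                 sprintf("consensus_%s.fasta", m)))
        dm <- distanceMatrix(genotypes[[m]],
                             min_informative = config$min_informative)
        if (!nrow(dm$pairs)) next
        all_pairs[[m]] <- dm$pairs
        utils::write.table(dm$matrix,
            file.path(output_dir, sprintf("distances_%s.tsv", m)),
            sep = "\t", quote = FALSE)
        clusters[[m]] <- strainClusters(dm$matrix,
                                        cutoff = config$cluster_cutoff)
        .writeTsvWithHeader(
            data.frame(sample_id = names(clusters[[m]]),
                       cluster = clusters[[m]]),
            file.path(output_dir, sprintf("clusters_%s.tsv", m)), hdr)
    }
    distances <- if (length(all_pairs)) do.call(rbind, all_pairs)
                 else data.frame()
    if (nrow(distances))
        .writeTsvWithHeader(distances,
            file.path(output_dir, "distances.tsv"), hdr)
    else
        message("no MSP present in at least 2 samples; ",
                "no distances computed")
    engraftment <- NULL
    if (!is.null(metadata) &&
        all(c("recipient_sample", "donor_sample") %in% names(metadata)) &&
        nrow(distances)) {
        if ("timepoint" %in% names(metadata)) {
            engraftment <- lapply(split(metadata, metadata$timepoint),
                function(md) engraftmentRate(distances, md,
                                             config$identical_cutoff))
            eng_df <- data.frame(
                timepoint = names(engraftment),
                rate = vapply(engraftment, function(e)
                    e$rate %||% NA_real_, numeric(1)),
                n_pairs = vapply(engraftment, function(e)
                    e$n_pairs, integer(1)))
        } else {
            engraftment <- engraftmentRate(distances, metadata,
                                           config$identical_cutoff)
            eng_df <- data.frame(timepoint = "all",
                                 rate = engraftment$rate,
                                 n_pairs = engraftment$n_pairs)
        }
        .writeTsvWithHeader(eng_df,
            file.path(output_dir, "engraftment.tsv"), hdr)
    } else if (!is.null(metadata)) {
        message("metadata without donor links; engraftment skipped")
    }
    invisible(list(genotypes = genotypes, distances = distances,
                   clusters = clusters, engraftment = engraftment))
}
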
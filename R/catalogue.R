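#' Construct a GeneCatalogue
#'
#' Low-level constructor; most users will call [loadCatalogue()] or
#' [generateCatalogue()] instead.
#'
#' @param genes data.frame with columns `gene_id`, `length`.
#' @param sequences optional [Biostrings::DNAStringSet], named by gene_id.
#' @param msps data.frame with columns `msp_id`, `gene_id`,
#'   `signature_rank` (NA for accessory genes).
#' @param annotations data.frame with columns `namespace`, `gene_id`,
#'   `term`.
#' @param modules named list of [ModuleDefinition-class] objects.
#' @param mode `"complete"` or `"fast"`.
#' @return a validated [GeneCatalogue-class] object.
#' @export
GeneCatalogue <- function(genes,
                          sequences = Biostrings::DNAStringSet(),
                          msps = data.frame(msp_id = character(),
                                            gene_id = character(),
                                            signature_rank = integer()),
                          annotations = data.frame(namespace = character(),
                                                   gene_id = character(),
                                                   term = character()),
                          modules = list(),
                          mode = c("complete", "fast")) {
    mode <- match.arg(mode)
    genes$gene_id <- as.character(genes$gene_id)
    genes$length <- as.integer(genes$length)
    msps$signature_rank <- as.integer(msps$signature_rank)
    obj <- new("GeneCatalogue", genes = genes, sequences = sequences,
               msps = msps, annotations = annotations, modules = modules,
               mode = mode)
    validObject(obj)
    obj
}

## ---- module definition grammar ------------------------------------------

## Split `s` at top-level (parenthesis depth 0) occurrences of characters
## in `sep`; whitespace runs collapse to one separator.
.splitTopLevel <- function(s, sep) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L
    parts <- character()
    buf <- character()
    for (i in seq_along(chars)) {
        ch <- chars[i]
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop(sprintf("unbalanced ')' at position %d in '%s'", i, s),
                     call. = FALSE)
        }
        if (depth == 0L && ch %in% sep) {
            parts <- c(parts, paste(buf, collapse = ""))
            buf <- character()
        } else {
            buf <- c(buf, ch)
        }
    }
    if (depth != 0L)
        stop(sprintf("unbalanced '(' in '%s'", s), call. = FALSE)
    parts <- c(parts, paste(buf, collapse = ""))
    if (identical(sep, c(" ", "\t"))) parts <- parts[nzchar(parts)]
    parts
}

.parseUnit <- function(unit, full) {
    unit <- trimws(unit)
    if (!nzchar(unit))
        stop(sprintf("empty unit in module definition '%s'", full),
             call. = FALSE)
    if (startsWith(unit, "(") && endsWith(unit, "(")) # defensive
        stop(sprintf("malformed group '%s'", unit), call. = FALSE)
    if (startsWith(unit, "(")) {
        if (!endsWith(unit, ")"))
            stop(sprintf("unbalanced parentheses in '%s'", unit),
                 call. = FALSE)
        inner <- substr(unit, 2L, nchar(unit) - 1L)
        steps <- .parseSteps(inner, full)
        return(.stepsConfigurations(steps))
    }
    if (grepl("[(),+[:space:]]", unit))
        stop(sprintf("invalid term '%s' in module definition '%s'",
                     unit, full), call. = FALSE)
    list(unit)
}

## One alternative: '+'-joined units; returns list of term-sets
## (a nested group may expand to several ways of satisfying the unit).
.parseAlternative <- function(alt, full) {
    alt <- trimws(alt)
    if (!nzchar(alt))
        stop(sprintf("empty alternative in module definition '%s'", full),
             call. = FALSE)
    units <- .splitTopLevel(alt, "+")
    sets <- lapply(units, .parseUnit, full = full)
    # cartesian product across units; each configuration is the union
    out <- list(character())
    for (u in sets) {
        out <- unlist(lapply(out, function(acc)
            lapply(u, function(term_set) union(acc, term_set))),
            recursive = FALSE)
    }
    lapply(out, function(x) sort(unique(x)))
}

.parseSteps <- function(expr, full) {
    step_strs <- .splitTopLevel(expr, c(" ", "\t"))
    if (!length(step_strs))
        stop(sprintf("empty module definition '%s'", full), call. = FALSE)
    lapply(step_strs, function(st) {
        alts <- .splitTopLevel(st, ",")
        unlist(lapply(alts, .parseAlternative, full = full),
               recursive = FALSE)
    })
}

## All configurations implied by a list of steps (used for nested groups).
.stepsConfigurations <- function(steps) {
    out <- list(character())
    for (st in steps) {
        out <- unlist(lapply(out, function(acc)
            lapply(st, function(a) union(acc, a))), recursive = FALSE)
    }
    lapply(out, function(x) sort(unique(x)))
}

#' Parse a functional module definition
#'
#' Parses a KEGG-module-style boolean definition into a
#' [ModuleDefinition-class]. The grammar follows KEGG module notation:
#' whitespace separates mandatory steps, a comma separates alternatives
#' within a step, `+` joins jointly required terms (a complex) and
#' parentheses group sub-expressions. For example `"K1 (K2,K3)"` is a
#' two-step module whose second step is satisfied by either K2 or K3.
#'
#' @param expr definition string.
#' @param module_id identifier to store (default the expression itself).
#' @param source `"KEGG"`, `"GMM"` or `"GBM"`; the same grammar is used
#'   for all three, terms being opaque strings.
#' @return a [ModuleDefinition-class].
#' @examples
#' m <- parseModuleDefinition("K1 (K2,K3)")
#' length(moduleSteps(m))       # 2 steps
#' enumerateConfigurations(m)   # {K1,K2} and {K1,K3}
#' @export
parseModuleDefinition <- function(expr, module_id = expr,
                                  source = c("KEGG", "GMM", "GBM")) {
    source <- match.arg(source)
    if (!isSingleString(expr) || !nzchar(trimws(expr)))
        stop("module definition must be a non-empty string", call. = FALSE)
    steps <- .parseSteps(trimws(expr), full = expr)
    obj <- new("ModuleDefinition", module_id = module_id, source = source,
               definition = expr, steps = steps)
    validObject(obj)
    obj
}

#' Enumerate the alternative configurations of a module
#'
#' A configuration picks one alternative per step; its term-set is the
#' union of the chosen alternatives. Module completeness is defined as a
#' maximum over these configurations, so their enumeration is the
#' brute-force reference for [moduleCompleteness()].
#'
#' @param m a [ModuleDefinition-class].
#' @param limit guard on the number of configurations (product of per-step
#'   alternative counts); above it an error advises per-step evaluation.
#' @return list of character vectors (sorted term-sets).
#' @export
enumerateConfigurations <- function(m, limit = 10000L) {
    stopifnot(is(m, "ModuleDefinition"))
    n <- prod(vapply(m@steps, length, integer(1)))
    if (n > limit)
        stop(sprintf(paste0("module '%s' has %d alternative configurations ",
                            "(limit %d); evaluate completeness per step ",
                            "instead of enumerating"),
                     m@module_id, n, limit), call. = FALSE)
    .stepsConfigurations(m@steps)
}

## ---- catalogue I/O -------------------------------------------------------

.readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE,
                      colClasses = "character")
}

#' Load a gene catalogue from a directory
#'
#' Reads the catalogue TSV dialect written by [writeCatalogue()] and
#' [generateCatalogue()]: `genes.tsv` (gene_id, length), `msps.tsv`
#' (msp_id, gene_id, signature_rank — empty rank marks accessory genes),
#' optional `genes.fasta`, optional `annotations/<namespace>.tsv`
#' (gene_id, term), optional `modules.tsv` (module_id, source,
#' definition) and a `manifest.yaml` carrying the catalogue mode and
#' version. All cross-references are validated; dangling gene ids are
#' rejected with an informative error.
#'
#' @param directory catalogue directory.
#' @param mode override the manifest mode (`"complete"` or `"fast"`).
#' @return a [GeneCatalogue-class].
#' @seealso [writeCatalogue()], [generateCatalogue()]
#' @export
loadCatalogue <- function(directory, mode = NULL) {
    need <- function(f) {
        p <- file.path(directory, f)
        if (!file.exists(p))
            stop(sprintf("catalogue is missing mandatory file '%s'", f),
                 call. = FALSE)
        p
    }
    genes <- .readTsv(need("genes.tsv"))
    genes$length <- as.integer(genes$length)
    msps <- .readTsv(need("msps.tsv"))
    msps$signature_rank <- suppressWarnings(as.integer(msps$signature_rank))

    manifest_path <- file.path(directory, "manifest.yaml")
    manifest <- if (file.exists(manifest_path))
        yaml::read_yaml(manifest_path) else list(mode = "complete")
    if (is.null(mode)) mode <- manifest$mode %||% "complete"

    fasta <- file.path(directory, "genes.fasta")
    sequences <- if (file.exists(fasta))
        Biostrings::readDNAStringSet(fasta) else Biostrings::DNAStringSet()
    names(sequences) <- sub("\\s.*", "", names(sequences))

    ann_dir <- file.path(directory, "annotations")
    annotations <- data.frame(namespace = character(), gene_id = character(),
                              term = character())
    if (dir.exists(ann_dir)) {
        files <- list.files(ann_dir, pattern = "\\.tsv$", full.names = TRUE)
        anns <- lapply(files, function(f) {
            df <- .readTsv(f)
            data.frame(namespace = sub("\\.tsv$", "", basename(f)),
                       gene_id = df$gene_id, term = df$term)
        })
        if (length(anns)) annotations <- do.call(rbind, anns)
    }

    modules <- list()
    mod_path <- file.path(directory, "modules.tsv")
    if (file.exists(mod_path)) {
        md <- .readTsv(mod_path)
        modules <- lapply(seq_len(nrow(md)), function(i)
            parseModuleDefinition(md$definition[i], md$module_id[i],
                                  md$source[i]))
        names(modules) <- md$module_id
    }

    GeneCatalogue(genes = genes, sequences = sequences, msps = msps,
                  annotations = annotations, modules = modules, mode = mode)
}

#' Write a gene catalogue to a directory
#'
#' Inverse of [loadCatalogue()]; writes the documented TSV dialect plus a
#' `manifest.yaml`. Loading the written directory yields a semantically
#' identical catalogue (row order aside).
#'
#' @param catalogue a [GeneCatalogue-class].
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCatalogue <- function(catalogue, directory) {
    stopifnot(is(catalogue, "GeneCatalogue"))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, f)
        utils::write.table(df, file.path(directory, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    wtsv(catalogue@genes, "genes.tsv")
    msps <- catalogue@msps
    msps$signature_rank[is.na(msps$signature_rank)] <- ""
    wtsv(msps, "msps.tsv")
    if (length(catalogue@sequences))
        Biostrings::writeXStringSet(catalogue@sequences,
                                    file.path(directory, "genes.fasta"))
    if (nrow(catalogue@annotations)) {
        dir.create(file.path(directory, "annotations"), showWarnings = FALSE)
        for (ns in unique(catalogue@annotations$namespace)) {
            sel <- catalogue@annotations$namespace == ns
            wtsv(catalogue@annotations[sel, c("gene_id", "term")],
                 file.path("annotations", paste0(ns, ".tsv")))
        }
    }
    if (length(catalogue@modules)) {
        md <- data.frame(
            module_id = vapply(catalogue@modules, slot, character(1),
                               "module_id"),
            source = vapply(catalogue@modules, slot, character(1), "source"),
            definition = vapply(catalogue@modules, slot, character(1),
                                "definition"))
        wtsv(md, "modules.tsv")
    }
    yaml::write_yaml(list(mode = catalogue@mode,
                          n_genes = nrow(catalogue@genes),
                          n_msps = length(mspIds(catalogue)),
                          version = "1"),
                     file.path(directory, "manifest.yaml"))
    invisible(directory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
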
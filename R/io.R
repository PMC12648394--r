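## External formats: FASTA input, annotation CSV, module/event tables,
## iTOL annotation datasets. All tabular output is plain comma-separated
## UTF-8 with a header row and unquoted ids; coordinates in files are
## 1-based inclusive (internally 0-based half-open).

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X")

#' Read family protein sequences from FASTA
#'
#' Each FASTA id must end in an underscore-separated NCBI taxonomy id, e.g.
#' \code{ADAMTS5_HUMAN_9606}: the trailing integer token is the taxid and
#' everything before it the protein id. Sequences must use the 20-letter
#' amino-acid alphabet plus \code{X}.
#'
#' @param path FASTA file.
#' @return a data.frame with columns \code{protein_id}, \code{taxid},
#'   \code{sequence}, one row per entry in file order.
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ## BStringSet: raw bytes, so alphabet violations are ours to report
    aa <- Biostrings::readBStringSet(path)
    if (length(aa) == 0L) stop("no sequences in ", path)
    headers <- sub("\\s.*$", "", names(aa))
    m <- regmatches(headers, regexec("^(.*)_([0-9]+)$", headers))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
        stop("header without parsable trailing _taxid: ", headers[bad][1L])
    ids <- vapply(m, `[[`, "", 2L)
    taxids <- as.integer(vapply(m, `[[`, "", 3L))
    if (any(!nzchar(ids))) stop("empty protein id in header: ",
                                headers[!nzchar(ids)][1L])
    if (any(taxids < 1L)) stop("taxid must be >= 1: ", headers[taxids < 1L][1L])
    if (anyDuplicated(ids))
        stop("duplicate id ", ids[duplicated(ids)][1L])
    seqs <- toupper(as.character(aa))
    for (i in seq_along(seqs)) {
        if (!nzchar(seqs[i])) stop("empty sequence for ", ids[i])
        pos <- regexpr(paste0("[^", paste(.AA_ALPHABET, collapse = ""), "]"),
                       seqs[i])
        if (pos > 0L)
            stop(sprintf("non-amino-acid character '%s' at position %d of %s",
                         substr(seqs[i], pos, pos), pos, ids[i]))
    }
    data.frame(protein_id = ids, taxid = taxids, sequence = unname(seqs),
               stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Headers are \code{protein_id_taxid}, the dialect read back by
#' \code{\link{readProteinFasta}}.
#'
#' @param records data.frame with \code{protein_id}, \code{taxid},
#'   \code{sequence}.
#' @param path output file.
#' @export
writeProteinFasta <- function(records, path) {
    aa <- Biostrings::AAStringSet(setNames(
        records$sequence, paste0(records$protein_id, "_", records$taxid)))
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Read binary functional annotations
#'
#' The CSV lists one (protein_id, function_id) row per observed function.
#' The annotated subset defaults to the proteins appearing at least once in
#' the file; for those proteins every unlisted function is recorded absent,
#' while proteins outside the subset are unknown for every function. Pass
#' \code{annotatedIds} (a character vector, or a path to a one-id-per-line
#' file) to override the subset.
#'
#' @param path CSV with header columns \code{protein_id,function_id}.
#' @param records protein records data.frame (for id validation).
#' @param annotatedIds optional explicit annotated subset.
#' @return a \linkS4class{FunctionTable}.
#' @export
readFunctionTable <- function(path, records, annotatedIds = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("protein_id", "function_id") %in% names(df)))
        stop("annotation CSV needs columns protein_id,function_id")
    if (nrow(df) == 0L) stop("no annotations in ", path)
    unknownProt <- setdiff(df$protein_id, records$protein_id)
    if (length(unknownProt))
        stop("unknown protein ", unknownProt[1L])
    if (is.character(annotatedIds) && length(annotatedIds) == 1L &&
        file.exists(annotatedIds))
        annotatedIds <- readLines(annotatedIds)
    annotated <- if (is.null(annotatedIds)) unique(df$protein_id)
                 else unique(annotatedIds)
    extra <- setdiff(annotated, records$protein_id)
    if (length(extra)) stop("unknown protein ", extra[1L])
    fns <- sort(unique(df$function_id))
    prots <- records$protein_id
    st <- matrix("unknown", nrow = length(prots), ncol = length(fns),
                 dimnames = list(prots, fns))
    st[rownames(st) %in% annotated, ] <- "absent"
    st[cbind(df$protein_id, df$function_id)] <- "present"
    ## annotations for proteins outside an explicit annotated subset stay
    ## unknown (they may or may not carry the function)
    st[!rownames(st) %in% annotated, ] <- "unknown"
    methods::new("FunctionTable", functions = fns, proteins = prots,
                 state = st, annotated = annotated)
}

## ---- module tables ----

#' Write the module table
#'
#' One row per (module, segment) with 1-based inclusive positions, sorted by
#' (module_id, protein_id).
#'
#' @param modules list of \linkS4class{SeqModule}.
#' @param path output CSV.
#' @export
writeModuleTable <- function(modules, path) {
    rows <- lapply(modules, function(m) {
        seg <- moduleSegments(m)
        data.frame(module_id = moduleId(m), protein_id = seg$protein_id,
                   start = seg$start + 1L, end = seg$end,
                   segment = seg$segment, stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(module_id = character(), protein_id = character(),
                          start = integer(), end = integer(),
                          segment = character())
    df <- df[order(df$module_id, df$protein_id), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a module table written by \code{writeModuleTable}
#'
#' @param path CSV path.
#' @return list of \linkS4class{SeqModule} (scores recomputed as 0; positions
#'   converted back to internal 0-based half-open coordinates).
#' @export
readModuleTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(list())
    lapply(split(df, df$module_id)[unique(df$module_id)], function(d) {
        seg <- data.frame(protein_id = d$protein_id, start = d$start - 1L,
                          end = d$end, segment = d$segment,
                          stringsAsFactors = FALSE)
        methods::new("SeqModule", moduleId = d$module_id[1L], segments = seg,
                     width = as.integer(d$end[1L] - d$start[1L] + 1L),
                     score = 0)
    })
}

## ---- event tables ----

#' Write the per-node presence/gain/loss event table
#'
#' Derives gain/loss events by parent comparison for every item and writes
#' one row per (node, item): columns \code{node_id,item_id,item_type,state,
#' event,support}. Support is the replicate frequency for modules and the
#' marginal posterior for functions.
#'
#' @param presence list of \linkS4class{PresenceMap}, one per item.
#' @param tree the \linkS4class{GeneTree}.
#' @param path output CSV.
#' @export
writeEventTable <- function(presence, tree, path) {
    rows <- lapply(presence, function(p) {
        deriveGainLossEvents(p, tree)
    })
    df <- do.call(rbind, rows)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an event table back into PresenceMap objects
#'
#' @param path CSV written by \code{\link{writeEventTable}}.
#' @return named list of \linkS4class{PresenceMap}.
#' @export
readEventTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    out <- lapply(split(df, df$item_id), function(d) {
        methods::new("PresenceMap", itemId = d$item_id[1L],
                     itemType = d$item_type[1L],
                     state = setNames(d$state == "present", d$node_id),
                     support = setNames(d$support, d$node_id))
    })
    out[unique(df$item_id)]
}

## ---- iTOL datasets ----

#' Deterministic module color palette
#'
#' Evenly spaced hues shuffled by a fixed-seed generator so adjacent module
#' ids get visually distinct colors; identical across runs.
#'
#' @param n number of colors.
#' @return character vector of \code{#rrggbb} colors.
#' @export
modulePalette <- function(n) {
    if (n == 0L) return(character(0))
    hues <- seq(0, 1 - 1 / n, length.out = n)
    perm <- local({
        rng <- .seededPermutation(n, seed = 421965L)
        rng
    })
    cols <- grDevices::hsv(hues[perm], s = 0.65, v = 0.85)
    toupper(cols)
}

## fixed-seed permutation without touching the global RNG stream
.seededPermutation <- function(n, seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    sample.int(n)
}

#' Write iTOL annotation datasets
#'
#' Emits, into \code{outDir}: the gene tree in newick with internal labels
#' (\code{gene_tree.nwk}); a \code{DATASET_BINARY} file with one field per
#' function giving observed leaf presence (1 present, 0 absent, -1 unknown;
#' \code{itol_functions_binary.txt}); a \code{DATASET_DOMAINS} file drawing
#' every module segment as a 1-based span on its leaf protein
#' (\code{itol_modules_domains.txt}); and a plain-text legend mapping module
#' ids to their palette colors (\code{module_colors.txt}). Output is byte
#' deterministic.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param modules list of \linkS4class{SeqModule}.
#' @param records protein records data.frame (for sequence lengths).
#' @param functionTable \linkS4class{FunctionTable} or NULL to skip the
#'   binary dataset.
#' @param outDir output directory, created if needed.
#' @return character vector of file paths written.
#' @export
writeItolDatasets <- function(tree, modules, records, functionTable = NULL,
                              outDir = ".") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)

    treeFile <- file.path(outDir, "gene_tree.nwk")
    writeGeneTree(tree, treeFile)
    files <- c(files, treeFile)

    if (!is.null(functionTable)) {
        fns <- functionIds(functionTable)
        binFile <- file.path(outDir, "itol_functions_binary.txt")
        hdr <- c("DATASET_BINARY", "SEPARATOR TAB",
                 "DATASET_LABEL\tfunctions", "COLOR\t#2166AC",
                 paste(c("FIELD_SHAPES", rep("1", length(fns))),
                       collapse = "\t"),
                 paste(c("FIELD_LABELS", fns), collapse = "\t"),
                 paste(c("FIELD_COLORS",
                         modulePalette(length(fns))), collapse = "\t"),
                 "DATA")
        code <- c(present = "1", absent = "0", unknown = "-1")
        rows <- vapply(treeLeaves(tree), function(p) {
            paste(c(p, code[functionTable@state[p, fns]]), collapse = "\t")
        }, "")
        writeLines(c(hdr, rows), binFile)
        files <- c(files, binFile)
    }

    domFile <- file.path(outDir, "itol_modules_domains.txt")
    pal <- modulePalette(length(modules))
    names(pal) <- vapply(modules, moduleId, "")
    seqLen <- setNames(nchar(records$sequence), records$protein_id)
    domains <- setNames(vector("list", length(treeLeaves(tree))),
                        treeLeaves(tree))
    for (m in modules) {
        seg <- moduleSegments(m)
        for (i in seq_len(nrow(seg))) {
            p <- seg$protein_id[i]
            domains[[p]] <- c(domains[[p]],
                sprintf("RE|%d|%d|%s|%s", seg$start[i] + 1L, seg$end[i],
                        pal[[moduleId(m)]], moduleId(m)))
        }
    }
    hdr <- c("DATASET_DOMAINS", "SEPARATOR COMMA",
             "DATASET_LABEL,modules", "COLOR,#B2182B", "DATA")
    rows <- vapply(treeLeaves(tree), function(p) {
        paste(c(p, seqLen[[p]], domains[[p]]), collapse = ",")
    }, "")
    writeLines(c(hdr, rows), domFile)
    files <- c(files, domFile)

    legFile <- file.path(outDir, "module_colors.txt")
    writeLines(c("module_id\tcolor",
                 sprintf("%s\t%s", names(pal), pal)), legFile)
    files <- c(files, legFile)

    files
}
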
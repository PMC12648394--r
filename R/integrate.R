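## Joint mapping of module and function histories: per-node gain/loss events
## by parent comparison, co-emergence signatures, and the annotated output
## bundle with a hashed manifest.

#' Gain/loss events for one item along the gene tree
#'
#' One record per node: \code{gain} when present and the direct parent is
#' absent (root presence counts as a gain), \code{loss} when absent with a
#' present parent, \code{none} otherwise. Support is copied from the
#' presence map.
#'
#' @param presence \linkS4class{PresenceMap} keyed on every tree node.
#' @param tree \linkS4class{GeneTree}.
#' @return data.frame with columns \code{node_id,item_id,item_type,state,
#'   event,support}, one row per node in preorder.
#' @export
deriveGainLossEvents <- function(presence, tree) {
    nodes <- treeNodes(tree)
    st <- presenceState(presence)
    miss <- setdiff(nodes, names(st))
    if (length(miss)) stop("presence map missing node: ", miss[1L])
    ev <- vapply(nodes, function(n) {
        p <- tree@parent[[n]]
        here <- st[[n]]
        up <- if (is.na(p)) FALSE else st[[p]]
        if (here && !up) "gain" else if (!here && up) "loss" else "none"
    }, "")
    data.frame(node_id = nodes, item_id = presence@itemId,
               item_type = presence@itemType,
               state = ifelse(st[nodes], "present", "absent"),
               event = ev,
               support = unname(presenceSupport(presence)[nodes]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Module signatures of functions by co-emergence
#'
#' For every node where a function is gained, lists the modules gained at
#' the same node with support at least \code{minSupport}. A row is emitted
#' even when no module co-emerges (flagged in \code{note}). With
#' \code{relaxed = TRUE} modules gained at the node's direct parent also
#' qualify. The \code{retained_module_ids} column additionally lists modules
#' present (but not gained) at the function-gain node — conservation-based
#' candidates, reported as an extra, not as signature members.
#'
#' @param moduleEvents event data.frame for all modules (rows from
#'   \code{\link{deriveGainLossEvents}}).
#' @param functionEvents event data.frame for all functions.
#' @param tree \linkS4class{GeneTree} (used for the relaxed parent rule).
#' @param minSupport minimal support for signature membership, default 0.5.
#' @param relaxed also accept modules gained at the direct parent node.
#' @return data.frame with one row per (function, gain node): columns
#'   \code{function_id, gain_node_id, module_ids} (";"-joined),
#'   \code{n_modules, min_module_support, function_posterior,
#'   retained_module_ids, note}.
#' @export
coEmergenceSignatures <- function(moduleEvents, functionEvents, tree,
                                  minSupport = 0.5, relaxed = FALSE) {
    fg <- functionEvents[functionEvents$event == "gain", , drop = FALSE]
    rows <- lapply(seq_len(nrow(fg)), function(i) {
        node <- fg$node_id[i]
        okNodes <- node
        if (relaxed && !is.na(tree@parent[[node]]))
            okNodes <- c(okNodes, tree@parent[[node]])
        hit <- moduleEvents[moduleEvents$event == "gain" &
                            moduleEvents$node_id %in% okNodes &
                            moduleEvents$support >= minSupport, ,
                            drop = FALSE]
        mods <- sort(unique(hit$item_id))
        ret <- moduleEvents[moduleEvents$node_id == node &
                            moduleEvents$state == "present" &
                            moduleEvents$event != "gain" &
                            moduleEvents$support >= minSupport, ,
                            drop = FALSE]
        data.frame(function_id = fg$item_id[i], gain_node_id = node,
                   module_ids = paste(mods, collapse = ";"),
                   n_modules = length(mods),
                   min_module_support = if (length(mods))
                       min(hit$support[hit$item_id %in% mods]) else NA_real_,
                   function_posterior = fg$support[i],
                   retained_module_ids =
                       paste(sort(unique(ret$item_id)), collapse = ";"),
                   note = if (length(mods)) "" else "no co-emerging module",
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(function_id = character(),
                           gain_node_id = character(),
                           module_ids = character(), n_modules = integer(),
                           min_module_support = numeric(),
                           function_posterior = numeric(),
                           retained_module_ids = character(),
                           note = character(), stringsAsFactors = FALSE)
    out[order(out$function_id, out$gain_node_id), , drop = FALSE]
}

#' Write the annotated output bundle
#'
#' Writes the per-node event table, the signature CSV and the iTOL bundle
#' (gene tree, binary function dataset, module domains, color legend), and
#' returns a manifest listing every file with its md5 content hash. The
#' manifest itself is written as \code{manifest.csv}.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param records protein records data.frame.
#' @param modules list of \linkS4class{SeqModule}.
#' @param presence list of \linkS4class{PresenceMap} (modules and functions).
#' @param functionTable \linkS4class{FunctionTable}.
#' @param signatures signature data.frame from
#'   \code{\link{coEmergenceSignatures}}.
#' @param outDir output directory.
#' @return invisible manifest data.frame (\code{file}, \code{md5}).
#' @export
assembleAnnotatedTree <- function(tree, records, modules, presence,
                                  functionTable, signatures, outDir) {
    nodes <- treeNodes(tree)
    for (p in presence) {
        if (!identical(sort(names(presenceState(p))), sort(nodes)))
            stop("presence map for ", p@itemId,
                 " keyed on a different node set than the tree")
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)

    evFile <- file.path(outDir, "events.csv")
    writeEventTable(presence, tree, evFile)
    files <- c(files, evFile)

    sigFile <- file.path(outDir, "signatures.csv")
    utils::write.csv(signatures, sigFile, row.names = FALSE, quote = FALSE)
    files <- c(files, sigFile)

    modFile <- file.path(outDir, "modules.csv")
    writeModuleTable(modules, modFile)
    files <- c(files, modFile)

    files <- c(files, writeItolDatasets(tree, modules, records,
                                        functionTable, outDir))

    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(manifest)
}
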
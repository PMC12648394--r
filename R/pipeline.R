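## End-to-end orchestration: configuration, stage functions with resumable
## on-disk intermediates, and the one-shot runner. Every intermediate is a
## plain CSV in the output directory so any stage can be re-run (or fed
## hand-made inputs) independently.

#' Pipeline configuration
#'
#' @param fasta,tree,annotations input file paths (FASTA with trailing-taxid
#'   headers; rooted binary newick; annotation CSV).
#' @param outDir output directory for all intermediates and results.
#' @param speciesTree optional newick species tree; validated (leaf taxids
#'   must be a subset of the FASTA taxids) and copied into the output bundle
#'   but never used in inference.
#' @param annotatedIds optional file (one protein id per line) or character
#'   vector overriding the annotated subset.
#' @param k,minWidth,minPairScore,matrix detection parameters, see
#'   \code{\link{detectionParams}}.
#' @param dupCost,transferCost,lossCost reconciliation event costs.
#' @param nRuns reconciliation replicates per module, default 10.
#' @param baseSeed integer seed; every stochastic step derives its seed from
#'   it.
#' @param minSupport minimal support for signature membership, default 0.5.
#' @param relaxed relaxed (parent-inclusive) co-emergence, default FALSE.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(fasta, tree, annotations, outDir,
                           speciesTree = NULL, annotatedIds = NULL,
                           k = 4L, minWidth = 6L, minPairScore = NA,
                           matrix = "BLOSUM62", dupCost = 2,
                           transferCost = 3, lossCost = 1, nRuns = 10L,
                           baseSeed = 1L, minSupport = 0.5,
                           relaxed = FALSE) {
    if (nRuns < 1L) stop("nRuns must be >= 1")
    structure(list(fasta = fasta, tree = tree, annotations = annotations,
                   outDir = outDir, speciesTree = speciesTree,
                   annotatedIds = annotatedIds, k = as.integer(k),
                   minWidth = as.integer(minWidth),
                   minPairScore = minPairScore, matrix = matrix,
                   dupCost = dupCost, transferCost = transferCost,
                   lossCost = lossCost, nRuns = as.integer(nRuns),
                   baseSeed = as.integer(baseSeed),
                   minSupport = minSupport, relaxed = relaxed),
              class = "PipelineConfig")
}

#' Read / write a flat key=value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Keys
#' match the arguments of \code{\link{pipelineConfig}}.
#'
#' @param path config file.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed config line: ", lines[bad][1L])
    vals <- setNames(lapply(kv, function(x) {
        v <- x[2L]
        if (grepl("^(TRUE|FALSE)$", v)) as.logical(v)
        else if (grepl("^-?[0-9.eE+-]+$", v) &&
                 !is.na(suppressWarnings(as.numeric(v))))
            as.numeric(v)
        else v
    }), vapply(kv, `[[`, "", 1L))
    do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
    keep <- !vapply(config, is.null, TRUE)
    writeLines(sprintf("%s = %s", names(config)[keep],
                       vapply(config[keep], function(v)
                           paste(as.character(v), collapse = ","), "")),
               path)
    invisible(path)
}

.stageFail <- function(stage, msg) stop("[", stage, "] ", msg, call. = FALSE)

.loadInputs <- function(config) {
    records <- readProteinFasta(config$fasta)
    tree <- readGeneTree(config$tree, records)
    ft <- readFunctionTable(config$annotations, records,
                            annotatedIds = config$annotatedIds)
    if (!is.null(config$speciesTree) && nzchar(config$speciesTree)) {
        sp <- ape::read.tree(config$speciesTree)
        spTax <- suppressWarnings(as.integer(sub("^.*_", "", sp$tip.label)))
        spTax <- ifelse(is.na(spTax),
                        suppressWarnings(as.integer(sp$tip.label)), spTax)
        if (any(is.na(spTax)) || !all(spTax %in% records$taxid))
            .stageFail("input", "species tree leaf taxids not a subset of FASTA taxids")
    }
    list(records = records, tree = tree, functionTable = ft)
}

#' Run the module/function phylogenomics pipeline
#'
#' Executes (any subset of) the stages \code{detect} (module detection),
#' \code{presence} (per-module replicate DTL consensus), \code{asr}
#' (per-function ancestral reconstruction) and \code{integrate} (events,
#' signatures, iTOL bundle, manifest). Stages not requested are resumed
#' from the intermediates already present in \code{outDir}
#' (\code{modules.csv}, \code{module_presence.csv},
#' \code{function_posteriors.csv}), so hand-made intermediates can be
#' supplied before the final integration. All parameters and seeds are
#' logged to \code{run.log}; apart from the log's timestamp the output
#' directory is byte-deterministic in (inputs, config).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param stages character subset of
#'   \code{c("detect", "presence", "asr", "integrate")}.
#' @return invisible manifest data.frame of the integrate stage (or NULL if
#'   integrate was not run).
#' @export
runPipeline <- function(config,
                        stages = c("detect", "presence", "asr",
                                   "integrate")) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    inp <- .loadInputs(config)
    records <- inp$records; tree <- inp$tree; ft <- inp$functionTable
    log <- file.path(config$outDir, "run.log")
    logLine <- function(...) cat(..., "\n", sep = "", file = log,
                                 append = TRUE)
    cat("", file = log)
    logLine("# pipeline run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    for (k in names(config))
        logLine("param ", k, " = ",
                paste(as.character(config[[k]]), collapse = ","))

    modFile <- file.path(config$outDir, "modules.csv")
    presFile <- file.path(config$outDir, "module_presence.csv")
    postFile <- file.path(config$outDir, "function_posteriors.csv")

    params <- detectionParams(config$k, config$minWidth,
                              config$minPairScore, config$matrix)
    costs <- reconciliationCosts(config$dupCost, config$transferCost,
                                 config$lossCost)

    ## -- detect --
    if ("detect" %in% stages) {
        modules <- tryCatch(detectModules(records, params),
                            error = function(e) .stageFail("detect",
                                                           conditionMessage(e)))
        writeModuleTable(modules, modFile)
        logLine("detect: ", length(modules), " modules")
    } else {
        if (!file.exists(modFile)) {
            needer <- if ("presence" %in% stages) "presence" else "integrate"
            .stageFail(needer, "missing intermediate modules.csv")
        }
        modules <- readModuleTable(modFile)
    }

    ## -- presence --
    if ("presence" %in% stages) {
        presMod <- lapply(modules, function(m) {
            tryCatch(consensusPresence(m, tree, costs,
                                       nRuns = config$nRuns,
                                       baseSeed = config$baseSeed),
                     error = function(e) .stageFail("presence",
                                                    conditionMessage(e)))
        })
        writeEventTable(presMod, tree, presFile)
        logLine("presence: ", length(presMod), " modules x ",
                config$nRuns, " runs")
    } else if ("integrate" %in% stages) {
        if (!file.exists(presFile))
            .stageFail("integrate", "missing intermediate module_presence.csv")
        presMod <- readEventTable(presFile)
    } else presMod <- NULL

    ## -- asr --
    if ("asr" %in% stages) {
        asrList <- lapply(functionIds(ft), function(fn) {
            tryCatch(asrForFunction(tree, ft, fn),
                     error = function(e) .stageFail("asr",
                                                    conditionMessage(e)))
        })
        post <- do.call(rbind, lapply(asrList, function(a) {
            data.frame(node_id = names(asrPosterior(a)),
                       function_id = a@functionId,
                       posterior = unname(asrPosterior(a)),
                       state = ifelse(asrState(a), "present", "absent"),
                       stringsAsFactors = FALSE)
        }))
        if (is.null(post))
            post <- data.frame(node_id = character(),
                               function_id = character(),
                               posterior = numeric(), state = character())
        utils::write.csv(post, postFile, row.names = FALSE, quote = FALSE)
        presFun <- lapply(asrList, presenceFromAsr)
        logLine("asr: ", length(asrList), " functions")
    } else if ("integrate" %in% stages) {
        if (!file.exists(postFile))
            .stageFail("integrate",
                       "missing intermediate function_posteriors.csv")
        df <- utils::read.csv(postFile, stringsAsFactors = FALSE)
        presFun <- lapply(split(df, df$function_id), function(d) {
            methods::new("PresenceMap", itemId = d$function_id[1L],
                         itemType = "function",
                         state = setNames(d$state == "present", d$node_id),
                         support = setNames(d$posterior, d$node_id))
        })
    } else presFun <- NULL

    ## -- integrate --
    manifest <- NULL
    if ("integrate" %in% stages) {
        presAll <- c(presMod, presFun)
        modEv <- do.call(rbind, lapply(presMod, deriveGainLossEvents, tree))
        if (is.null(modEv))
            modEv <- data.frame(node_id = character(),
                                item_id = character(),
                                item_type = character(), state = character(),
                                event = character(), support = numeric())
        funEv <- do.call(rbind, lapply(presFun, deriveGainLossEvents, tree))
        if (is.null(funEv))
            funEv <- modEv[0, ]
        sig <- coEmergenceSignatures(modEv, funEv, tree,
                                     minSupport = config$minSupport,
                                     relaxed = config$relaxed)
        manifest <- tryCatch(
            assembleAnnotatedTree(tree, records, modules, presAll, ft, sig,
                                  config$outDir),
            error = function(e) .stageFail("integrate",
                                           conditionMessage(e)))
        if (!is.null(config$speciesTree) && nzchar(config$speciesTree))
            file.copy(config$speciesTree,
                      file.path(config$outDir, "species_tree.nwk"),
                      overwrite = TRUE)
        logLine("integrate: ", nrow(sig), " signature rows")
    }
    invisible(manifest)
}
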
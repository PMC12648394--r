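## Synthetic families with known ground truth: Yule gene trees, binary
## characters evolved under the two-state model, and sequences with planted
## conservation blocks inherited from chosen ancestral gene nodes. All
## simulations are reproducible from (parameters, seed) and never disturb
## the caller's RNG stream.

## Robinson-Robinson style background amino-acid composition (the standard
## frequencies underlying the BLOSUM construction), used for i.i.d.
## background residues.
.AA_BACKGROUND <- c(
    A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
    E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
    M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
    Y = 0.032, V = 0.065)

.PLANT_ALPHABET <- c("W", "Y", "F", "H")

#' Simulate a pure-birth (Yule) gene tree
#'
#' Birth rate 1, no extinction; branch lengths are the exponential waiting
#' times of the conditioned birth process. Leaves are labelled
#' \code{P01..Pn}. Deterministic for a fixed seed.
#'
#' @param nLeaves number of leaves (>= 2).
#' @param seed integer seed.
#' @return a \linkS4class{GeneTree}.
#' @export
simulateYuleTree <- function(nLeaves, seed = 1L) {
    if (nLeaves < 2L) stop("need at least 2 leaves")
    phy <- .withSeed(seed, ape::rphylo(nLeaves, birth = 1, death = 0))
    phy$tip.label <- sprintf("P%02d", seq_len(nLeaves))
    phy$node.label <- NULL
    geneTreeFromPhylo(phy)
}

#' Simulate one binary character on the gene tree
#'
#' The root state is drawn from the stationary distribution of the
#' two-state model and evolved down every branch with the model's
#' transition probabilities.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param alpha,beta gain and loss rates (alpha + beta > 0).
#' @param seed integer seed.
#' @return list with \code{leafStates} (named 0/1 over leaves) and
#'   \code{nodeStates} (named 0/1 over all nodes).
#' @export
simulateBinaryCharacter <- function(tree, alpha, beta, seed = 1L) {
    if (alpha < 0 || beta < 0 || alpha + beta <= 0)
        stop("need alpha, beta >= 0 with alpha + beta > 0")
    nodes <- treeNodes(tree)
    st <- .withSeed(seed, {
        s <- setNames(integer(length(nodes)), nodes)
        p1 <- alpha / (alpha + beta)
        s[treeRoot(tree)] <- as.integer(runif(1) < p1)
        for (n in nodes) {
            if (n == treeRoot(tree)) next
            P <- transitionMatrix(tree@brlen[[n]], alpha, beta)
            par <- tree@parent[[n]]
            s[n] <- as.integer(runif(1) < P[s[[par]] + 1L, 2L])
        }
        s
    })
    list(leafStates = st[treeLeaves(tree)], nodeStates = st)
}

## draw an ancestral segment whose 4-mers avoid `taken` (so distinct planted
## modules cannot seed anchors against each other)
.drawAncestralSegment <- function(width, alphabet, taken, k = 4L) {
    for (try in 1:200) {
        anc <- sample(alphabet, width, replace = TRUE)
        s <- paste(anc, collapse = "")
        kms <- substring(s, 1:(width - k + 1L), k:width)
        ## no internal k-mer repeats (no self-shifted seeds) and no k-mer
        ## shared with previously planted modules
        if (!anyDuplicated(kms) && !any(kms %in% taken)) return(anc)
    }
    stop("could not draw a seed-disjoint planted segment; ",
         "use fewer/narrower modules or a larger alphabet")
}

## evolve a planted ancestral segment down the subtree of `gain`, mutating
## each site with probability `rate` per branch (uniformly to another letter
## of the module alphabet); lineages under `lossNodes` are pruned
.evolveSegment <- function(tree, gain, width, rate, lossNodes, alphabet,
                           anc) {
    segs <- list()
    recurse <- function(node, seg) {
        if (node %in% lossNodes) return(invisible())
        if (.isLeaf(tree, node)) {
            segs[[node]] <<- seg
            return(invisible())
        }
        for (ch in treeChildren(tree, node)) {
            s <- seg
            if (rate > 0) {
                hit <- which(runif(length(s)) < rate)
                for (h in hit) {
                    s[h] <- sample(setdiff(alphabet, s[h]), 1L)
                }
            }
            recurse(ch, s)
        }
        invisible()
    }
    recurse(gain, anc)
    segs
}

#' Plant conservation modules into simulated sequences
#'
#' For each module spec an ancestral segment is generated at the spec's gain
#' node and inherited by all descendant leaves (lineages under loss nodes
#' are pruned), each branch mutating every site independently with the
#' spec's per-site substitution probability. Ancestral segments of distinct
#' modules are drawn so that they share no length-4 words, keeping planted
#' modules from seeding anchors against each other. Segments are inserted at
#' evenly spaced, recorded positions into i.i.d. background residues. With
#' \code{disjointAlphabet = TRUE} planted segments use only
#' \{W, Y, F, H\} and the background the remaining 16 letters — a test
#' device guaranteeing planted blocks share no seeds with the background.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param moduleSpecs list of specs, each a list with \code{gainNode},
#'   \code{width}, \code{rate} and optional \code{lossNodes}.
#' @param backgroundLength background residues per sequence, default 120.
#' @param seed integer seed.
#' @param disjointAlphabet see above; default FALSE (full 20-letter
#'   alphabet for plants, standard composition for background).
#' @return list with \code{records} (protein data.frame with taxids
#'   \code{1001, 1002, ...}) and \code{truth} (a ground-truth list: module
#'   table with gain/loss nodes, 0-based planted spans per leaf, the seed).
#' @export
plantModulesAndSequences <- function(tree, moduleSpecs,
                                     backgroundLength = 120L, seed = 1L,
                                     disjointAlphabet = FALSE) {
    leaves <- treeLeaves(tree)
    for (sp in moduleSpecs) {
        if (!sp$gainNode %in% treeNodes(tree))
            stop("gain node not in tree: ", sp$gainNode)
    }
    plantAb <- if (disjointAlphabet) .PLANT_ALPHABET
               else names(.AA_BACKGROUND)
    bgAb <- if (disjointAlphabet)
        setdiff(names(.AA_BACKGROUND), .PLANT_ALPHABET)
    else names(.AA_BACKGROUND)
    bgW <- .AA_BACKGROUND[bgAb] / sum(.AA_BACKGROUND[bgAb])

    res <- .withSeed(seed, {
        taken <- character(0)
        segsByModule <- lapply(seq_along(moduleSpecs), function(i) {
            sp <- moduleSpecs[[i]]
            anc <- .drawAncestralSegment(sp$width, plantAb, taken)
            s <- paste(anc, collapse = "")
            taken <<- c(taken, substring(s, 1:(sp$width - 3L), 4:sp$width))
            .evolveSegment(tree, sp$gainNode, sp$width, sp$rate,
                           if (is.null(sp$lossNodes)) character(0)
                           else sp$lossNodes, plantAb, anc)
        })
        seqs <- setNames(character(length(leaves)), leaves)
        spans <- list()
        for (lf in leaves) {
            mine <- which(vapply(segsByModule,
                                 function(s) lf %in% names(s), TRUE))
            k <- length(mine)
            gap <- backgroundLength %/% (k + 1L)
            pieces <- character(0)
            pos <- 0L
            used <- 0L
            for (q in seq_len(k)) {
                bg <- paste(sample(bgAb, gap, replace = TRUE, prob = bgW),
                            collapse = "")
                seg <- paste(segsByModule[[mine[q]]][[lf]], collapse = "")
                pieces <- c(pieces, bg, seg)
                pos <- pos + gap
                spans[[length(spans) + 1L]] <- data.frame(
                    module_id = paste0("pm", mine[q]), protein_id = lf,
                    start = pos, end = pos + nchar(seg),
                    stringsAsFactors = FALSE)
                pos <- pos + nchar(seg)
                used <- used + gap
            }
            tailLen <- backgroundLength - used
            pieces <- c(pieces, paste(sample(bgAb, tailLen, replace = TRUE,
                                             prob = bgW), collapse = ""))
            seqs[lf] <- paste(pieces, collapse = "")
        }
        list(seqs = seqs, spans = if (length(spans)) do.call(rbind, spans)
                                  else data.frame(module_id = character(),
                                                  protein_id = character(),
                                                  start = integer(),
                                                  end = integer()))
    })
    spanDf <- res$spans
    if (nrow(spanDf)) {
        bad <- unlist(lapply(split(spanDf, spanDf$protein_id), function(d) {
            d <- d[order(d$start), ]
            any(d$start[-1L] < d$end[-nrow(d)])
        }))
        if (any(bad)) stop("overlapping planted spans on one leaf")
    }
    records <- data.frame(protein_id = leaves,
                          taxid = 1000L + seq_along(leaves),
                          sequence = unname(res$seqs[leaves]),
                          stringsAsFactors = FALSE)
    moduleDf <- do.call(rbind, lapply(seq_along(moduleSpecs), function(i) {
        sp <- moduleSpecs[[i]]
        data.frame(module_id = paste0("pm", i), gain_node = sp$gainNode,
                   loss_nodes = paste(if (is.null(sp$lossNodes)) character(0)
                                      else sp$lossNodes, collapse = ";"),
                   width = sp$width, rate = sp$rate,
                   stringsAsFactors = FALSE)
    }))
    list(records = records,
         truth = list(modules = moduleDf, spans = spanDf, seed = seed))
}

#' Plant binary functions with known gain nodes
#'
#' Each function is present exactly at the descendant leaves of its gain
#' node (minus pruned loss lineages).
#'
#' @param tree \linkS4class{GeneTree}.
#' @param functionSpecs list of specs with \code{functionId},
#'   \code{gainNode}, optional \code{lossNodes}.
#' @return list with \code{annotations} (data.frame protein_id,function_id
#'   of present pairs) and \code{truth} data.frame.
#' @export
plantFunctions <- function(tree, functionSpecs) {
    rows <- list(); truth <- list()
    for (sp in functionSpecs) {
        loss <- if (is.null(sp$lossNodes)) character(0) else sp$lossNodes
        lv <- .leavesUnder(tree, sp$gainNode)
        for (l in loss) lv <- setdiff(lv, .leavesUnder(tree, l))
        if (length(lv))
            rows[[length(rows) + 1L]] <- data.frame(
                protein_id = lv, function_id = sp$functionId,
                stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
            function_id = sp$functionId, gain_node = sp$gainNode,
            loss_nodes = paste(loss, collapse = ";"),
            stringsAsFactors = FALSE)
    }
    list(annotations = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Write / read a ground-truth manifest
#'
#' Serializes the module truth table and planted spans to one CSV that
#' round-trips exactly.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{plantModulesAndSequences}}.
#' @param path CSV path.
#' @export
writeGroundTruth <- function(truth, path) {
    mod <- truth$modules; spn <- truth$spans
    mod2 <- data.frame(record = "module", module_id = mod$module_id,
                       gain_node = mod$gain_node,
                       loss_nodes = mod$loss_nodes, width = mod$width,
                       rate = mod$rate, protein_id = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
    spn2 <- data.frame(record = "span", module_id = spn$module_id,
                       gain_node = NA_character_,
                       loss_nodes = NA_character_, width = NA_integer_,
                       rate = NA_real_, protein_id = spn$protein_id,
                       start = spn$start, end = spn$end,
                       stringsAsFactors = FALSE)
    all <- rbind(mod2, spn2)
    all <- all[order(all$record, all$module_id, all$protein_id), ,
               drop = FALSE]
    utils::write.csv(all, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @return \code{readGroundTruth}: a list with \code{modules} and
#'   \code{spans} data.frames.
#' @export
readGroundTruth <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    mod <- df[df$record == "module",
              c("module_id", "gain_node", "loss_nodes", "width", "rate")]
    spn <- df[df$record == "span",
              c("module_id", "protein_id", "start", "end")]
    rownames(mod) <- rownames(spn) <- NULL
    mod$loss_nodes[is.na(mod$loss_nodes)] <- ""
    list(modules = mod, spans = spn)
}
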
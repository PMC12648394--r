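## Ancestral module presence: Dollo parsimony baseline, undated
## duplication-transfer-loss (DTL) reconciliation of a module tree into the
## gene tree by dynamic programming, conversion of a reconciliation into a
## per-node presence map, and replicate consensus with support frequencies.

#' Dollo-parsimony presence of a module
#'
#' Single gain at the last common ancestor of the carriers; a node is present
#' iff it descends from (or is) that ancestor and retains at least one
#' carrier leaf in its subtree. Support is 1 everywhere (the scenario is
#' unique).
#'
#' @param tree \linkS4class{GeneTree}.
#' @param carriers non-empty character vector of carrier leaf ids.
#' @param itemId id recorded on the returned map.
#' @return a \linkS4class{PresenceMap}.
#' @export
dolloPresence <- function(tree, carriers, itemId = "module") {
    if (!length(carriers)) stop("empty carrier set")
    if (!all(carriers %in% treeLeaves(tree)))
        stop("carrier not a leaf: ",
             setdiff(carriers, treeLeaves(tree))[1L])
    lca <- .lca(tree, carriers)
    below <- .descendants(tree, lca)
    state <- setNames(rep(FALSE, length(treeNodes(tree))), treeNodes(tree))
    for (n in below) {
        lv <- .leavesUnder(tree, n)
        state[n] <- any(lv %in% carriers)
    }
    methods::new("PresenceMap", itemId = itemId, itemType = "module",
                 state = state,
                 support = setNames(rep(1, length(state)), names(state)))
}

## ---- DTL dynamic programming ----

## internal tree tables on integer preorder indices for speed
.treeTables <- function(tree) {
    nodes <- treeNodes(tree)
    idx <- setNames(seq_along(nodes), nodes)
    n <- length(nodes)
    kids <- matrix(0L, n, 2L)
    par <- integer(n)
    for (nd in names(tree@children)) {
        ch <- tree@children[[nd]]
        kids[idx[[nd]], ] <- c(idx[[ch[1L]]], idx[[ch[2L]]])
        par[idx[[ch[1L]]]] <- idx[[nd]]
        par[idx[[ch[2L]]]] <- idx[[nd]]
    }
    list(nodes = nodes, idx = idx, kids = kids, parent = par,
         post = rev(seq_len(n)), isLeaf = kids[, 1L] == 0L)
}

#' Reconcile a module tree with the gene tree (undated DTL)
#'
#' Minimum-cost embedding of the module tree into the gene tree by dynamic
#' programming over (module node, gene node), with events speciation (free;
#' the two module children separate into the two gene subtrees), duplication
#' (both children stay in the same gene lineage), transfer (one child lands
#' on a gene node neither ancestor nor descendant of the donor), and
#' per-edge losses. Transfers are undated: time consistency is not enforced.
#' Ties are broken deterministically by gene-node preorder index, then by
#' event order speciation < duplication < transfer.
#'
#' @param moduleTree \linkS4class{GeneTree} over the carrier proteins, or a
#'   single carrier id (character) for the degenerate one-carrier case.
#' @param geneTree \linkS4class{GeneTree}.
#' @param costs \code{\link{reconciliationCosts}}.
#' @return a \linkS4class{Reconciliation}.
#' @export
dtlReconcile <- function(moduleTree, geneTree,
                         costs = reconciliationCosts()) {
    if (is.character(moduleTree) && length(moduleTree) == 1L) {
        if (!moduleTree %in% treeLeaves(geneTree))
            stop("carrier not a gene leaf: ", moduleTree)
        return(methods::new("Reconciliation",
            mapping = setNames(moduleTree, moduleTree),
            event = setNames("leaf", moduleTree),
            losses = character(0), gains = moduleTree,
            paths = setNames(list(moduleTree), moduleTree),
            totalCost = 0))
    }
    G <- .treeTables(geneTree)
    M <- .treeTables(moduleTree)
    bad <- setdiff(treeLeaves(moduleTree), treeLeaves(geneTree))
    if (length(bad)) stop("carrier not a gene leaf: ", bad[1L])
    dup <- costs[["dup"]]; tra <- costs[["transfer"]]; los <- costs[["loss"]]
    nG <- length(G$nodes)

    cTab <- inTab <- outTab <- vector("list", length(M$nodes))
    outWit <- vector("list", length(M$nodes))

    for (u in M$post) {
        cc <- rep(Inf, nG)
        if (M$isLeaf[u]) {
            cc[G$idx[[M$nodes[u]]]] <- 0
        } else {
            u1 <- M$kids[u, 1L]; u2 <- M$kids[u, 2L]
            in1 <- inTab[[u1]]; in2 <- inTab[[u2]]
            out1 <- outTab[[u1]]; out2 <- outTab[[u2]]
            for (g in seq_len(nG)) {
                spec <- Inf
                if (!G$isLeaf[g]) {
                    gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
                    spec <- min(in1[gl] + in2[gr], in1[gr] + in2[gl])
                }
                dd <- dup + in1[g] + in2[g]
                tt <- tra + min(in1[g] + out2[g], in2[g] + out1[g])
                cc[g] <- min(spec, dd, tt)
            }
        }
        ## in: cheapest placement of u at-or-below g, charging losses
        inn <- cc
        for (g in rev(seq_len(nG))) {
            if (!G$isLeaf[g]) {
                gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
                inn[g] <- min(cc[g], inn[gl] + los, inn[gr] + los)
            }
        }
        ## cmin: cheapest landing of u anywhere in the subtree of g (a
        ## transfer lands directly on its mapping node, no losses charged)
        cmin <- cc
        cminArg <- seq_len(nG)
        for (g in rev(seq_len(nG))) {
            if (!G$isLeaf[g]) {
                gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
                cands <- c(cc[g], cmin[gl], cmin[gr])
                args <- c(g, cminArg[gl], cminArg[gr])
                best <- min(cands)
                hit <- which(cands <= best + 1e-9 * max(1, abs(best)))
                cmin[g] <- best
                cminArg[g] <- min(args[hit])   # smallest preorder on ties
            }
        }
        ## out: cheapest landing of u on a node incomparable to g
        oo <- rep(Inf, nG); wit <- rep(NA_integer_, nG)
        for (g in seq_len(nG)) {
            if (G$parent[g] == 0L) next   # root: everything is comparable
            p <- G$parent[g]
            sib <- if (G$kids[p, 1L] == g) G$kids[p, 2L] else G$kids[p, 1L]
            cands <- c(oo[p], cmin[sib])
            wits <- c(wit[p], cminArg[sib])
            best <- min(cands)
            if (is.finite(best)) {
                hit <- which(abs(cands - best) <= 1e-9 * max(1, abs(best)))
                ## tie-break: smallest preorder index of the landing node
                wsel <- wits[hit]
                wsel <- wsel[!is.na(wsel)]
                wit[g] <- if (length(wsel)) min(wsel) else NA_integer_
                oo[g] <- best
            }
        }
        cTab[[u]] <- cc; inTab[[u]] <- inn
        outTab[[u]] <- oo; outWit[[u]] <- wit
    }

    rootU <- 1L
    rootCosts <- cTab[[rootU]]
    total <- min(rootCosts)
    if (!is.finite(total)) stop("no feasible reconciliation")
    gStar <- which(rootCosts <= total + 1e-9 * max(1, abs(total)))[1L]

    ## ---- backtracking ----
    mapping <- setNames(rep(NA_character_, length(M$nodes)), M$nodes)
    event <- setNames(rep(NA_character_, length(M$nodes)), M$nodes)
    losses <- character(0)
    gains <- G$nodes[gStar]
    paths <- setNames(vector("list", length(M$nodes)), M$nodes)

    near <- function(x, y) is.finite(x) && is.finite(y) &&
        abs(x - y) <= 1e-9 * max(1, abs(x), abs(y))

    ## descend the in-chain of u from g; returns final gene index, records
    ## losses; path is the chain of gene nodes visited (g first)
    resolveIn <- function(u, g) {
        chain <- g
        while (!near(inTab[[u]][g], cTab[[u]][g])) {
            gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
            if (near(inTab[[u]][g], inTab[[u]][gl] + los)) {
                losses <<- c(losses, G$nodes[gr])
                g <- gl
            } else {
                losses <<- c(losses, G$nodes[gl])
                g <- gr
            }
            chain <- c(chain, g)
        }
        list(g = g, chain = chain)
    }

    resolveEvent <- function(u, g) {
        mapping[M$nodes[u]] <<- G$nodes[g]
        if (M$isLeaf[u]) { event[M$nodes[u]] <<- "leaf"; return(invisible()) }
        u1 <- M$kids[u, 1L]; u2 <- M$kids[u, 2L]
        in1 <- inTab[[u1]]; in2 <- inTab[[u2]]
        out1 <- outTab[[u1]]; out2 <- outTab[[u2]]
        cc <- cTab[[u]][g]
        spec <- Inf; o1 <- o2 <- Inf
        if (!G$isLeaf[g]) {
            gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
            o1 <- in1[gl] + in2[gr]; o2 <- in1[gr] + in2[gl]
            spec <- min(o1, o2)
        }
        if (near(cc, spec)) {
            event[M$nodes[u]] <<- "speciation"
            gl <- G$kids[g, 1L]; gr <- G$kids[g, 2L]
            e1 <- if (near(spec, o1)) gl else gr
            e2 <- if (near(spec, o1)) gr else gl
            r1 <- resolveIn(u1, e1)
            r2 <- resolveIn(u2, e2)
            paths[[M$nodes[u1]]] <<- G$nodes[c(g, r1$chain)]
            paths[[M$nodes[u2]]] <<- G$nodes[c(g, r2$chain)]
            resolveEvent(u1, r1$g); resolveEvent(u2, r2$g)
        } else if (near(cc, dup + in1[g] + in2[g])) {
            event[M$nodes[u]] <<- "duplication"
            r1 <- resolveIn(u1, g)
            r2 <- resolveIn(u2, g)
            paths[[M$nodes[u1]]] <<- G$nodes[r1$chain]
            paths[[M$nodes[u2]]] <<- G$nodes[r2$chain]
            resolveEvent(u1, r1$g); resolveEvent(u2, r2$g)
        } else {
            event[M$nodes[u]] <<- "transfer"
            stay1 <- in1[g] + out2[g] <= in2[g] + out1[g] + 1e-12
            uStay <- if (stay1) u1 else u2
            uMove <- if (stay1) u2 else u1
            rs <- resolveIn(uStay, g)
            land <- if (stay1) outWit[[u2]][g] else outWit[[u1]][g]
            gains <<- c(gains, G$nodes[land])
            paths[[M$nodes[uStay]]] <<- G$nodes[rs$chain]
            paths[[M$nodes[uMove]]] <<- G$nodes[land]
            resolveEvent(uStay, rs$g); resolveEvent(uMove, land)
        }
        invisible()
    }

    paths[[M$nodes[rootU]]] <- G$nodes[gStar]
    resolveEvent(rootU, gStar)

    methods::new("Reconciliation", mapping = mapping, event = event,
                 losses = losses, gains = unique(gains), paths = paths,
                 totalCost = total)
}

#' Presence map implied by a reconciliation
#'
#' A gene node is present iff it lies on the gene-tree path covered by some
#' module-tree edge; for transfer edges only the recipient-side path from the
#' transfer landing node counts. Support is 1 for a single run.
#'
#' @param rec \linkS4class{Reconciliation}.
#' @param geneTree \linkS4class{GeneTree}.
#' @param itemId id recorded on the map.
#' @return a \linkS4class{PresenceMap}.
#' @export
presenceFromReconciliation <- function(rec, geneTree, itemId = "module") {
    covered <- unique(unlist(rec@paths, use.names = FALSE))
    nodes <- treeNodes(geneTree)
    state <- setNames(nodes %in% covered, nodes)
    methods::new("PresenceMap", itemId = itemId, itemType = "module",
                 state = state,
                 support = setNames(rep(1, length(nodes)), nodes))
}

#' Consensus module presence over reconciliation replicates
#'
#' Runs \code{\link{buildModuleTree}} (seed \code{baseSeed + run - 1}),
#' \code{\link{dtlReconcile}} and \code{\link{presenceFromReconciliation}}
#' \code{nRuns} times; the consensus state is the majority vote (a 0.5 tie
#' resolves to present) and the support is the fraction of runs predicting
#' presence.
#'
#' With \code{rootBy = "cost"} (the default) each replicate's NJ topology is
#' re-rooted at the edge minimizing the reconciliation cost, the midpoint
#' rooting winning ties: short module segments rarely carry enough signal to
#' place the root, and cost-optimal rooting plays the role the gene-tree-
#' template tree correction plays in conventional workflows.
#' \code{rootBy = "midpoint"} keeps the midpoint rooting as built.
#'
#' @param module \linkS4class{SeqModule}.
#' @param geneTree \linkS4class{GeneTree}.
#' @param costs \code{\link{reconciliationCosts}}.
#' @param nRuns number of replicates, default 10.
#' @param baseSeed seed of the first replicate.
#' @param rootBy \code{"cost"} or \code{"midpoint"}, see above.
#' @return a \linkS4class{PresenceMap} (support = replicate frequency).
#' @export
consensusPresence <- function(module, geneTree,
                              costs = reconciliationCosts(),
                              nRuns = 10L, baseSeed = 1L,
                              rootBy = c("cost", "midpoint")) {
    if (nRuns < 1L) stop("nRuns must be >= 1")
    rootBy <- match.arg(rootBy)
    nodes <- treeNodes(geneTree)
    votes <- matrix(FALSE, nRuns, length(nodes),
                    dimnames = list(NULL, nodes))
    for (r in seq_len(nRuns)) {
        mt <- buildModuleTree(module, seed = baseSeed + r - 1L)
        rec <- if (rootBy == "cost")
            .bestRootedReconciliation(mt, geneTree, costs)
        else dtlReconcile(mt, geneTree, costs)
        pm <- presenceFromReconciliation(rec, geneTree,
                                         itemId = moduleId(module))
        votes[r, ] <- presenceState(pm)[nodes]
    }
    supp <- colMeans(votes)
    methods::new("PresenceMap", itemId = moduleId(module),
                 itemType = "module",
                 state = setNames(supp >= 0.5, nodes),
                 support = setNames(supp, nodes))
}

## reconcile every rooting of the module tree's unrooted topology, keep the
## cheapest (first candidate -- the input rooting -- wins ties)
.bestRootedReconciliation <- function(moduleTree, geneTree, costs) {
    best <- NULL
    for (cand in rootingCandidates(moduleTree)) {
        rec <- dtlReconcile(cand, geneTree, costs)
        if (is.null(best) || rec@totalCost < best@totalCost - 1e-9)
            best <- rec
    }
    best
}
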
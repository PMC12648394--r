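## GeneTree construction and traversal helpers.
## Node ids are labels; internal tables are named vectors keyed on labels.

#' Build a GeneTree from an ape phylo object
#'
#' Validates that the tree is rooted and strictly binary, fills in missing
#' internal node labels as \code{"g0"}, \code{"g1"}, ... in preorder (root
#' first), and defaults missing branch lengths to 1.0 (root edge 0).
#'
#' @param phy an \code{ape::phylo}.
#' @param defaultBrlen branch length used when the newick carries none.
#' @return a \linkS4class{GeneTree}.
#' @export
geneTreeFromPhylo <- function(phy, defaultBrlen = 1.0) {
    if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
    ntip <- length(phy$tip.label)
    if (ntip < 2L) stop("tree must have >= 2 leaves")
    nChild <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
    bad <- which(nChild[(ntip + 1L):(ntip + phy$Nnode)] != 2L) + ntip
    if (length(bad)) {
        lab <- if (!is.null(phy$node.label)) phy$node.label[bad[1L] - ntip]
               else ""
        stop(sprintf("polytomy at node with %d children%s",
                     nChild[bad[1L]],
                     if (nzchar(lab) && !is.na(lab)) paste0(" (", lab, ")")
                     else ""))
    }
    if (anyDuplicated(phy$tip.label))
        stop("duplicate leaf label: ",
             phy$tip.label[duplicated(phy$tip.label)][1L])
    phy <- ape::reorder.phylo(phy, "cladewise")
    rootNum <- ntip + 1L
    preNums <- c(rootNum, phy$edge[, 2L])        # preorder over ape numbers
    intPre <- preNums[preNums > ntip]            # internal nodes in preorder
    lab <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
    lab[is.na(lab)] <- ""
    auto <- paste0("g", seq_along(intPre) - 1L)
    idx <- match(intPre, (ntip + 1L):(ntip + phy$Nnode))
    fill <- !nzchar(lab[idx])
    lab[idx[fill]] <- auto[fill]
    if (anyDuplicated(c(phy$tip.label, lab)))
        stop("duplicate node label after auto-labelling: ",
             c(phy$tip.label, lab)[duplicated(c(phy$tip.label, lab))][1L])
    phy$node.label <- lab
    labelOf <- c(phy$tip.label, lab)             # by ape number

    el <- phy$edge.length
    if (is.null(el)) el <- rep(defaultBrlen, nrow(phy$edge))
    el[is.na(el)] <- defaultBrlen

    nodes <- labelOf[preNums]
    parent <- setNames(rep(NA_character_, length(nodes)), nodes)
    brlen <- setNames(rep(0, length(nodes)), nodes)
    children <- vector("list", phy$Nnode)
    names(children) <- lab
    for (i in seq_len(nrow(phy$edge))) {
        p <- labelOf[phy$edge[i, 1L]]
        ch <- labelOf[phy$edge[i, 2L]]
        parent[ch] <- p
        brlen[ch] <- el[i]
        children[[p]] <- c(children[[p]], ch)
    }
    methods::new("GeneTree", phylo = phy, nodes = nodes,
                 root = labelOf[rootNum], parent = parent,
                 children = children, brlen = brlen,
                 leaves = phy$tip.label)
}

#' Read a rooted binary gene tree from a newick file
#'
#' The leaf set must coincide exactly with the protein ids of \code{records};
#' any mismatch is a hard error listing the symmetric difference. Missing
#' internal labels are auto-named \code{"gN"} in preorder and missing branch
#' lengths default to 1.0.
#'
#' @param path newick file.
#' @param records optional data.frame of protein records (from
#'   \code{\link{readProteinFasta}}) to validate leaves against.
#' @return a \linkS4class{GeneTree}.
#' @export
readGeneTree <- function(path, records = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    phy <- ape::read.tree(path)
    if (is.null(phy)) stop("could not parse newick in ", path)
    gt <- geneTreeFromPhylo(phy)
    if (!is.null(records)) {
        ids <- records$protein_id
        extra <- setdiff(treeLeaves(gt), ids)
        missing <- setdiff(ids, treeLeaves(gt))
        if (length(extra) || length(missing))
            stop("leaf/FASTA mismatch: ",
                 paste(c(sprintf("leaf %s not in FASTA", extra),
                         sprintf("protein %s not in tree", missing)),
                       collapse = "; "))
    }
    gt
}

#' Write a GeneTree to newick, internal labels included
#'
#' @param tree a \linkS4class{GeneTree}.
#' @param path output file.
#' @export
writeGeneTree <- function(tree, path) {
    ape::write.tree(asPhylo(tree), file = path)
    invisible(path)
}

## ---- internal traversal helpers ----

## integer index of each node in preorder
.nodeIndex <- function(tree) setNames(seq_along(tree@nodes), tree@nodes)

.isLeaf <- function(tree, node) !(node %in% names(tree@children))

## postorder node ids (children before parents)
.postorder <- function(tree) rev(tree@nodes)

## all descendants of `node`, including itself
.descendants <- function(tree, node) {
    out <- character(0)
    stack <- node
    while (length(stack)) {
        n <- stack[[1L]]; stack <- stack[-1L]
        out <- c(out, n)
        kids <- tree@children[[n]]
        if (!is.null(kids)) stack <- c(kids, stack)
    }
    out
}

.leavesUnder <- function(tree, node) {
    d <- .descendants(tree, node)
    d[d %in% tree@leaves]
}

## last common ancestor of a set of node ids
.lca <- function(tree, nodes) {
    stopifnot(length(nodes) >= 1L)
    depth <- function(n) {
        d <- 0L
        while (!is.na(tree@parent[[n]])) { n <- tree@parent[[n]]; d <- d + 1L }
        d
    }
    cur <- nodes[[1L]]
    for (other in nodes[-1L]) {
        a <- cur; b <- other
        da <- depth(a); db <- depth(b)
        while (da > db) { a <- tree@parent[[a]]; da <- da - 1L }
        while (db > da) { b <- tree@parent[[b]]; db <- db - 1L }
        while (a != b) { a <- tree@parent[[a]]; b <- tree@parent[[b]] }
        cur <- a
    }
    cur
}

## nodes on the path from ancestor `anc` down to `node` (inclusive both ends)
.pathDown <- function(tree, anc, node) {
    path <- node
    while (node != anc) {
        node <- tree@parent[[node]]
        if (is.na(node)) stop("'", anc, "' is not an ancestor")
        path <- c(node, path)
    }
    path
}
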
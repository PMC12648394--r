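## Distance-based module trees: Poisson-corrected p-distances, an in-package
## neighbor-joining with seeded tie-breaks on the Q criterion (the pipeline's
## only replicate-to-replicate stochasticity), and deterministic midpoint
## rooting. Negative NJ branch lengths are clamped to zero.

#' Pairwise distances between the segments of one module
#'
#' p-distance (fraction of mismatched columns) Poisson-corrected as
#' \code{d = -log(1 - p)} with \code{p} capped at 0.95.
#'
#' @param module a \linkS4class{SeqModule}.
#' @return symmetric numeric matrix with zero diagonal, dimnames the carrier
#'   protein ids.
#' @export
segmentDistanceMatrix <- function(module) {
    seg <- moduleSegments(module)
    chars <- lapply(seg$segment, function(s) strsplit(s, "")[[1L]])
    n <- length(chars)
    D <- matrix(0, n, n, dimnames = list(seg$protein_id, seg$protein_id))
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        p <- mean(chars[[i]] != chars[[j]])
        p <- min(p, 0.95)
        D[i, j] <- D[j, i] <- -log(1 - p)
    }
    D
}

## run expr with a private RNG stream seeded by `seed`; the global stream is
## untouched
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

## neighbor-joining over a named distance matrix; ties in Q (within 1e-9
## absolute-relative tolerance) are broken uniformly at random from the
## caller's RNG stream. Returns an unrooted tree as an adjacency structure:
## list(edges = data.frame(a, b, len), leaves).
.njUnrooted <- function(D) {
    labs <- rownames(D)
    n <- length(labs)
    stopifnot(n >= 3L)
    active <- labs
    d <- D
    edges <- data.frame(a = character(), b = character(), len = numeric(),
                        stringsAsFactors = FALSE)
    nextInternal <- 0L
    while (length(active) > 3L) {
        m <- length(active)
        R <- rowSums(d)
        Q <- (m - 2) * d - outer(R, R, `+`)
        diag(Q) <- Inf
        qmin <- min(Q)
        tol <- 1e-9 * max(1, abs(qmin))
        cand <- which(Q <= qmin + tol, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        pick <- if (nrow(cand) > 1L) cand[sample.int(nrow(cand), 1L), ]
                else cand[1L, ]
        i <- pick[[1L]]; j <- pick[[2L]]
        li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
        lj <- d[i, j] - li
        nextInternal <- nextInternal + 1L
        u <- paste0("u", nextInternal)
        edges <- rbind(edges, data.frame(
            a = c(u, u), b = active[c(i, j)],
            len = pmax(c(li, lj), 0), stringsAsFactors = FALSE))
        newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        d2 <- rbind(cbind(d[keep, keep, drop = FALSE],
                          pmax(newd[keep], 0)),
                    c(pmax(newd[keep], 0), 0))
        rownames(d2) <- colnames(d2) <- c(active[keep], u)
        d <- d2
        active <- c(active[keep], u)
    }
    ## final three clusters join at a central node
    nextInternal <- nextInternal + 1L
    ctr <- paste0("u", nextInternal)
    l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    edges <- rbind(edges, data.frame(
        a = rep(ctr, 3L), b = active,
        len = pmax(c(l1, l2, l3), 0), stringsAsFactors = FALSE))
    list(edges = edges, leaves = labs)
}

## deterministic midpoint rooting of the unrooted adjacency structure.
## The longest leaf-to-leaf path is found (ties: lexicographically smallest
## leaf pair); the root splits the edge containing the path midpoint. A
## zero-length longest path roots on its first edge.
.adjacency <- function(ed) {
    nodes <- unique(c(ed$a, ed$b))
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (r in seq_len(nrow(ed))) {
        adj[[ed$a[r]]] <- c(adj[[ed$a[r]]], list(list(to = ed$b[r],
                                                      len = ed$len[r])))
        adj[[ed$b[r]]] <- c(adj[[ed$b[r]]], list(list(to = ed$a[r],
                                                      len = ed$len[r])))
    }
    adj
}

## newick for the tree rooted inside edge (a, b), a-side length la, b-side lb
.rootAtEdge <- function(adj, a, b, la, lb) {
    buildNewick <- function(node, from) {
        kids <- Filter(function(nb) nb$to != from, adj[[node]])
        if (!length(kids)) return(node)
        parts <- vapply(kids, function(nb)
            sprintf("%s:%.10g", buildNewick(nb$to, node), nb$len), "")
        sprintf("(%s)", paste(parts, collapse = ","))
    }
    sprintf("(%s:%.10g,%s:%.10g);",
            buildNewick(a, b), la, buildNewick(b, a), lb)
}

.midpointRoot <- function(un) {
    ed <- un$edges
    nodes <- unique(c(ed$a, ed$b))
    adj <- .adjacency(ed)
    dists <- function(src) {
        dd <- setNames(rep(NA_real_, length(nodes)), nodes)
        prev <- setNames(rep(NA_character_, length(nodes)), nodes)
        dd[src] <- 0
        queue <- src
        while (length(queue)) {
            u <- queue[[1L]]; queue <- queue[-1L]
            for (nb in adj[[u]]) {
                if (is.na(dd[nb$to])) {
                    dd[nb$to] <- dd[u] + nb$len
                    prev[nb$to] <- u
                    queue <- c(queue, nb$to)
                }
            }
        }
        list(d = dd, prev = prev)
    }
    leaves <- sort(un$leaves)
    best <- NULL
    for (lf in leaves) {
        r <- dists(lf)
        for (other in leaves) {
            if (other <= lf) next
            if (is.null(best) || r$d[other] > best$d + 1e-12) {
                best <- list(from = lf, to = other, d = unname(r$d[other]),
                             prev = r$prev)
            }
        }
    }
    ## reconstruct path from -> to
    path <- best$to
    while (path[1L] != best$from) path <- c(best$prev[[path[1L]]], path)
    half <- best$d / 2
    cum <- 0
    rootEdge <- NULL
    for (s in seq_len(length(path) - 1L)) {
        a <- path[s]; b <- path[s + 1L]
        len <- NA_real_
        for (nb in adj[[a]]) if (nb$to == b) { len <- nb$len; break }
        if (cum + len >= half - 1e-12 || s == length(path) - 1L) {
            rootEdge <- list(a = a, b = b, la = max(half - cum, 0),
                             lb = max(len - (half - cum), 0))
            break
        }
        cum <- cum + len
    }
    .rootAtEdge(adj, rootEdge$a, rootEdge$b, rootEdge$la, rootEdge$lb)
}

#' All rootings of a module tree's unrooted topology
#'
#' One candidate per edge of the unrooted tree (the input's own rooting
#' first), in deterministic order. Used to place the module-tree root at the
#' reconciliation-cost optimum.
#'
#' @param tree a rooted binary \linkS4class{GeneTree}.
#' @return list of \linkS4class{GeneTree}, the input first.
#' @export
rootingCandidates <- function(tree) {
    phy <- asPhylo(tree)
    if (length(phy$tip.label) == 2L) return(list(tree))
    un <- ape::unroot(phy)
    labelOf <- c(un$tip.label,
                 if (is.null(un$node.label)) paste0("n", seq_len(un$Nnode))
                 else un$node.label)
    labelOf[!nzchar(labelOf)] <- paste0("n", which(!nzchar(labelOf)))
    ed <- data.frame(a = labelOf[un$edge[, 1L]], b = labelOf[un$edge[, 2L]],
                     len = if (is.null(un$edge.length))
                         rep(1, nrow(un$edge)) else un$edge.length,
                     stringsAsFactors = FALSE)
    adj <- .adjacency(ed)
    out <- list(tree)
    for (r in seq_len(nrow(ed))) {
        nwk <- .rootAtEdge(adj, ed$a[r], ed$b[r], ed$len[r] / 2,
                           ed$len[r] / 2)
        out[[length(out) + 1L]] <-
            geneTreeFromPhylo(ape::read.tree(text = nwk))
    }
    out
}

#' Build a module tree by seeded neighbor-joining
#'
#' Neighbor-joining on the Poisson-corrected segment distance matrix, with
#' Q-criterion ties broken uniformly at random from a private RNG stream
#' seeded by \code{seed} (identical seeds give identical trees; different
#' seeds can differ only when ties exist). The unrooted NJ tree is
#' midpoint-rooted with deterministic tie-breaks. Modules with exactly two
#' carriers yield the unique cherry without invoking NJ.
#'
#' @param module a \linkS4class{SeqModule} with >= 2 carriers.
#' @param seed integer seed for tie-breaking.
#' @return a \linkS4class{GeneTree} whose leaves are the carrier proteins.
#' @export
buildModuleTree <- function(module, seed = 1L) {
    seg <- moduleSegments(module)
    if (nrow(seg) < 2L) stop("module tree needs >= 2 carriers")
    if (nrow(seg) == 2L) {
        D <- segmentDistanceMatrix(module)
        nwk <- sprintf("(%s:%.10g,%s:%.10g);", seg$protein_id[1L],
                       D[1, 2] / 2, seg$protein_id[2L], D[1, 2] / 2)
        return(geneTreeFromPhylo(ape::read.tree(text = nwk)))
    }
    D <- segmentDistanceMatrix(module)
    nwk <- .withSeed(seed, {
        un <- .njUnrooted(D)
        .midpointRoot(un)
    })
    geneTreeFromPhylo(ape::read.tree(text = nwk))
}
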
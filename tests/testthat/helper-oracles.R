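# Independent oracles used to validate the package's algorithms by
# enumeration / brute force on small instances. These deliberately avoid the
# package's DP/pruning code paths.

gtree <- function(newick) geneTreeFromPhylo(ape::read.tree(text = newick))

nodeDepths <- function(tree) {
    vapply(treeNodes(tree), function(n) {
        d <- 0L
        while (!is.na(tree@parent[[n]])) {
            n <- tree@parent[[n]]; d <- d + 1L
        }
        d
    }, 0L)
}

# ---- DTL oracle: enumerate all mappings of internal module nodes ----

oracleDtlCost <- function(moduleTree, geneTree, costs) {
    gN <- treeNodes(geneTree)
    desc <- lapply(gN, function(n) phyloModules:::.descendants(geneTree, n))
    names(desc) <- gN
    depth <- nodeDepths(geneTree)
    below <- function(a, b) a %in% desc[[b]]          # a at-or-below b
    incomp <- function(a, b) !below(a, b) && !below(b, a)
    plen <- function(top, bot) depth[[bot]] - depth[[top]]
    dup <- costs[["dup"]]; tra <- costs[["transfer"]]; los <- costs[["loss"]]

    mN <- treeNodes(moduleTree)
    internals <- names(moduleTree@children)
    leafMap <- setNames(treeLeaves(moduleTree), treeLeaves(moduleTree))

    grid <- do.call(expand.grid, c(
        setNames(rep(list(gN), length(internals)), internals),
        list(stringsAsFactors = FALSE)))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
        sigma <- c(unlist(grid[r, , drop = FALSE]), leafMap)
        tot <- 0
        for (u in internals) {
            g <- sigma[[u]]
            kids <- treeChildren(moduleTree, u)
            h1 <- sigma[[kids[1L]]]; h2 <- sigma[[kids[2L]]]
            ev <- Inf
            if (!phyloModules:::.isLeaf(geneTree, g)) {
                gc <- treeChildren(geneTree, g)
                if (below(h1, gc[1L]) && below(h2, gc[2L]))
                    ev <- min(ev, los * (plen(gc[1L], h1) + plen(gc[2L], h2)))
                if (below(h1, gc[2L]) && below(h2, gc[1L]))
                    ev <- min(ev, los * (plen(gc[2L], h1) + plen(gc[1L], h2)))
            }
            if (below(h1, g) && below(h2, g))
                ev <- min(ev, dup + los * (plen(g, h1) + plen(g, h2)))
            if (below(h1, g) && incomp(h2, g))
                ev <- min(ev, tra + los * plen(g, h1))
            if (below(h2, g) && incomp(h1, g))
                ev <- min(ev, tra + los * plen(g, h2))
            tot <- tot + ev
            if (!is.finite(tot)) break
        }
        if (tot < best) best <- tot
    }
    best
}

# ---- Dollo oracle: enumerate all single-gain labelings ----

oracleDolloStates <- function(tree, carriers) {
    nodes <- treeNodes(tree)
    internals <- names(tree@children)
    fixed <- setNames(treeLeaves(tree) %in% carriers, treeLeaves(tree))
    bestLoss <- Inf; bestSets <- list()
    for (mask in 0:(2^length(internals) - 1L)) {
        st <- c(fixed,
                setNames(bitwAnd(mask, bitwShiftL(1L,
                    seq_along(internals) - 1L)) != 0L, internals))
        st <- st[nodes]
        gains <- 0L; losses <- 0L
        for (n in nodes) {
            p <- tree@parent[[n]]
            up <- if (is.na(p)) FALSE else st[[p]]
            if (st[[n]] && !up) gains <- gains + 1L
            if (!st[[n]] && up) losses <- losses + 1L
        }
        if (gains != 1L) next
        if (losses < bestLoss) { bestLoss <- losses; bestSets <- list(st) }
        else if (losses == bestLoss) bestSets <- c(bestSets, list(st))
    }
    bestSets
}

# ---- ASR oracle: exhaustive sum over unobserved node states ----

oracleAsr <- function(tree, leafStates, alpha, beta) {
    nodes <- treeNodes(tree)
    obs <- leafStates[!is.na(leafStates)]
    free <- setdiff(nodes, names(obs))
    p1 <- alpha / (alpha + beta)
    pri <- c(1 - p1, p1)
    probOf <- function(st) {
        pr <- pri[st[[treeRoot(tree)]] + 1L]
        for (n in nodes) {
            if (n == treeRoot(tree)) next
            P <- transitionMatrix(tree@brlen[[n]], alpha, beta)
            pr <- pr * P[st[[tree@parent[[n]]]] + 1L, st[[n]] + 1L]
        }
        pr
    }
    tot <- 0
    postNum <- setNames(numeric(length(nodes)), nodes)
    for (mask in 0:(2^length(free) - 1L)) {
        st <- c(as.list(obs),
                setNames(as.list(as.integer(bitwAnd(mask,
                    bitwShiftL(1L, seq_along(free) - 1L)) != 0L)), free))
        pr <- probOf(st)
        tot <- tot + pr
        ones <- names(st)[unlist(st) == 1L]
        postNum[ones] <- postNum[ones] + pr
    }
    list(logLik = log(tot), posterior = postNum / tot)
}

# ---- compatibility checker & max-weight subset (independent of detect.R) --

segIntervals <- function(m) {
    s <- moduleSegments(m)
    setNames(lapply(seq_len(nrow(s)), function(i) c(s$start[i], s$end[i])),
             s$protein_id)
}

pairCompatible <- function(m1, m2) {
    i1 <- segIntervals(m1); i2 <- segIntervals(m2)
    shared <- intersect(names(i1), names(i2))
    if (!length(shared)) return(TRUE)
    signs <- character(0)
    for (p in shared) {
        a <- i1[[p]]; b <- i2[[p]]
        if (max(a[1], b[1]) < min(a[2], b[2])) return(FALSE)
        signs <- c(signs, if (a[1] < b[1]) "L" else "R")
    }
    all(signs == signs[1])
}

allPairsCompatible <- function(mods) {
    if (length(mods) < 2L) return(TRUE)
    for (i in seq_len(length(mods) - 1L)) for (j in (i + 1L):length(mods))
        if (!pairCompatible(mods[[i]], mods[[j]])) return(FALSE)
    TRUE
}

bruteForceMaxWeight <- function(mods) {
    n <- length(mods)
    bestW <- -Inf; best <- list()
    for (mask in 0:(2^n - 1L)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
        sub <- mods[sel]
        if (!allPairsCompatible(sub)) next
        w <- sum(vapply(sub, moduleScore, 0))
        if (w > bestW + 1e-9) { bestW <- w; best <- sub }
    }
    list(weight = bestW, modules = best)
}

# ---- small random instance generators ----

makeModule <- function(id, carriers, starts, width, score) {
    seg <- data.frame(protein_id = carriers, start = as.integer(starts),
                      end = as.integer(starts + width),
                      segment = strrep("A", width),
                      stringsAsFactors = FALSE)
    methods::new("SeqModule", moduleId = id, segments = seg,
                 width = as.integer(width), score = score)
}

randomCandidateSet <- function(n, proteins = c("A", "B", "C")) {
    lapply(seq_len(n), function(i) {
        carriers <- sort(sample(proteins, sample(2:length(proteins), 1L)))
        width <- sample(6:10, 1L)
        makeModule(paste0("r", i), carriers,
                   sample(0:40, length(carriers), replace = TRUE), width,
                   score = round(runif(1, 5, 50), 1))
    })
}

randomBinaryGeneTree <- function(nLeaves, seed,
                                 labels = LETTERS[seq_len(nLeaves)]) {
    phy <- phyloModules:::.withSeed(seed,
        ape::rphylo(nLeaves, birth = 1, death = 0))
    phy$tip.label <- labels
    phy$node.label <- NULL
    geneTreeFromPhylo(phy)
}

# random rooted binary module-tree topology over the given carrier labels
randomModuleTopology <- function(carriers, seed) {
    phyloModules:::.withSeed(seed, {
        groups <- as.list(sample(carriers))
        while (length(groups) > 1L) {
            i <- sample(length(groups), 2L)
            merged <- sprintf("(%s:1,%s:1)", groups[[i[1L]]],
                              groups[[i[2L]]])
            groups <- c(groups[-i], merged)
        }
        gtree(paste0(groups[[1L]], ";"))
    })
}
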
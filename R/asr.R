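## Maximum-likelihood ancestral reconstruction of a binary function on the
## gene tree under a two-state continuous-time Markov model. Unknown leaves
## are missing data (partial likelihood 1 for both states); the root is
## combined with the stationary frequencies. Zero branch lengths are clamped
## to 1e-8 so transition matrices stay well defined.

.MIN_BRLEN <- 1e-8

#' Two-state transition probability matrix
#'
#' @param t branch length (clamped below at 1e-8).
#' @param alpha gain rate (0 to 1).
#' @param beta loss rate (1 to 0).
#' @return 2x2 matrix with rows/cols in state order (0, 1); rows sum to 1.
#' @export
transitionMatrix <- function(t, alpha, beta) {
    t <- max(t, .MIN_BRLEN)
    r <- alpha + beta
    e <- exp(-r * t)
    p1 <- alpha / r
    p01 <- p1 * (1 - e)
    p10 <- (1 - p1) * (1 - e)
    matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
           dimnames = list(c("0", "1"), c("0", "1")))
}

## normalize leaf states to an integer vector (0, 1, NA) keyed by leaf
.normLeafStates <- function(tree, leafStates) {
    lv <- treeLeaves(tree)
    miss <- setdiff(lv, names(leafStates))
    if (length(miss)) stop("leaf without state: ", miss[1L])
    x <- leafStates[lv]
    if (is.character(x)) {
        y <- rep(NA_integer_, length(x))
        y[x %in% c("1", "present")] <- 1L
        y[x %in% c("0", "absent")] <- 0L
        x <- y
    }
    x <- as.integer(x)
    names(x) <- lv
    if (all(is.na(x))) stop("all leaves unknown: nothing to reconstruct")
    x
}

## post-order partial likelihoods with per-node log scaling.
## Returns list(partial = matrix nodes x 2, logScale = named numeric).
.downPass <- function(tree, states, alpha, beta) {
    nodes <- treeNodes(tree)
    L <- matrix(NA_real_, length(nodes), 2L,
                dimnames = list(nodes, c("0", "1")))
    logScale <- setNames(rep(0, length(nodes)), nodes)
    for (n in .postorder(tree)) {
        if (.isLeaf(tree, n)) {
            s <- states[[n]]
            L[n, ] <- if (is.na(s)) c(1, 1) else if (s == 0L) c(1, 0)
                      else c(0, 1)
        } else {
            kids <- treeChildren(tree, n)
            v <- c(1, 1)
            sc <- 0
            for (ch in kids) {
                P <- transitionMatrix(tree@brlen[[ch]], alpha, beta)
                v <- v * as.vector(P %*% L[ch, ])
                sc <- sc + logScale[[ch]]
            }
            m <- max(v)
            if (m <= 0) { L[n, ] <- c(0, 0); logScale[n] <- -Inf }
            else { L[n, ] <- v / m; logScale[n] <- sc + log(m) }
        }
    }
    list(partial = L, logScale = logScale)
}

#' Log-likelihood of leaf states under a two-state model
#'
#' Felsenstein pruning over the gene tree; unknown leaves contribute partial
#' likelihood 1 for both states and the root partials are combined with the
#' stationary frequencies.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param leafStates named vector over all leaves: 0/1/NA (or
#'   "present"/"absent"/"unknown").
#' @param model \linkS4class{TwoStateModel}.
#' @return log-likelihood (numeric scalar).
#' @export
pruningLikelihood <- function(tree, leafStates, model) {
    states <- .normLeafStates(tree, leafStates)
    dp <- .downPass(tree, states, model@alpha, model@beta)
    pi_ <- stationaryFreq(model)
    root <- treeRoot(tree)
    lik <- sum(pi_ * dp$partial[root, ])
    if (lik <= 0) return(-Inf)
    log(lik) + dp$logScale[[root]]
}

#' Fit the two-state model by maximum likelihood
#'
#' Bounded 2-D optimization over log rates in [1e-6, 1e2], multi-started
#' from a fixed 3x3 grid of rates; deterministic. Boundary optima are
#' returned with the \code{boundary} flag set.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param leafStates as in \code{\link{pruningLikelihood}} (>= 2 observed
#'   leaves recommended).
#' @return a fitted \linkS4class{TwoStateModel} with its \code{logLik}.
#' @export
fitTwoStateModel <- function(tree, leafStates) {
    states <- .normLeafStates(tree, leafStates)
    nll <- function(lr) {
        a <- exp(lr[1L]); b <- exp(lr[2L])
        dp <- .downPass(tree, states, a, b)
        root <- treeRoot(tree)
        pi_ <- c(b, a) / (a + b)
        lik <- sum(pi_ * dp$partial[root, ])
        if (lik <= 0 || !is.finite(dp$logScale[[root]])) return(1e10)
        -(log(lik) + dp$logScale[[root]])
    }
    lo <- log(1e-6); hi <- log(1e2)
    grid <- log(c(0.01, 0.5, 10))
    best <- NULL
    for (ga in grid) for (gb in grid) {
        fit <- stats::optim(c(ga, gb), nll, method = "L-BFGS-B",
                            lower = lo, upper = hi)
        if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
    }
    lr <- best$par
    onBound <- any(lr <= lo + 1e-6) || any(lr >= hi - 1e-6)
    methods::new("TwoStateModel", alpha = exp(lr[1L]), beta = exp(lr[2L]),
                 logLik = -best$value, boundary = onBound)
}

#' Marginal posterior state probabilities at every node
#'
#' Up-down algorithm combining rootward (outside) and leafward (pruning)
#' partials; per-node posteriors sum to one and observed leaves are pinned
#' exactly to their state.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param leafStates as in \code{\link{pruningLikelihood}}.
#' @param model \linkS4class{TwoStateModel} (fitted or supplied).
#' @param functionId id recorded on the result.
#' @return an \linkS4class{AncestralStateMap}.
#' @export
marginalPosteriors <- function(tree, leafStates, model,
                               functionId = "function") {
    states <- .normLeafStates(tree, leafStates)
    dp <- .downPass(tree, states, model@alpha, model@beta)
    L <- dp$partial
    pi_ <- stationaryFreq(model)
    nodes <- treeNodes(tree)
    O <- matrix(NA_real_, length(nodes), 2L,
                dimnames = list(nodes, c("0", "1")))
    O[treeRoot(tree), ] <- pi_
    for (n in nodes) {                      # preorder: parents first
        if (.isLeaf(tree, n)) next
        kids <- treeChildren(tree, n)
        msg <- lapply(kids, function(ch) {
            P <- transitionMatrix(tree@brlen[[ch]], model@alpha, model@beta)
            as.vector(P %*% L[ch, ])        # message from child to n
        })
        names(msg) <- kids
        for (ch in kids) {
            others <- setdiff(kids, ch)
            up <- O[n, ]
            for (b in others) up <- up * msg[[b]]
            P <- transitionMatrix(tree@brlen[[ch]], model@alpha, model@beta)
            oc <- as.vector(t(P) %*% up)    # sum over parent state
            m <- max(oc)
            O[ch, ] <- if (m > 0) oc / m else c(0, 0)
        }
    }
    post <- setNames(rep(NA_real_, length(nodes)), nodes)
    for (n in nodes) {
        w <- O[n, ] * L[n, ]
        tot <- sum(w)
        post[n] <- if (tot > 0) w[2L] / tot else 0.5
    }
    methods::new("AncestralStateMap", functionId = functionId,
                 posterior = post, state = post >= 0.5, model = model)
}

#' Call binary ancestral states from posteriors
#'
#' Present iff the marginal posterior of presence is at least 0.5 (the exact
#' tie resolves to present); the posterior is retained as support.
#'
#' @param asr an \linkS4class{AncestralStateMap}.
#' @return the map with states recomputed from its posteriors.
#' @export
mapAncestralStates <- function(asr) {
    methods::new("AncestralStateMap", functionId = asr@functionId,
                 posterior = asr@posterior, state = asr@posterior >= 0.5,
                 model = asr@model)
}

#' Ancestral reconstruction of one annotated function
#'
#' Convenience wrapper: extracts the function's leaf states from the
#' annotation table (unknown proteins are missing data), fits the two-state
#' model, and computes marginal posteriors.
#'
#' @param tree \linkS4class{GeneTree}.
#' @param functionTable \linkS4class{FunctionTable}.
#' @param fn function id.
#' @return an \linkS4class{AncestralStateMap}.
#' @export
asrForFunction <- function(tree, functionTable, fn) {
    lv <- treeLeaves(tree)
    st <- functionTable@state[lv, fn]
    model <- fitTwoStateModel(tree, st)
    marginalPosteriors(tree, st, model, functionId = fn)
}

#' Convert an ancestral state map to a PresenceMap
#'
#' @param asr \linkS4class{AncestralStateMap}.
#' @return a \linkS4class{PresenceMap} with \code{itemType = "function"} and
#'   support equal to the marginal posterior of presence.
#' @export
presenceFromAsr <- function(asr) {
    methods::new("PresenceMap", itemId = asr@functionId,
                 itemType = "function", state = asr@state,
                 support = asr@posterior)
}
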
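#' @import methods
#' @importFrom stats optim runif setNames
#' @importFrom utils read.csv write.csv
NULL

setOldClass("phylo")

#' Rooted binary gene tree
#'
#' Wraps an \pkg{ape} \code{phylo} object and precomputed traversal tables for
#' a rooted, strictly binary tree whose leaves are protein identifiers.
#' Internal nodes carry unique labels; labels missing in the input newick are
#' auto-generated as \code{"g0"}, \code{"g1"}, ... in preorder (root first).
#' The same class is used for module trees (leaves are then the carrier
#' proteins of one module).
#'
#' @slot phylo the underlying \code{ape::phylo} object, node labels filled in.
#' @slot nodes character, all node ids in preorder (root first).
#' @slot root character(1), the root node id.
#' @slot parent named character, parent id per node (\code{NA} for the root).
#' @slot children named list, the (left, right) child ids per internal node.
#' @slot brlen named numeric, length of the edge above each node (root 0).
#' @slot leaves character, the leaf labels in \code{phylo} tip order.
#'
#' @exportClass GeneTree
setClass("GeneTree",
    representation(phylo = "phylo", nodes = "character", root = "character",
                   parent = "character", children = "list",
                   brlen = "numeric", leaves = "character"))

setValidity("GeneTree", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node ids")
    if (!object@root %in% object@nodes)
        msg <- c(msg, "root not among nodes")
    if (!all(lengths(object@children) == 2L))
        msg <- c(msg, "tree is not strictly binary")
    nInt <- length(object@children)
    if (length(object@leaves) != nInt + 1L)
        msg <- c(msg, "leaf/internal count mismatch for a binary tree")
    if (any(object@brlen < 0))
        msg <- c(msg, "negative branch length")
    if (length(msg)) msg else TRUE
})

#' Sequence conservation module
#'
#' An ungapped block of aligned, mutually similar segments shared by at least
#' two proteins (at most one segment per protein, all of equal width).
#' Segment coordinates are 0-based half-open internally; all serialized
#' output uses 1-based inclusive positions.
#'
#' @slot moduleId character(1) identifier, e.g. \code{"m1"}.
#' @slot segments data.frame with columns \code{protein_id}, \code{start}
#'   (0-based inclusive), \code{end} (0-based exclusive), \code{segment}.
#' @slot width integer(1), common segment width.
#' @slot score numeric(1), sum of pairwise ungapped substitution scores.
#'
#' @exportClass SeqModule
setClass("SeqModule",
    representation(moduleId = "character", segments = "data.frame",
                   width = "integer", score = "numeric"))

setValidity("SeqModule", function(object) {
    seg <- object@segments
    msg <- character()
    need <- c("protein_id", "start", "end", "segment")
    if (!all(need %in% names(seg)))
        return(paste("segments must have columns", paste(need, collapse = ", ")))
    if (nrow(seg) < 2L) msg <- c(msg, "module quorum is 2: need >= 2 segments")
    if (anyDuplicated(seg$protein_id))
        msg <- c(msg, "at most one segment per protein")
    if (any(seg$end - seg$start != object@width))
        msg <- c(msg, "all segments must have length equal to width")
    if (any(nchar(seg$segment) != object@width))
        msg <- c(msg, "segment strings must match width")
    if (any(seg$start < 0L)) msg <- c(msg, "negative segment start")
    if (length(msg)) msg else TRUE
})

#' Binary functional annotation table
#'
#' Presence/absence/unknown state of each function for each protein. Proteins
#' in the annotated subset have a determined (present/absent) state for every
#' function; all other proteins are unknown for every function.
#'
#' @slot functions character, function ids.
#' @slot proteins character, protein ids (all family members).
#' @slot state character matrix (proteins x functions) with values
#'   \code{"present"}, \code{"absent"} or \code{"unknown"}.
#' @slot annotated character, the annotated protein subset.
#'
#' @exportClass FunctionTable
setClass("FunctionTable",
    representation(functions = "character", proteins = "character",
                   state = "matrix", annotated = "character"))

setValidity("FunctionTable", function(object) {
    st <- object@state
    msg <- character()
    if (!identical(rownames(st), object@proteins) ||
        !identical(colnames(st), object@functions))
        msg <- c(msg, "state dimnames must match proteins/functions")
    if (!all(st %in% c("present", "absent", "unknown")))
        msg <- c(msg, "states must be present/absent/unknown")
    ann <- object@proteins %in% object@annotated
    if (length(st) && any(st[ann, , drop = FALSE] == "unknown"))
        msg <- c(msg, "annotated proteins must have determined states")
    if (length(st) && any(st[!ann, , drop = FALSE] != "unknown"))
        msg <- c(msg, "unannotated proteins must be unknown for all functions")
    if (length(msg)) msg else TRUE
})

#' Per-node presence of one item (module or function)
#'
#' @slot itemId character(1).
#' @slot itemType character(1), \code{"module"} or \code{"function"}.
#' @slot state named logical, presence per gene-tree node.
#' @slot support named numeric in [0,1]: replicate frequency for modules,
#'   marginal posterior for functions.
#'
#' @exportClass PresenceMap
setClass("PresenceMap",
    representation(itemId = "character", itemType = "character",
                   state = "logical", support = "numeric"))

setValidity("PresenceMap", function(object) {
    msg <- character()
    if (!object@itemType %in% c("module", "function"))
        msg <- c(msg, "itemType must be 'module' or 'function'")
    if (!identical(names(object@state), names(object@support)))
        msg <- c(msg, "state and support must be keyed on the same nodes")
    if (any(object@support < 0 | object@support > 1, na.rm = TRUE))
        msg <- c(msg, "support must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Two-state continuous-time Markov model of a binary character
#'
#' Gain rate \code{alpha} (0 to 1) and loss rate \code{beta} (1 to 0) per unit
#' branch length; stationary frequency of state 1 is
#' \code{alpha / (alpha + beta)}.
#'
#' @slot alpha numeric(1), gain rate, >= 0.
#' @slot beta numeric(1), loss rate, >= 0.
#' @slot logLik numeric(1), log-likelihood at the fitted optimum (NA if the
#'   model was not fitted).
#' @slot boundary logical(1), TRUE when a fitted rate sits on the search bound.
#'
#' @exportClass TwoStateModel
setClass("TwoStateModel",
    representation(alpha = "numeric", beta = "numeric",
                   logLik = "numeric", boundary = "logical"),
    prototype(logLik = NA_real_, boundary = FALSE))

setValidity("TwoStateModel", function(object) {
    if (object@alpha < 0 || object@beta < 0) return("rates must be >= 0")
    if (object@alpha + object@beta <= 0) return("alpha + beta must be > 0")
    TRUE
})

#' Marginal ancestral reconstruction of one binary function
#'
#' @slot functionId character(1).
#' @slot posterior named numeric, marginal probability of state 1 per node.
#' @slot state named logical, \code{posterior >= 0.5} (ties resolve present).
#' @slot model the \linkS4class{TwoStateModel} used.
#'
#' @exportClass AncestralStateMap
setClass("AncestralStateMap",
    representation(functionId = "character", posterior = "numeric",
                   state = "logical", model = "TwoStateModel"))

setValidity("AncestralStateMap", function(object) {
    msg <- character()
    if (!identical(names(object@posterior), names(object@state)))
        msg <- c(msg, "posterior and state must share node names")
    if (any(object@posterior < -1e-9 | object@posterior > 1 + 1e-9))
        msg <- c(msg, "posteriors must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Module-tree to gene-tree DTL reconciliation
#'
#' Minimum-cost embedding of a module tree into the gene tree under
#' duplication, transfer and loss events (speciation free), undated model.
#'
#' @slot mapping named character, module-tree node id -> gene-tree node id.
#' @slot event named character per module node: \code{"speciation"},
#'   \code{"duplication"}, \code{"transfer"} or \code{"leaf"}.
#' @slot losses character, child ends of the gene-tree edges carrying a loss
#'   (one entry per loss; repeats allowed).
#' @slot gains character, gene nodes where the module is gained (root mapping
#'   plus every transfer landing node).
#' @slot paths list, per module-tree node the gene nodes covered by the module
#'   edge ending at that node (for the module root: its mapping only).
#' @slot totalCost numeric(1).
#'
#' @exportClass Reconciliation
setClass("Reconciliation",
    representation(mapping = "character", event = "character",
                   losses = "character", gains = "character",
                   paths = "list", totalCost = "numeric"))

setMethod("show", "GeneTree", function(object) {
    cat(sprintf("GeneTree: %d leaves, %d internal nodes, root '%s'\n",
                length(object@leaves), length(object@children), object@root))
})

setMethod("show", "SeqModule", function(object) {
    cat(sprintf("Module %s: width %d, %d segments, score %.1f\n",
                object@moduleId, object@width, nrow(object@segments),
                object@score))
})

setMethod("show", "FunctionTable", function(object) {
    cat(sprintf("FunctionTable: %d functions x %d proteins (%d annotated)\n",
                length(object@functions), length(object@proteins),
                length(object@annotated)))
})

setMethod("show", "PresenceMap", function(object) {
    cat(sprintf("PresenceMap for %s '%s': present at %d/%d nodes\n",
                object@itemType, object@itemId, sum(object@state),
                length(object@state)))
})

setMethod("show", "TwoStateModel", function(object) {
    cat(sprintf("TwoStateModel: alpha=%.4g beta=%.4g pi1=%.3f%s\n",
                object@alpha, object@beta,
                object@alpha / (object@alpha + object@beta),
                if (isTRUE(object@boundary)) " (boundary fit)" else ""))
})

setMethod("show", "AncestralStateMap", function(object) {
    cat(sprintf("AncestralStateMap for '%s': present at %d/%d nodes\n",
                object@functionId, sum(object@state), length(object@state)))
})

setMethod("show", "Reconciliation", function(object) {
    ev <- table(factor(object@event,
                       c("leaf", "speciation", "duplication", "transfer")))
    cat(sprintf(
      "Reconciliation: cost %.3f (%d dup, %d transfer, %d loss)\n",
      object@totalCost, ev[["duplication"]], ev[["transfer"]],
      length(object@losses)))
})

## ---- accessors ----

#' @rdname GeneTree-class
#' @param x,object a \code{GeneTree}
#' @export
treeNodes <- function(x) x@nodes

#' @rdname GeneTree-class
#' @export
treeLeaves <- function(x) x@leaves

#' @rdname GeneTree-class
#' @export
treeRoot <- function(x) x@root

#' @rdname GeneTree-class
#' @param node a node id
#' @export
treeParent <- function(x, node) unname(x@parent[node])

#' @rdname GeneTree-class
#' @export
treeChildren <- function(x, node) x@children[[node]]

#' @rdname GeneTree-class
#' @export
branchLengths <- function(x) x@brlen

#' @rdname GeneTree-class
#' @export
asPhylo <- function(x) x@phylo

#' @rdname SeqModule-class
#' @param x a \code{Module}
#' @export
moduleId <- function(x) x@moduleId

#' @rdname SeqModule-class
#' @export
moduleSegments <- function(x) x@segments

#' @rdname SeqModule-class
#' @export
moduleWidth <- function(x) x@width

#' @rdname SeqModule-class
#' @export
moduleScore <- function(x) x@score

#' @rdname SeqModule-class
#' @export
moduleCarriers <- function(x) x@segments$protein_id

#' @rdname FunctionTable-class
#' @param x a \code{FunctionTable}
#' @export
functionIds <- function(x) x@functions

#' @rdname FunctionTable-class
#' @export
annotatedProteins <- function(x) x@annotated

#' @rdname FunctionTable-class
#' @param protein,fn protein and function ids
#' @export
functionState <- function(x, protein, fn) x@state[protein, fn]

#' @rdname PresenceMap-class
#' @param x a \code{PresenceMap}
#' @export
presenceState <- function(x) x@state

#' @rdname PresenceMap-class
#' @export
presenceSupport <- function(x) x@support

#' @rdname PresenceMap-class
#' @export
itemId <- function(x) x@itemId

#' @rdname TwoStateModel-class
#' @param x a \code{TwoStateModel}
#' @export
gainRate <- function(x) x@alpha

#' @rdname TwoStateModel-class
#' @export
lossRate <- function(x) x@beta

#' @rdname TwoStateModel-class
#' @export
stationaryFreq <- function(x) {
    p1 <- x@alpha / (x@alpha + x@beta)
    c(`0` = 1 - p1, `1` = p1)
}

#' @rdname AncestralStateMap-class
#' @param x an \code{AncestralStateMap}
#' @export
asrPosterior <- function(x) x@posterior

#' @rdname AncestralStateMap-class
#' @export
asrState <- function(x) x@state

#' @rdname Reconciliation-class
#' @param x a \code{Reconciliation}
#' @export
reconciliationCost <- function(x) x@totalCost

#' @rdname Reconciliation-class
#' @export
reconciliationEvents <- function(x) x@event

#' @rdname Reconciliation-class
#' @export
reconciliationMapping <- function(x) x@mapping

#' Event costs for DTL reconciliation
#'
#' Duplication, transfer and loss costs (speciation is free). Transfers
#' cheaper than losses are accepted with a warning, as they tend to produce
#' degenerate scenarios.
#'
#' @param dup duplication cost, default 2.
#' @param transfer transfer cost, default 3.
#' @param loss loss cost, default 1.
#' @return a named numeric vector of class \code{ReconciliationCosts}.
#' @export
reconciliationCosts <- function(dup = 2, transfer = 3, loss = 1) {
    if (any(c(dup, transfer, loss) < 0))
        stop("reconciliation costs must be >= 0")
    if (transfer < loss)
        warning("transfer cost below loss cost; scenarios may be degenerate")
    structure(c(dup = dup, transfer = transfer, loss = loss),
              class = "ReconciliationCosts")
}
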
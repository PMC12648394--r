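## Detection of ungapped sequence-conservation modules: exact k-mer seeding,
## greedy positive-score extension, offset-consistent single-linkage
## clustering, and maximum-weight selection of mutually compatible blocks.

#' Parameters for module detection
#'
#' @param k seed k-mer length (>= 2), default 4.
#' @param minWidth minimal module width (>= k), default 6.
#' @param minPairScore significance threshold, in substitution-matrix units,
#'   required of every member segment against the cluster's highest-scoring
#'   segment. \code{NA} (default) uses \code{0.5 * width * mean diagonal} of
#'   the substitution matrix, computed per cluster; Paloma-style significance
#'   models are out of scope and this threshold stands in for them.
#' @param matrix substitution matrix name (a \pkg{Biostrings} data set),
#'   default \code{"BLOSUM62"}.
#' @return a list of class \code{DetectionParams}.
#' @export
detectionParams <- function(k = 4L, minWidth = 6L, minPairScore = NA,
                            matrix = "BLOSUM62") {
    k <- as.integer(k); minWidth <- as.integer(minWidth)
    if (k < 2L) stop("k must be >= 2")
    if (minWidth < k) stop("minWidth must be >= k")
    structure(list(k = k, minWidth = minWidth, minPairScore = minPairScore,
                   matrix = matrix),
              class = "DetectionParams")
}

## substitution matrix by name, cached per session
.matrixCache <- new.env(parent = emptyenv())
.substMatrix <- function(name) {
    if (!is.null(.matrixCache[[name]])) return(.matrixCache[[name]])
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
    .matrixCache[[name]] <- mat
    mat
}

.diagMean <- function(mat) {
    std <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
             "S","T","W","Y","V")
    mean(diag(mat[std, std]))
}

#' Ungapped score of two equal-length segments
#'
#' Sum of per-column substitution scores; symmetric in its arguments.
#'
#' @param a,b residue strings of equal length.
#' @param matrix substitution matrix name or numeric matrix.
#' @return numeric score.
#' @export
scoreSegmentPair <- function(a, b, matrix = "BLOSUM62") {
    if (nchar(a) != nchar(b)) stop("segment length mismatch")
    if (nchar(a) < 1L) stop("empty segment")
    mat <- if (is.character(matrix)) .substMatrix(matrix) else matrix
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    sum(mat[cbind(ca, cb)])
}

## per-position score vectors, vectorized over columns
.columnScores <- function(a, b, mat) {
    mat[cbind(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]])]
}

#' Find anchor segment pairs between proteins
#'
#' All pairs of length-\code{k} segments from distinct proteins with
#' identical k-mer content, each extended greedily left and right while the
#' per-column substitution score stays positive, truncated at sequence
#' bounds; duplicate extended anchors are merged.
#'
#' @param records protein records data.frame.
#' @param params \code{\link{detectionParams}}.
#' @return data.frame with columns \code{protein1,start1,protein2,start2,len}
#'   (0-based starts; segments have equal length \code{len}).
#' @export
findAnchorPairs <- function(records, params = detectionParams()) {
    if (nrow(records) < 2L) {
        return(data.frame(protein1 = character(), start1 = integer(),
                          protein2 = character(), start2 = integer(),
                          len = integer()))
    }
    mat <- .substMatrix(params$matrix)
    k <- params$k
    seqs <- setNames(records$sequence, records$protein_id)
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
    kmers <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, 1:(n - k + 1L), k:n)
    })
    ids <- records$protein_id
    out <- list()
    for (i in seq_len(length(ids) - 1L)) {
        for (j in (i + 1L):length(ids)) {
            shared <- intersect(kmers[[i]], kmers[[j]])
            if (!length(shared)) next
            for (km in shared) {
                pos1 <- which(kmers[[i]] == km)
                pos2 <- which(kmers[[j]] == km)
                for (p1 in pos1) for (p2 in pos2) {
                    a <- .extendAnchor(chars[[i]], chars[[j]], p1, p2, k, mat)
                    out[[length(out) + 1L]] <-
                        c(i = i, j = j, s1 = a[1L], s2 = a[2L], len = a[3L])
                }
            }
        }
    }
    if (!length(out)) {
        return(data.frame(protein1 = character(), start1 = integer(),
                          protein2 = character(), start2 = integer(),
                          len = integer()))
    }
    m <- unique(do.call(rbind, out))
    df <- data.frame(protein1 = ids[m[, "i"]], start1 = m[, "s1"] - 1L,
                     protein2 = ids[m[, "j"]], start2 = m[, "s2"] - 1L,
                     len = m[, "len"], stringsAsFactors = FALSE)
    df[order(df$protein1, df$protein2, df$start1, df$start2), , drop = FALSE]
}

## greedy extension of a seed at 1-based starts p1, p2; returns
## c(start1, start2, len) in 1-based coordinates
.extendAnchor <- function(c1, c2, p1, p2, k, mat) {
    l1 <- p1; l2 <- p2
    while (l1 > 1L && l2 > 1L && mat[c1[l1 - 1L], c2[l2 - 1L]] > 0) {
        l1 <- l1 - 1L; l2 <- l2 - 1L
    }
    r1 <- p1 + k - 1L; r2 <- p2 + k - 1L
    while (r1 < length(c1) && r2 < length(c2) &&
           mat[c1[r1 + 1L], c2[r2 + 1L]] > 0) {
        r1 <- r1 + 1L; r2 <- r2 + 1L
    }
    c(l1, l2, r1 - l1 + 1L)
}

#' Cluster anchors into candidate modules
#'
#' Anchor segments are single-linkage clustered: anchor partners are linked
#' (their starts aligned), as are two segments of the same protein whose
#' overlap is at least 50\% of the longer segment. Each cluster is laid out
#' in a common coordinate frame, one contiguous interval retained per protein
#' (the widest among consistent-offset merges), and trimmed to the maximal
#' window every member protein covers in full. Clusters failing the minimal
#' width, the quorum of 2 proteins, or the per-member significance threshold
#' against the cluster's highest-scoring segment are discarded.
#'
#' @param anchors from \code{\link{findAnchorPairs}}.
#' @param records protein records data.frame.
#' @param params \code{\link{detectionParams}}.
#' @return list of candidate \linkS4class{SeqModule} (ids \code{c1, c2, ...} in
#'   deterministic order; final ids are assigned by
#'   \code{\link{detectModules}}).
#' @export
clusterAnchorsToBlocks <- function(anchors, records,
                                   params = detectionParams()) {
    if (nrow(anchors) == 0L) return(list())
    mat <- .substMatrix(params$matrix)
    seqs <- setNames(records$sequence, records$protein_id)

    seg <- unique(rbind(
        data.frame(protein = anchors$protein1, start = anchors$start1,
                   len = anchors$len, stringsAsFactors = FALSE),
        data.frame(protein = anchors$protein2, start = anchors$start2,
                   len = anchors$len, stringsAsFactors = FALSE)))
    seg <- seg[order(seg$protein, seg$start, seg$len), , drop = FALSE]
    key <- paste(seg$protein, seg$start, seg$len)
    idx <- setNames(seq_len(nrow(seg)), key)

    ## linkage edges with frame offsets: frame(b) = frame(a) + off.
    ## Weight = length of the shorter linked segment, so longer (more
    ## reliable) anchors dictate the alignment frame when offsets conflict.
    edges <- list()
    addEdge <- function(a, b, off, w) {
        edges[[length(edges) + 1L]] <<- c(a = a, b = b, off = off, w = w)
    }
    for (r in seq_len(nrow(anchors))) {
        a <- idx[[paste(anchors$protein1[r], anchors$start1[r],
                        anchors$len[r])]]
        b <- idx[[paste(anchors$protein2[r], anchors$start2[r],
                        anchors$len[r])]]
        addEdge(a, b, 0L, anchors$len[r])
    }
    for (p in unique(seg$protein)) {
        rows <- which(seg$protein == p)
        if (length(rows) < 2L) next
        for (u in seq_len(length(rows) - 1L)) for (v in (u + 1L):length(rows)) {
            i <- rows[u]; j <- rows[v]
            ov <- min(seg$start[i] + seg$len[i], seg$start[j] + seg$len[j]) -
                  max(seg$start[i], seg$start[j])
            ## fraction of the longer segment, so short chance anchors
            ## cannot bridge two unrelated blocks
            if (ov >= 0.5 * max(seg$len[i], seg$len[j]))
                addEdge(i, j, seg$start[j] - seg$start[i], ov)
        }
    }

    ## offset-consistent single linkage: union-find over segments carrying
    ## each segment's offset to its component root; edges processed by
    ## descending weight (ties: insertion order), conflicting-offset edges
    ## within a component are ignored
    n <- nrow(seg)
    parent <- seq_len(n)
    shift <- integer(n)              # frame(x) = frame(root) + shift
    findRoot <- function(x) {
        off <- 0L
        while (parent[x] != x) { off <- off + shift[x]; x <- parent[x] }
        list(root = x, off = off)
    }
    if (length(edges)) {
        em <- do.call(rbind, edges)
        for (e in order(-em[, "w"], seq_len(nrow(em)))) {
            a <- em[e, "a"]; b <- em[e, "b"]; off <- em[e, "off"]
            ra <- findRoot(a); rb <- findRoot(b)
            if (ra$root == rb$root) next   # keep the heavier, earlier frame
            ## frame(b) = frame(a) + off  =>  shift for rb's root
            parent[rb$root] <- ra$root
            shift[rb$root] <- ra$off + off - rb$off
        }
    }
    comp <- integer(n); frame <- integer(n)
    roots <- integer(0)
    for (s in seq_len(n)) {
        r <- findRoot(s)
        ci <- match(r$root, roots)
        if (is.na(ci)) { roots <- c(roots, r$root); ci <- length(roots) }
        comp[s] <- ci
        frame[s] <- r$off
    }
    nComp <- length(roots)

    candidates <- list()
    for (cid in seq_len(nComp)) {
        rows <- which(comp == cid)
        sub <- cbind(seg[rows, , drop = FALSE], frame = frame[rows])
        ## per protein: merge contiguous coverage among equal-offset segments,
        ## keep the widest interval (ties: smallest frame start)
        picks <- lapply(split(sub, sub$protein), function(d) {
            d$offset <- d$start - d$frame
            best <- NULL
            for (off in sort(unique(d$offset))) {
                g <- d[d$offset == off, , drop = FALSE]
                g <- g[order(g$frame), , drop = FALSE]
                curS <- g$frame[1L]; curE <- g$frame[1L] + g$len[1L]
                ivs <- list()
                for (q in seq_len(nrow(g))[-1L]) {
                    if (g$frame[q] <= curE) {
                        curE <- max(curE, g$frame[q] + g$len[q])
                    } else {
                        ivs[[length(ivs) + 1L]] <- c(curS, curE)
                        curS <- g$frame[q]; curE <- g$frame[q] + g$len[q]
                    }
                }
                ivs[[length(ivs) + 1L]] <- c(curS, curE)
                for (iv in ivs) {
                    cand <- list(protein = d$protein[1L], offset = off,
                                 fs = iv[1L], fe = iv[2L])
                    if (is.null(best) || (cand$fe - cand$fs) >
                        (best$fe - best$fs) ||
                        ((cand$fe - cand$fs) == (best$fe - best$fs) &&
                         cand$fs < best$fs))
                        best <- cand
                }
            }
            best
        })
        if (length(picks) < 2L) next
        ws <- max(vapply(picks, function(p) p$fs, 0))
        we <- min(vapply(picks, function(p) p$fe, 0))
        width <- we - ws
        if (width < params$minWidth) next
        segdf <- do.call(rbind, lapply(picks, function(p) {
            s <- ws + p$offset
            data.frame(protein_id = p$protein, start = as.integer(s),
                       end = as.integer(s + width),
                       segment = substr(seqs[[p$protein]], s + 1L, s + width),
                       stringsAsFactors = FALSE)
        }))
        rownames(segdf) <- NULL
        segdf <- segdf[order(segdf$protein_id), , drop = FALSE]

        ## significance: every member against the highest-scoring segment
        strs <- segdf$segment
        np <- length(strs)
        pw <- matrix(0, np, np)
        for (u in seq_len(np - 1L)) for (v in (u + 1L):np) {
            sc <- scoreSegmentPair(strs[u], strs[v], mat)
            pw[u, v] <- pw[v, u] <- sc
        }
        rep_ <- which.max(rowSums(pw))
        thr <- if (is.na(params$minPairScore))
            0.5 * width * .diagMean(mat) else params$minPairScore
        if (any(pw[rep_, -rep_] < thr)) next
        candidates[[length(candidates) + 1L]] <-
            methods::new("SeqModule",
                         moduleId = paste0("c", length(candidates) + 1L),
                         segments = segdf, width = as.integer(width),
                         score = sum(pw) / 2)
    }
    candidates
}

## pairwise compatibility: no per-protein overlap, no order crossing on
## proteins shared by both modules
.modulesCompatible <- function(m1, m2) {
    s1 <- moduleSegments(m1); s2 <- moduleSegments(m2)
    shared <- intersect(s1$protein_id, s2$protein_id)
    if (!length(shared)) return(TRUE)
    rel <- integer(0)
    for (p in shared) {
        a <- s1[s1$protein_id == p, ]
        b <- s2[s2$protein_id == p, ]
        if (a$start < b$end && b$start < a$end) return(FALSE)  # overlap
        rel <- c(rel, if (a$start < b$start) -1L else 1L)
    }
    length(unique(rel)) == 1L
}

#' Select a maximum-weight set of mutually compatible modules
#'
#' Two modules are compatible when their segments never overlap on a protein
#' and their left-to-right order is identical on every protein they share.
#' For up to \code{maxExact} candidates the exact maximum-score compatible
#' subset is found by exhaustive search (deterministic tie-break preferring
#' higher-scoring, then lexicographically earlier candidates); larger inputs
#' fall back to a greedy sweep by descending score with the same tie-break.
#'
#' @param candidates list of \linkS4class{SeqModule}.
#' @param maxExact exhaustive-search size limit, default 12.
#' @return the selected sub-list, in the deterministic candidate order.
#' @export
selectCompatibleBlocks <- function(candidates, maxExact = 12L) {
    n <- length(candidates)
    if (n <= 1L) return(candidates)
    ## deterministic priority order: score desc, then smallest carrier id,
    ## then its start
    keyProt <- vapply(candidates, function(m)
        min(moduleSegments(m)$protein_id), "")
    keyStart <- vapply(candidates, function(m) {
        s <- moduleSegments(m); s$start[order(s$protein_id)[1L]]
    }, 0L)
    scores <- vapply(candidates, moduleScore, 0)
    ord <- order(-scores, keyProt, keyStart)
    cand <- candidates[ord]
    sc <- scores[ord]
    compat <- matrix(TRUE, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        compat[i, j] <- compat[j, i] <- .modulesCompatible(cand[[i]], cand[[j]])

    if (n <= maxExact) {
        best <- integer(0); bestW <- -Inf
        for (mask in 0:(2^n - 1L)) {
            sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
            if (length(sel) > 1L) {
                ok <- TRUE
                for (u in seq_len(length(sel) - 1L)) {
                    if (!all(compat[sel[u], sel[(u + 1L):length(sel)]])) {
                        ok <- FALSE; break
                    }
                }
                if (!ok) next
            }
            w <- sum(sc[sel])
            if (w > bestW + 1e-9) { bestW <- w; best <- sel }
            ## ties: prefer the subset containing the earliest-priority
            ## candidates
            else if (abs(w - bestW) <= 1e-9 &&
                     .lexBefore(sel, best)) best <- sel
        }
        keep <- best
    } else {
        keep <- integer(0)
        for (i in seq_len(n)) {
            if (all(compat[i, keep])) keep <- c(keep, i)
        }
    }
    cand[sort(keep)]
}

## TRUE when index set a precedes b lexicographically (shorter-prefix wins)
.lexBefore <- function(a, b) {
    a <- sort(a); b <- sort(b)
    k <- min(length(a), length(b))
    if (k > 0L) for (i in seq_len(k)) {
        if (a[i] < b[i]) return(TRUE)
        if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
}

#' Detect sequence-conservation modules
#'
#' Full detection pass: k-mer anchor pairs, anchor clustering into candidate
#' blocks, and maximum-weight compatible selection. Module ids
#' \code{m1..mN} are assigned by sorting on each module's lexicographically
#' smallest carrier protein and the segment start on that carrier. The result
#' is deterministic in the inputs and parameters.
#'
#' @param records protein records data.frame (>= 2 rows).
#' @param params \code{\link{detectionParams}}.
#' @return list of \linkS4class{SeqModule}.
#' @export
detectModules <- function(records, params = detectionParams()) {
    if (nrow(records) < 2L) stop("module detection needs >= 2 sequences")
    anchors <- findAnchorPairs(records, params)
    cands <- clusterAnchorsToBlocks(anchors, records, params)
    sel <- selectCompatibleBlocks(cands)
    if (!length(sel)) return(list())
    keyProt <- vapply(sel, function(m) min(moduleSegments(m)$protein_id), "")
    keyStart <- vapply(sel, function(m) {
        s <- moduleSegments(m); s$start[order(s$protein_id)[1L]]
    }, 0L)
    sel <- sel[order(keyProt, keyStart)]
    for (i in seq_along(sel)) sel[[i]]@moduleId <- paste0("m", i)
    sel
}
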
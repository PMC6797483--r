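# Independent oracles used across the suite. These deliberately avoid the
# package's own depth/mrca machinery: paths are counted by breadth-first
# search on the explicit node graph, and bipartitions are found by cutting
# each edge of the unrooted graph.

# Path-length matrix by BFS on the adjacency graph: entry (i,j) = number of
# internal nodes strictly between leaves i and j.
bfsPathLengths <- function(phy) {
    ntip <- length(phy$tip.label)
    nn <- ntip + phy$Nnode
    adj <- vector("list", nn)
    for (k in seq_len(nrow(phy$edge))) {
        a <- phy$edge[k, 1L]; b <- phy$edge[k, 2L]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    out <- matrix(0L, ntip, ntip,
                  dimnames = list(phy$tip.label, phy$tip.label))
    for (i in seq_len(ntip)) {
        # BFS recording parents
        parent <- rep(NA_integer_, nn)
        seen <- logical(nn); seen[i] <- TRUE
        queue <- i
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            for (w in adj[[v]]) if (!seen[w]) {
                seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
            }
        }
        for (j in seq_len(ntip)) {
            if (j == i) next
            # walk back from j to i, counting internal nodes
            v <- parent[j]; cnt <- 0L
            while (v != i) { cnt <- cnt + 1L; v <- parent[v] }
            out[i, j] <- cnt
        }
    }
    out
}

# Non-trivial bipartitions of the unrooted tree by cutting each edge of the
# explicit graph and reading leaf components.
cutSplits <- function(phy) {
    ntip <- length(phy$tip.label)
    nn <- ntip + phy$Nnode
    edges <- phy$edge
    ref <- sort(phy$tip.label, method = "radix")[1L]
    out <- character(0L)
    for (k in seq_len(nrow(edges))) {
        adj <- vector("list", nn)
        for (m in seq_len(nrow(edges))) {
            if (m == k) next
            a <- edges[m, 1L]; b <- edges[m, 2L]
            adj[[a]] <- c(adj[[a]], b)
            adj[[b]] <- c(adj[[b]], a)
        }
        start <- edges[k, 2L]
        seen <- logical(nn); seen[start] <- TRUE
        queue <- start
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
        }
        side <- phy$tip.label[which(seen[seq_len(ntip)])]
        other <- setdiff(phy$tip.label, side)
        if (length(side) < 2L || length(other) < 2L) next
        if (ref %in% side) side <- other
        out <- c(out, paste(sort(side, method = "radix"), collapse = "|"))
    }
    unique(out)
}

# Random rooted binary topology over given labels, generated independently of
# the package (ape::rtree), canonicalized for comparisons.
randomTopo <- function(labels) {
    phy <- ape::rtree(length(labels), rooted = TRUE, br = NULL)
    phy$tip.label <- sample(labels)
    readNewick(paste0(ape::write.tree(phy)))
}

# Cached exhaustive enumeration: for n leaves (labels A, B, ...) returns
# list(trees, newick, pl) where pl is a topologies x pairs matrix of
# BFS-counted path lengths, pairs in combn order over sorted labels.
.enumCache <- new.env(parent = emptyenv())
enumWithPaths <- function(n) {
    key <- as.character(n)
    if (!is.null(.enumCache[[key]])) return(.enumCache[[key]])
    labels <- LETTERS[seq_len(n)]
    trees <- enumerateTopologies(labels)
    newick <- vapply(trees, canonicalNewick, character(1L))
    pairs <- t(combn(n, 2L))
    pl <- t(vapply(trees, function(tr) {
        m <- bfsPathLengths(tr)[labels, labels]
        m[pairs]
    }, integer(nrow(pairs))))
    res <- list(trees = trees, newick = newick, pl = pl, labels = labels,
                pairs = pairs)
    .enumCache[[key]] <- res
    res
}

# Oracle: score every rooted topology over the distribution's universe by
# direct lookup of log frequencies on BFS path lengths; returns scores and a
# constructible flag (all pair lengths observed).
oracleScores <- function(d) {
    n <- length(d@universe)
    en <- enumWithPaths(n)
    stopifnot(identical(en$labels, d@universe))
    lf <- log(d@counts / d@valid)
    lf[d@counts == 0L] <- -Inf
    Lmax <- ncol(lf)
    P <- nrow(en$pairs)
    scores <- numeric(nrow(en$pl))
    supported <- logical(nrow(en$pl))
    for (t in seq_len(nrow(en$pl))) {
        s <- 0; ok <- TRUE
        for (p in seq_len(P)) {
            L <- en$pl[t, p]
            v <- if (L > Lmax) -Inf else lf[p, L]
            if (is.infinite(v)) { ok <- FALSE; break }
            s <- s + v
        }
        scores[t] <- s; supported[t] <- ok
    }
    list(newick = en$newick, scores = scores, supported = supported)
}

# Top-n constructible topologies per the oracle, ordered like the search
# (score descending, canonical Newick ascending).
oracleTopN <- function(d, n) {
    os <- oracleScores(d)
    idx <- which(os$supported)
    ord <- idx[order(-round(os$scores[idx], 9L), os$newick[idx],
                     method = "radix")]
    ord <- head(ord, n)
    list(newick = os$newick[ord], scores = os$scores[ord])
}

# Compare a ReconstructionResult with an oracle top-n list: scores must agree
# to 1e-12 rank by rank, and the topologies must agree once ties (equal
# scores up to float summation noise) are put in canonical order.
expectMatchesOracle <- function(rr, oo) {
    expect_equal(length(rr@scores), length(oo$scores))
    expect_lt(max(abs(rr@scores - oo$scores)), 1e-12)
    os <- order(-round(oo$scores, 9L), oo$newick, method = "radix")
    rs <- order(-round(rr@scores, 9L), rr@newick, method = "radix")
    expect_identical(rr@newick[rs], oo$newick[os])
}

# Exhaustively enumerate the scores of all complete topologies reachable from
# an assembly (pure branching, no bound) -- used for admissibility checks.
reachableCompletionScores <- function(a, d) {
    out <- numeric(0L)
    recurse <- function(x) {
        if (length(x@subtrees) == 1L) { out <<- c(out, x@score); return() }
        for (y in branchExtensions(x, d)) recurse(y)
    }
    recurse(a)
    out
}
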
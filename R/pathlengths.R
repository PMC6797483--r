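#' Leaf-to-leaf path-length matrix of a rooted topology
#'
#' Entry (i, j) is the number of internal nodes on the unique path between
#' leaves i and j, counting every internal node on the path -- the root
#' included whenever the path traverses it. Note that many tree libraries
#' count *edges*; here a cherry has path length 1, and the maximum possible
#' entry on n leaves is 2n-3. This matrix representation is equivalent to the
#' topology itself (see [topologyFromMatrix()]), and is what ensemble
#' aggregation operates on.
#'
#' @param t a rooted binary \code{phylo} or [PrunedTopology-class].
#' @return symmetric integer matrix with leaf labels as dimnames; the
#'   diagonal is 0 and unused.
#' @examples
#' m <- pathLengthMatrix(readNewick("(((A,B),((C,D),E)),F);"))
#' m["A", "B"] # 1
#' m["E", "F"] # 3 (the root is on this path)
#' @export
pathLengthMatrix <- function(t) {
    if (is(t, "PrunedTopology")) t <- t@tree
    .checkBinaryRooted(t)
    ntip <- length(t$tip.label)
    if (ntip < 2L) stop("need at least 2 leaves", call. = FALSE)
    info <- .nodeDepths(t)
    depth <- info$depth
    mr <- ape::mrca(t)
    pl <- matrix(0L, ntip, ntip, dimnames = list(t$tip.label, t$tip.label))
    for (i in seq_len(ntip - 1L)) {
        for (j in (i + 1L):ntip) {
            v <- depth[i] + depth[j] - 2L * depth[mr[i, j]] - 1L
            pl[i, j] <- v
            pl[j, i] <- v
        }
    }
    pl
}

#' Reconstruct the unique topology realizing a path-length matrix
#'
#' Bottom-up construction guided by the entries sorted by increasing path
#' length: each entry whose two leaves lie in different partial subtrees
#' triggers the join of those subtrees under a new internal node when the
#' join reproduces the entry's length; every leaf pair spanning the join is
#' checked against the matrix, and the first entry that can never be
#' satisfied raises an error. Because a matrix derived from a real topology
#' is internally consistent, the construction is unambiguous and inverts
#' [pathLengthMatrix()] exactly.
#'
#' @param m symmetric integer matrix with leaf labels as dimnames (as
#'   produced by [pathLengthMatrix()]).
#' @return a rooted binary \code{phylo} in canonical form.
#' @export
topologyFromMatrix <- function(m) {
    labs <- rownames(m)
    if (is.null(labs) || !identical(labs, colnames(m)))
        stop("matrix needs identical row/column leaf labels", call. = FALSE)
    n <- length(labs)
    if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
    if (!isTRUE(all.equal(m, t(m)))) stop("matrix must be symmetric", call. = FALSE)
    if (n == 2L) return(readNewick(paste0("(", labs[1L], ",", labs[2L], ");")))

    pairs <- t(combn(n, 2L))
    L <- m[pairs]
    if (any(L < 1L)) stop("path lengths must be >= 1", call. = FALSE)
    ord <- order(L, labs[pairs[, 1L]], labs[pairs[, 2L]], method = "radix")
    pairs <- pairs[ord, , drop = FALSE]
    L <- L[ord]
    entryName <- function(e) sprintf("(%s,%s,%d)", labs[pairs[e, 1L]],
                                     labs[pairs[e, 2L]], L[e])

    comp <- seq_len(n)               # component id per leaf
    h <- integer(n)                  # internal nodes from leaf to component root
    nodes <- lapply(labs, function(x) list(label = x, len = NA_real_))
    names(nodes) <- NULL             # one nested tree per component id
    satisfied <- logical(nrow(pairs))

    repeat {
        if (all(satisfied)) break
        progress <- FALSE
        for (e in which(!satisfied)) {
            i <- pairs[e, 1L]; j <- pairs[e, 2L]
            ci <- comp[i]; cj <- comp[j]
            if (ci == cj) { # must have been completed by an earlier join
                stop("unrealizable path-length matrix at entry ", entryName(e),
                     call. = FALSE)
            }
            implied <- h[i] + h[j] + 1L
            if (implied > L[e])
                stop("unrealizable path-length matrix at entry ", entryName(e),
                     call. = FALSE)
            if (implied < L[e]) next # components must grow first
            memA <- which(comp == ci); memB <- which(comp == cj)
            cross <- outer(h[memA], h[memB], function(a, b) a + b + 1L)
            want <- m[memA, memB, drop = FALSE]
            if (!all(cross == want)) {
                bad <- which(cross != want, arr.ind = TRUE)[1L, ]
                u <- memA[bad[1L]]; v <- memB[bad[2L]]
                stop(sprintf("unrealizable path-length matrix at entry (%s,%s,%d)",
                             labs[min(u, v)], labs[max(u, v)], m[u, v]),
                     call. = FALSE)
            }
            nodes[[ci]] <- list(children = list(nodes[[ci]], nodes[[cj]]),
                                len = NA_real_)
            nodes[cj] <- list(NULL)
            comp[memB] <- ci
            h[c(memA, memB)] <- h[c(memA, memB)] + 1L
            # mark all cross pairs satisfied
            for (e2 in which(!satisfied)) {
                a <- pairs[e2, 1L]; b <- pairs[e2, 2L]
                if ((a %in% memA && b %in% memB) || (a %in% memB && b %in% memA))
                    satisfied[e2] <- TRUE
            }
            progress <- TRUE
            break # component ids changed; restart the traversal
        }
        if (!progress)
            stop("unrealizable path-length matrix at entry ",
                 entryName(which(!satisfied)[1L]), call. = FALSE)
    }
    if (length(unique(comp)) != 1L)
        stop("unrealizable path-length matrix: disconnected construction",
             call. = FALSE)
    out <- .nestedToPhylo(.canonicalizeNested(nodes[[comp[1L]]]))
    check <- pathLengthMatrix(out)[labs, labs]
    if (!all(check == m)) # defensive: greedy order failed to realize m
        stop("unrealizable path-length matrix", call. = FALSE)
    out
}

#' Aggregate an ensemble into path-length frequency distributions
#'
#' Every member is converted to its path-length matrix and each pair's
#' observed length is counted, except for compromised observations: pairs
#' with either ancestor leaf missing from the member, and pairs whose path
#' passes through a spurious node (non-monophyletic reconstruction).
#' Uncompromised paths of such members still contribute. Frequencies
#' normalize per pair over that pair's valid observations, keeping pairs with
#' different numbers of compromised observations comparable.
#'
#' @param ensemble non-empty list of [PrunedTopology-class] over one universe.
#' @return a [PathLengthDistribution-class].
#' @export
aggregateEnsemble <- function(ensemble) {
    if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
    universe <- sort(ensemble[[1L]]@universe, method = "radix")
    for (t in ensemble)
        if (!identical(sort(t@universe, method = "radix"), universe))
            stop("ensemble members must share one orthoset universe", call. = FALSE)
    N <- length(universe)
    pairs <- t(combn(N, 2L))
    P <- nrow(pairs)
    Lmax <- 2L * N - 3L
    counts <- matrix(0L, P, Lmax,
                     dimnames = list(paste(universe[pairs[, 1L]],
                                           universe[pairs[, 2L]], sep = "|"),
                                     seq_len(Lmax)))
    pairIndex <- matrix(0L, N, N)
    pairIndex[pairs] <- seq_len(P)
    pairIndex[pairs[, c(2L, 1L)]] <- seq_len(P)

    for (t in ensemble) {
        phy <- t@tree
        tipIdx <- match(phy$tip.label, universe)
        pl <- pathLengthMatrix(phy)
        k <- length(phy$tip.label)
        compromised <- matrix(FALSE, k, k)
        if (length(t@spurious)) {
            chains <- .ancestorChains(phy)
            spur <- t@spurious
            for (a in seq_len(k - 1L)) {
                for (b in (a + 1L):k) {
                    ca <- chains[[a]]; cb <- chains[[b]]
                    mrca <- intersect(ca, cb)[1L]
                    onpath <- c(setdiff(ca, cb), setdiff(cb, ca), mrca)
                    compromised[a, b] <- any(onpath %in% spur)
                }
            }
        }
        for (a in seq_len(k - 1L)) {
            for (b in (a + 1L):k) {
                if (compromised[a, b]) next
                p <- pairIndex[tipIdx[a], tipIdx[b]]
                counts[p, pl[a, b]] <- counts[p, pl[a, b]] + 1L
            }
        }
    }
    new("PathLengthDistribution", universe = universe, pairs = pairs,
        counts = counts, valid = rowSums(counts),
        ensembleSize = length(ensemble))
}

#' Sorted entry list of a path-length distribution
#'
#' One record per (pair, length) with a positive observation count, carrying
#' the per-pair frequency. Sorted by increasing length, ties broken by
#' decreasing frequency and then lexicographic pair, so that bottom-up
#' construction meets short paths first. Completeness of the N-best search
#' does not depend on this order.
#'
#' @param d a [PathLengthDistribution-class].
#' @return data.frame with columns \code{leaf1}, \code{leaf2}, \code{length},
#'   \code{count}, \code{frequency}.
#' @export
sortedEntries <- function(d) {
    idx <- which(d@counts > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty distribution", call. = FALSE)
    p <- idx[, 1L]
    df <- data.frame(leaf1 = d@universe[d@pairs[p, 1L]],
                     leaf2 = d@universe[d@pairs[p, 2L]],
                     length = as.integer(idx[, 2L]),
                     count = d@counts[idx],
                     frequency = d@counts[idx] / d@valid[p])
    df <- df[order(df$length, -df$frequency, df$leaf1, df$leaf2,
                   method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Restrict a distribution to a subset of ancestors
#'
#' Keeps only the pairs among \code{keep}; per-pair counts and valid totals
#' are unchanged (frequencies already normalize per pair). Used when an
#' ancestor is so rarely recovered that some of its pairs have no valid
#' observations at all -- such an ancestor is not high-confidence and cannot
#' be placed by the search.
#'
#' @param d a [PathLengthDistribution-class].
#' @param keep character vector of ancestors to retain (>= 2).
#' @return a [PathLengthDistribution-class] over \code{keep}.
#' @export
subsetDistribution <- function(d, keep) {
    keep <- sort(intersect(d@universe, keep), method = "radix")
    if (length(keep) < 2L) stop("need at least 2 ancestors", call. = FALSE)
    idx <- match(keep, d@universe)
    sel <- which(d@pairs[, 1L] %in% idx & d@pairs[, 2L] %in% idx)
    pairs <- cbind(match(d@universe[d@pairs[sel, 1L]], keep),
                   match(d@universe[d@pairs[sel, 2L]], keep))
    new("PathLengthDistribution", universe = keep, pairs = pairs,
        counts = d@counts[sel, , drop = FALSE],
        valid = d@valid[sel], ensembleSize = d@ensembleSize)
}

#' Write / read a path-length matrix as TSV
#'
#' @param m matrix from [pathLengthMatrix()].
#' @param file path.
#' @export
writePathMatrix <- function(m, file) {
    write.table(m, file, sep = "\t", quote = FALSE, col.names = NA)
    invisible(file)
}

#' @rdname writePathMatrix
#' @export
readPathMatrix <- function(file) {
    m <- as.matrix(read.table(file, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE))
    storage.mode(m) <- "integer"
    m
}

#' JSON serialization of a path-length distribution
#'
#' @param d a [PathLengthDistribution-class].
#' @param file optional output path.
#' @return JSON string (pair -> length -> count, plus valid totals and
#'   ensemble size).
#' @export
distributionJSON <- function(d, file = NULL) {
    perPair <- lapply(seq_len(nrow(d@counts)), function(p) {
        nz <- which(d@counts[p, ] > 0L)
        list(counts = setNames(as.list(d@counts[p, nz]), nz),
             valid = d@valid[p])
    })
    names(perPair) <- rownames(d@counts)
    js <- jsonlite::toJSON(list(universe = d@universe,
                                ensemble_size = d@ensembleSize,
                                pairs = perPair),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
    js
}
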
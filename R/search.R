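# --- internal assembly representation ------------------------------------
# A subtree record: list(leaves = integer indices into the universe,
#                        h      = integer, internal nodes from each leaf up to
#                                 and including the subtree root (0 for a
#                                 singleton),
#                        str    = canonical Newick fragment,
#                        minLeaf = smallest leaf index)

.singletonForest <- function(universe) {
    lapply(seq_along(universe), function(i)
        list(leaves = i, h = 0L, str = universe[i], minLeaf = i))
}

.forestKey <- function(subtrees) {
    paste(sort(vapply(subtrees, `[[`, character(1L), "str"), method = "radix"),
          collapse = ";")
}

# Attempt to join subtrees si and sj of a forest under a new root. Permitted
# only if every leaf pair spanning the join gets a path length with a nonzero
# observed frequency. Returns NULL when not permitted, else the updated
# (forest, completed, score).
.tryJoin <- function(subtrees, si, sj, completed, score, logf, pm) {
    A <- subtrees[[si]]; B <- subtrees[[sj]]
    Lmax <- ncol(logf)
    inc <- 0
    nA <- length(A$leaves); nB <- length(B$leaves)
    newLens <- integer(nA * nB); newPairs <- integer(nA * nB)
    k <- 0L
    for (ai in seq_len(nA)) {
        for (bi in seq_len(nB)) {
            L <- A$h[ai] + B$h[bi] + 1L
            if (L > Lmax) return(NULL)
            p <- pm[A$leaves[ai], B$leaves[bi]]
            lf <- logf[p, L]
            if (is.infinite(lf)) return(NULL)
            k <- k + 1L
            newLens[k] <- L; newPairs[k] <- p
            inc <- inc + lf
        }
    }
    joined <- if (A$minLeaf < B$minLeaf) {
        list(leaves = c(A$leaves, B$leaves), h = c(A$h, B$h) + 1L,
             str = paste0("(", A$str, ",", B$str, ")"), minLeaf = A$minLeaf)
    } else {
        list(leaves = c(B$leaves, A$leaves), h = c(B$h, A$h) + 1L,
             str = paste0("(", B$str, ",", A$str, ")"), minLeaf = B$minLeaf)
    }
    completed[newPairs] <- newLens
    forest <- c(subtrees[-c(si, sj)], list(joined))
    list(subtrees = forest, completed = completed, score = score + inc)
}

#' Empty assembly over a distribution's ancestor universe
#'
#' The starting state of the branch-and-bound search: every ancestor is a
#' singleton subtree, no pair completed, running score 0.
#'
#' @param d a [PathLengthDistribution-class].
#' @return an [Assembly-class].
#' @export
newAssembly <- function(d) {
    P <- nrow(d@pairs)
    new("Assembly", universe = d@universe,
        subtrees = .singletonForest(d@universe),
        completedLengths = rep(NA_integer_, P), score = 0)
}

#' Entry statuses of an assembly
#'
#' Classifies every (pair, length) record of [sortedEntries()] relative to an
#' assembly: \code{completed} when the pair is connected at that length,
#' \code{incompatible} when the pair is connected at a different length or the
#' length can no longer be realized (both leaves already sit too deep in
#' their subtrees), \code{open} otherwise.
#'
#' @param a an [Assembly-class].
#' @param d the matching [PathLengthDistribution-class].
#' @return [sortedEntries()] data.frame with an extra \code{status} column.
#' @export
entryStatuses <- function(a, d) {
    ent <- sortedEntries(d)
    pm <- .pairIndexMatrix(d)
    leafComp <- integer(length(d@universe))
    leafH <- integer(length(d@universe))
    for (s in seq_along(a@subtrees)) {
        st <- a@subtrees[[s]]
        leafComp[st$leaves] <- s
        leafH[st$leaves] <- st$h
    }
    i1 <- match(ent$leaf1, d@universe); i2 <- match(ent$leaf2, d@universe)
    p <- pm[cbind(i1, i2)]
    done <- a@completedLengths[p]
    minL <- leafH[i1] + leafH[i2] + 1L
    ent$status <- ifelse(!is.na(done) & done == ent$length, "completed",
                  ifelse(!is.na(done) | ent$length < minL, "incompatible",
                         "open"))
    ent
}

#' All single-join extensions of an assembly
#'
#' The branching step: for every pair of subtrees in the forest, a join under
#' a new internal node is permitted only when every leaf pair completed by
#' the proposed node has a path length that was observed in the ensemble
#' (nonzero frequency); each permitted join yields one extended assembly with
#' the completed cross-pairs scored.
#'
#' @param a an [Assembly-class].
#' @param d the matching [PathLengthDistribution-class].
#' @return list of [Assembly-class] (empty when the assembly is a dead end or
#'   already complete).
#' @export
setMethod("branchExtensions", signature("Assembly", "PathLengthDistribution"),
          function(a, d) {
    lt <- .logFreqTable(d)
    pm <- .pairIndexMatrix(d)
    out <- list()
    ns <- length(a@subtrees)
    if (ns < 2L) return(out)
    for (si in seq_len(ns - 1L)) {
        for (sj in (si + 1L):ns) {
            j <- .tryJoin(a@subtrees, si, sj, a@completedLengths, a@score,
                          lt$logf, pm)
            if (is.null(j)) next
            out <- c(out, list(new("Assembly", universe = a@universe,
                                   subtrees = j$subtrees,
                                   completedLengths = j$completed,
                                   score = j$score)))
        }
    }
    out
})

#' Branch-and-bound enumeration of the N best-scoring topologies
#'
#' Enumerates the \code{n} rooted topologies over the distribution's ancestor
#' universe that score highest under the log-frequency objective
#' ([logFrequencyScore()]), among all topologies constructible from observed
#' path lengths. Assemblies are expanded best-first by their admissible
#' projected score ([projectedScore()]); duplicate construction states
#' (identical forests reached by different join orders) are pruned via
#' canonical keys; once \code{n} topologies exist, assemblies whose projected
#' score falls strictly below the current n-th best score are abandoned, so
#' co-optimal topologies at the bound are always retained. On exhaustion the
#' result is exactly the n best constructible topologies; with a budget the
#' run may stop early, returning a correctly-ordered subset flagged
#' incomplete.
#'
#' @param d a [PathLengthDistribution-class] covering every ancestor pair.
#' @param n how many topologies to reconstruct (>= 1).
#' @param budget optional cap on the number of assemblies created;
#'   \code{Inf} (default) guarantees completeness.
#' @return a [ReconstructionResult-class].
#' @examples
#' ens <- c(rep(list(asPrunedTopology("((A,B),C);")), 8),
#'          rep(list(asPrunedTopology("(A,(B,C));")), 2))
#' d <- aggregateEnsemble(ens)
#' reconstructNBest(d, 3)
#' @export
reconstructNBest <- function(d, n, budget = Inf) {
    if (n < 1L) stop("n must be >= 1", call. = FALSE)
    if (any(d@valid == 0))
        stop("distribution has pairs with no valid observations: ",
             paste(head(rownames(d@counts)[d@valid == 0], 5L), collapse = ", "),
             call. = FALSE)
    lt <- .logFreqTable(d)
    logf <- lt$logf
    pm <- .pairIndexMatrix(d)
    universe <- d@universe
    eps <- 1e-9 # tie tolerance: scores equal up to float summation noise

    states <- list(list(subtrees = .singletonForest(universe),
                        completed = rep(NA_integer_, nrow(d@pairs)),
                        score = 0))
    proj <- .projectedScoreInternal(states[[1L]]$subtrees, NULL, 0, logf, pm)
    keys <- .forestKey(states[[1L]]$subtrees)
    alive <- TRUE
    visited <- new.env(hash = TRUE, parent = emptyenv())
    assign(keys[1L], TRUE, envir = visited)

    created <- 1L; abandoned <- 0L; deduplicated <- 0L
    doneStr <- character(0L); doneScore <- numeric(0L)
    bound <- -Inf
    truncated <- FALSE

    popBest <- function() {
        idx <- which(alive)
        if (!length(idx)) return(0L)
        p <- proj[idx]
        best <- idx[p == max(p)]
        if (length(best) > 1L) best <- best[order(keys[best], method = "radix")[1L]]
        best
    }

    repeat {
        i <- popBest()
        if (i == 0L) break
        alive[i] <- FALSE
        st <- states[[i]]
        if (length(doneScore) >= n && proj[i] < bound - eps) {
            # best-first: nothing left can beat the bound
            abandoned <- abandoned + sum(alive)
            break
        }
        if (length(st$subtrees) == 1L) {
            doneStr <- c(doneStr, paste0(st$subtrees[[1L]]$str, ";"))
            doneScore <- c(doneScore, st$score)
            if (length(doneScore) >= n)
                bound <- sort(doneScore, decreasing = TRUE)[n]
            next
        }
        ns <- length(st$subtrees)
        stop_outer <- FALSE
        for (si in seq_len(ns - 1L)) {
            for (sj in (si + 1L):ns) {
                j <- .tryJoin(st$subtrees, si, sj, st$completed, st$score,
                              logf, pm)
                if (is.null(j)) next
                key <- .forestKey(j$subtrees)
                if (exists(key, envir = visited, inherits = FALSE)) {
                    deduplicated <- deduplicated + 1L
                    next
                }
                assign(key, TRUE, envir = visited)
                created <- created + 1L
                if (created > budget) { truncated <- TRUE; stop_outer <- TRUE; break }
                pj <- .projectedScoreInternal(j$subtrees, NULL, j$score, logf, pm)
                if (is.infinite(pj) && pj < 0) { abandoned <- abandoned + 1L; next }
                if (length(doneScore) >= n && pj < bound - eps) {
                    abandoned <- abandoned + 1L
                    next
                }
                states[[length(states) + 1L]] <- j
                proj[length(proj) + 1L] <- pj
                keys[length(keys) + 1L] <- key
                alive[length(alive) + 1L] <- TRUE
            }
            if (stop_outer) break
        }
        if (stop_outer) break
    }

    ord <- order(-round(doneScore, 9L), doneStr, method = "radix")
    ord <- head(ord, n)
    newick <- doneStr[ord]
    scores <- doneScore[ord]
    new("ReconstructionResult",
        topologies = lapply(newick, readNewick),
        newick = newick, scores = scores,
        complete = !truncated,
        stats = c(created = created, abandoned = abandoned,
                  deduplicated = deduplicated,
                  completed = length(doneScore)))
}

#' Clade frequencies across a set of topologies
#'
#' For every clade (leaf set under an internal node, the root included)
#' occurring in any input topology, the fraction of topologies containing it
#' -- the annotation used to summarize ancestral nodes across the most likely
#' reconstructions.
#'
#' @param topologies non-empty list of \code{phylo} (or
#'   [PrunedTopology-class]) over one leaf universe, or a
#'   [ReconstructionResult-class].
#' @return data.frame with columns \code{clade} (comma-joined sorted leaf
#'   labels), \code{count} and \code{frequency}, most frequent first.
#' @export
cladeFrequencies <- function(topologies) {
    if (is(topologies, "ReconstructionResult"))
        topologies <- topologies@topologies
    if (length(topologies) == 0L) stop("empty topology list", call. = FALSE)
    topologies <- lapply(topologies, function(t)
        if (is(t, "PrunedTopology")) t@tree else t)
    leafU <- sort(topologies[[1L]]$tip.label, method = "radix")
    tab <- new.env(hash = TRUE, parent = emptyenv())
    for (t in topologies) {
        if (!identical(sort(t$tip.label, method = "radix"), leafU))
            stop("mixed leaf universes", call. = FALSE)
        ntip <- length(t$tip.label)
        sets <- .cladeSets(t)
        clades <- unique(vapply((ntip + 1L):(ntip + t$Nnode),
                                function(v) paste(sets[[v]], collapse = ","),
                                character(1L)))
        for (cl in clades) {
            cur <- if (exists(cl, envir = tab, inherits = FALSE))
                get(cl, envir = tab) else 0L
            assign(cl, cur + 1L, envir = tab)
        }
    }
    cl <- ls(tab, sorted = TRUE)
    cnt <- vapply(cl, get, integer(1L), envir = tab)
    df <- data.frame(clade = cl, count = unname(cnt),
                     frequency = unname(cnt) / length(topologies))
    df <- df[order(-df$frequency, df$clade, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Annotate a topology with clade frequencies
#'
#' Sets each internal node's label to the frequency at which its clade is
#' recapitulated across a topology set (e.g. the top-N reconstructions) and
#' returns the annotated Newick string.
#'
#' @param t a \code{phylo} or [PrunedTopology-class] to annotate.
#' @param freqs data.frame from [cladeFrequencies()].
#' @param digits rounding for the node labels.
#' @return annotated Newick string.
#' @export
cladeAnnotatedNewick <- function(t, freqs, digits = 2L) {
    if (is(t, "PrunedTopology")) t <- t@tree
    t <- .canonicalizePhylo(t)
    ntip <- length(t$tip.label)
    sets <- .cladeSets(t)
    lab <- vapply((ntip + 1L):(ntip + t$Nnode), function(v) {
        key <- paste(sets[[v]], collapse = ",")
        i <- match(key, freqs$clade)
        if (is.na(i)) "0" else as.character(round(freqs$frequency[i], digits))
    }, character(1L))
    t$node.label <- lab
    ape::write.tree(t)
}
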
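# log-frequency lookup table: matrix pairs x lengths of log(count/valid),
# -Inf where a length was never observed; plus per-pair floor log-frequency
# log(1/(2 E_pair + 1)) used for unobserved lengths when scoring arbitrary
# topologies (any floor below 1/E preserves the ranking of supported
# topologies while keeping scores finite).
.logFreqTable <- function(d) {
    lf <- log(d@counts / d@valid)
    lf[d@counts == 0L] <- -Inf
    list(logf = lf, floor = log(1 / (2 * d@valid + 1)))
}

.pairIndexMatrix <- function(d) {
    N <- length(d@universe)
    pm <- matrix(0L, N, N)
    pm[d@pairs] <- seq_len(nrow(d@pairs))
    pm[d@pairs[, c(2L, 1L)]] <- seq_len(nrow(d@pairs))
    pm
}

#' Log-frequency score of a topology against an ensemble
#'
#' The ensemble-consistency objective: the sum over all unordered leaf pairs
#' of the natural log of the observation frequency of that pair's path length,
#' \deqn{score = \sum_{pairs} \log f_{pair,L}.}
#' The score is 0 exactly when every path length of the topology was observed
#' with frequency 1, and decreases as the topology incorporates rarer path
#' lengths. A length with zero observations for its pair contributes the
#' finite floor frequency \eqn{1/(2 E_{pair}+1)} (E = the pair's valid
#' observations) and sets the \code{floored} flag, so that topologies outside
#' the ensemble's support still receive a finite, always-worse score.
#'
#' @param t a rooted binary \code{phylo}, Newick string, or
#'   [PrunedTopology-class]; its leaves must be a subset of the
#'   distribution's universe.
#' @param d a [PathLengthDistribution-class].
#' @return a [TopologyScore-class].
#' @examples
#' tt <- readNewick("((A,B),C);")
#' d <- aggregateEnsemble(c(
#'   rep(list(asPrunedTopology("((A,B),C);")), 8),
#'   rep(list(asPrunedTopology("(A,(B,C));")), 2)))
#' logFrequencyScore(tt, d) # log .8 + log 1 + log .8
#' @export
setMethod("logFrequencyScore", signature("ANY", "PathLengthDistribution"),
          function(t, d) {
    if (is.character(t)) t <- readNewick(t)
    if (is(t, "PrunedTopology")) t <- t@tree
    if (!all(t$tip.label %in% d@universe))
        stop("topology leaves outside the distribution universe", call. = FALSE)
    lt <- .logFreqTable(d)
    pm <- .pairIndexMatrix(d)
    tipIdx <- match(t$tip.label, d@universe)
    pl <- pathLengthMatrix(t)
    k <- length(t$tip.label)
    value <- 0
    floored <- FALSE
    Lmax <- ncol(lt$logf)
    for (a in seq_len(k - 1L)) {
        for (b in (a + 1L):k) {
            p <- pm[tipIdx[a], tipIdx[b]]
            if (d@valid[p] == 0)
                stop("pair ", rownames(d@counts)[p],
                     " has no valid observations", call. = FALSE)
            L <- pl[a, b]
            lf <- if (L > Lmax) -Inf else lt$logf[p, L]
            if (is.infinite(lf)) { lf <- lt$floor[p]; floored <- TRUE }
            value <- value + lf
        }
    }
    new("TopologyScore", value = unname(value), floored = floored)
})

#' Optimistic projected score of a partial assembly
#'
#' The branch-and-bound bound: the running score of already-incorporated
#' paths plus, for every pair not yet connected, the log frequency of that
#' pair's most frequent still-achievable path length. Because every pair's
#' realized log frequency can only be lower, no completion of the assembly
#' can score above this value (admissibility), which is what makes bounding
#' safe.
#'
#' @param a an [Assembly-class].
#' @param d the [PathLengthDistribution-class] the assembly is built against.
#' @return a single numeric upper bound; \code{-Inf} when some open pair can
#'   no longer be completed with an observed length (dead assembly).
#' @export
setMethod("projectedScore", signature("Assembly", "PathLengthDistribution"),
          function(a, d) {
    lt <- .logFreqTable(d)
    .projectedScoreInternal(a@subtrees, a@completedLengths, a@score,
                            lt$logf, .pairIndexMatrix(d))
})

# subtrees: list of list(leaves = int vector, h = int vector, str = chr)
.projectedScoreInternal <- function(subtrees, completed, score, logf, pm) {
    Lmax <- ncol(logf)
    # max over achievable lengths (>= current minimum implied length)
    total <- score
    ns <- length(subtrees)
    if (ns <= 1L) return(total)
    for (si in seq_len(ns - 1L)) {
        for (sj in (si + 1L):ns) {
            A <- subtrees[[si]]; B <- subtrees[[sj]]
            for (ai in seq_along(A$leaves)) {
                for (bi in seq_along(B$leaves)) {
                    p <- pm[A$leaves[ai], B$leaves[bi]]
                    minL <- A$h[ai] + B$h[bi] + 1L
                    if (minL > Lmax) return(-Inf)
                    best <- max(logf[p, minL:Lmax])
                    if (is.infinite(best)) return(-Inf)
                    total <- total + best
                }
            }
        }
    }
    total
}

#' JSON score report
#'
#' @param t topology scored (phylo, Newick, or [PrunedTopology-class]).
#' @param d a [PathLengthDistribution-class].
#' @param file optional output path.
#' @return JSON string with the canonical Newick, score and floored flag.
#' @export
scoreReportJSON <- function(t, d, file = NULL) {
    if (is.character(t)) t <- readNewick(t)
    sc <- logFrequencyScore(t, d)
    js <- jsonlite::toJSON(list(topology = canonicalNewick(t),
                                score = sc@value, floored = sc@floored),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
    js
}
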
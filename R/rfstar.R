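# Non-trivial unrooted splits of a rooted binary tree, restricted to a common
# leaf set. Each split is serialized as the sorted side *not* containing the
# reference leaf (the smallest common label), so equal splits compare equal.
.restrictedSplits <- function(phy, common) {
    ref <- common[1L]
    ntip <- length(phy$tip.label)
    if (phy$Nnode < 2L) return(character(0L))
    sets <- .cladeSets(phy)
    out <- character(0L)
    for (v in (ntip + 2L):(ntip + phy$Nnode)) { # every internal node but the root
        side <- intersect(sets[[v]], common)
        other <- setdiff(common, side)
        if (length(side) < 2L || length(other) < 2L) next # trivial after restriction
        if (ref %in% side) side <- other
        out <- c(out, paste(sort(side, method = "radix"), collapse = "\r"))
    }
    unique(out)
}

#' Modified Robinson-Foulds distance between pruned topologies
#'
#' The classic normalized Robinson-Foulds distance \eqn{(x+y)/(2N-6)} extended
#' with terms z and z' counting designated ancestors lost to non-monophyletic
#' reconstruction: z is the number of ancestor leaves missing from the first
#' topology but not the second, z' the reverse, and
#' \deqn{RF^* = (x + y + z + z')/(2N - 6).}
#' The split counts x and y are taken over non-trivial unrooted splits
#' restricted to the ancestor leaves present in both topologies (splits that
#' become trivial after restriction are discarded, since a node above a lost
#' ancestor can still match nodes of other topologies through the partition it
#' induces on the shared ancestors). N is the universe size, so the
#' denominator \eqn{2N-6} is the number of informative splits in two complete
#' topologies.
#'
#' @param a,b [PrunedTopology-class] objects over the same orthoset universe
#'   of size N >= 4.
#' @return an [RFStarResult-class].
#' @examples
#' u <- LETTERS[1:5]
#' x <- asPrunedTopology("(((A,B),C),(D,E));", u)
#' y <- asPrunedTopology("(((A,C),B),(D,E));", u)
#' rfStar(x, y)
#' @export
setMethod("rfStar", signature("PrunedTopology", "PrunedTopology"), function(a, b) {
    if (!identical(sort(a@universe), sort(b@universe)))
        stop("topologies must share one orthoset universe", call. = FALSE)
    N <- length(a@universe)
    if (N < 4L)
        stop("RF* needs a universe of at least 4 ancestors (2N-6 informative splits)",
             call. = FALSE)
    presentA <- a@tree$tip.label
    presentB <- b@tree$tip.label
    z <- length(setdiff(presentB, presentA))      # missing from A but not B
    zprime <- length(setdiff(presentA, presentB)) # missing from B but not A
    common <- sort(intersect(presentA, presentB), method = "radix")
    if (length(common) >= 4L) {
        sa <- .restrictedSplits(a@tree, common)
        sb <- .restrictedSplits(b@tree, common)
        x <- length(setdiff(sa, sb))
        y <- length(setdiff(sb, sa))
    } else {
        x <- 0L; y <- 0L
    }
    new("RFStarResult", x = as.integer(x), y = as.integer(y),
        z = as.integer(z), zprime = as.integer(zprime), N = as.integer(N),
        distance = (x + y + z + zprime) / (2 * N - 6),
        classic = z == 0L && zprime == 0L)
})

#' Reconstruction accuracy
#'
#' \code{1 - rfStar(truth, recon)@distance}: 1 when the topologies are
#' identical, 0 when their RF* distance is maximal.
#'
#' @param truth the true pruned topology.
#' @param recon a reconstructed pruned topology over the same universe.
#' @return a number in [0, 1] for well-formed inputs.
#' @export
setMethod("topologyAccuracy", signature("PrunedTopology", "PrunedTopology"),
          function(truth, recon) 1 - rfStar(truth, recon)@distance)

#' Reconstruction precision
#'
#' One minus the ensemble mean of RF* distances between a reference topology
#' (typically the all-sequence reconstruction) and high-fraction subsample
#' reconstructions. Precision is observable without knowing the truth and
#' tracks the accuracy of the reference reconstruction.
#'
#' @param reference the all-sequence pruned topology.
#' @param ensemble non-empty list of pruned topologies over the same universe.
#' @return a number in [0, 1] for well-formed inputs.
#' @export
setMethod("topologyPrecision", signature("PrunedTopology", "list"),
          function(reference, ensemble) {
    if (length(ensemble) == 0L)
        stop("precision needs a non-empty ensemble", call. = FALSE)
    d <- vapply(ensemble, function(t) rfStar(reference, t)@distance, numeric(1L))
    1 - mean(d)
})

#' JSON serialization of an RF* comparison
#'
#' @param x an [RFStarResult-class].
#' @param file optional output path.
#' @return JSON string.
#' @export
rfStarJSON <- function(x, file = NULL) {
    js <- jsonlite::toJSON(list(x = x@x, y = x@y, z = x@z, zprime = x@zprime,
                                N = x@N, distance = x@distance,
                                classic = x@classic),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
    js
}
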
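#' @rdname rfStar
#' @export
setGeneric("rfStar", function(a, b) standardGeneric("rfStar"))

#' @rdname topologyAccuracy
#' @export
setGeneric("topologyAccuracy", function(truth, recon) standardGeneric("topologyAccuracy"))

#' @rdname topologyPrecision
#' @export
setGeneric("topologyPrecision", function(reference, ensemble) standardGeneric("topologyPrecision"))

#' @rdname logFrequencyScore
#' @export
setGeneric("logFrequencyScore", function(t, d) standardGeneric("logFrequencyScore"))

#' @rdname projectedScore
#' @export
setGeneric("projectedScore", function(a, d) standardGeneric("projectedScore"))

#' @rdname branchExtensions
#' @export
setGeneric("branchExtensions", function(a, d) standardGeneric("branchExtensions"))

#' @rdname subsampleFamily
#' @export
setGeneric("subsampleFamily", function(f, s) standardGeneric("subsampleFamily"))

#' @rdname buildEnsemble
#' @export
setGeneric("buildEnsemble",
           function(f, s, adapter, ...) standardGeneric("buildEnsemble"))

# --- simple accessors ----------------------------------------------------

#' Accessors for the S4 containers
#'
#' \code{prunedTree} returns the pruned \code{phylo}; \code{ancestorLeaves}
#' the orthoset ancestors present as leaves; \code{missingAncestors} the
#' orthosets lost to non-monophyly; \code{spuriousNodes} the flagged internal
#' node ids; \code{monophylyReport} the per-orthoset report;
#' \code{orthosetUniverse} the designated-ancestor universe;
#' \code{scoreValue}/\code{scoreFloored} the components of a
#' \code{TopologyScore}; \code{topologies}/\code{topologyScores} and
#' \code{isComplete}/\code{searchStats} the components of a
#' \code{ReconstructionResult}.
#'
#' @param x an object of the matching class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("prunedTree", function(x) standardGeneric("prunedTree"))
#' @rdname accessors
#' @export
setGeneric("ancestorLeaves", function(x) standardGeneric("ancestorLeaves"))
#' @rdname accessors
#' @export
setGeneric("missingAncestors", function(x) standardGeneric("missingAncestors"))
#' @rdname accessors
#' @export
setGeneric("spuriousNodes", function(x) standardGeneric("spuriousNodes"))
#' @rdname accessors
#' @export
setGeneric("monophylyReport", function(x) standardGeneric("monophylyReport"))
#' @rdname accessors
#' @export
setGeneric("orthosetUniverse", function(x) standardGeneric("orthosetUniverse"))
#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setGeneric("scoreFloored", function(x) standardGeneric("scoreFloored"))
#' @rdname accessors
#' @export
setGeneric("topologies", function(x) standardGeneric("topologies"))
#' @rdname accessors
#' @export
setGeneric("topologyScores", function(x) standardGeneric("topologyScores"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setGeneric("searchStats", function(x) standardGeneric("searchStats"))

setMethod("prunedTree", "PrunedTopology", function(x) x@tree)
setMethod("ancestorLeaves", "PrunedTopology", function(x) x@tree$tip.label)
setMethod("missingAncestors", "PrunedTopology", function(x) x@missing)
setMethod("spuriousNodes", "PrunedTopology", function(x) x@spurious)
setMethod("monophylyReport", "PrunedTopology", function(x) x@monophyly)
setMethod("orthosetUniverse", "PrunedTopology", function(x) x@universe)
setMethod("orthosetUniverse", "PathLengthDistribution", function(x) x@universe)
setMethod("scoreValue", "TopologyScore", function(x) x@value)
setMethod("scoreFloored", "TopologyScore", function(x) x@floored)
setMethod("topologies", "ReconstructionResult", function(x) x@topologies)
setMethod("topologyScores", "ReconstructionResult", function(x) x@scores)
setMethod("isComplete", "ReconstructionResult", function(x) x@complete)
setMethod("searchStats", "ReconstructionResult", function(x) x@stats)

# --- show methods --------------------------------------------------------

setMethod("show", "PrunedTopology", function(object) {
    cat("PrunedTopology over", length(object@universe), "orthoset ancestors\n")
    cat("  present:", paste(object@tree$tip.label, collapse = ", "), "\n")
    if (length(object@missing))
        cat("  missing (non-monophyletic):",
            paste(object@missing, collapse = ", "), "\n")
    if (length(object@spurious))
        cat("  spurious internal nodes:", length(object@spurious), "\n")
    cat(" ", canonicalNewick(object@tree), "\n")
})

setMethod("show", "RFStarResult", function(object) {
    cat(sprintf("RF* = %.4f  (x=%d y=%d z=%d z'=%d, N=%d%s)\n",
                object@distance, object@x, object@y, object@z,
                object@zprime, object@N,
                if (object@classic) ", classic" else ""))
})

setMethod("show", "PathLengthDistribution", function(object) {
    cat("PathLengthDistribution:", length(object@universe), "ancestors,",
        nrow(object@pairs), "pairs,", object@ensembleSize, "ensemble members\n")
    cat("  valid observations per pair:",
        paste(range(object@valid), collapse = "-"), "\n")
})

setMethod("show", "TopologyScore", function(object) {
    cat(sprintf("log-frequency score %.6f%s\n", object@value,
                if (object@floored) " (floored)" else ""))
})

setMethod("show", "Assembly", function(object) {
    cat("Assembly:", length(object@subtrees), "subtrees,",
        sum(!is.na(object@completedLengths)), "of",
        length(object@completedLengths), "pairs completed, score",
        format(object@score, digits = 6), "\n")
})

setMethod("show", "ReconstructionResult", function(object) {
    cat("ReconstructionResult:", length(object@scores), "topologies",
        if (object@complete) "(complete)" else "(truncated)", "\n")
    n <- min(5L, length(object@scores))
    for (i in seq_len(n))
        cat(sprintf("  %2d. %s  score %.6f\n", i, object@newick[i],
                    object@scores[i]))
    if (length(object@scores) > n) cat("  ...\n")
    cat("  assemblies:", paste(names(object@stats), object@stats,
                               collapse = ", "), "\n")
})

setMethod("show", "FamilyDataset", function(object) {
    os <- table(object@orthosets[names(object@sequences)])
    cat("FamilyDataset:", length(object@sequences), "sequences,",
        length(os), "orthosets (", paste(range(os), collapse = "-"),
        "members )\n")
    if (!is.null(object@trueTopology))
        cat("  true topology:", canonicalNewick(object@trueTopology), "\n")
})

setMethod("show", "SubsampleSpec", function(object) {
    mode <- if (is.na(object@fraction))
        paste(object@count, "per orthoset")
    else paste0(round(100 * object@fraction), "% per orthoset (ceiling)")
    cat("SubsampleSpec:", mode, "x", object@replicates,
        "replicates, seed", object@seed, "\n")
})

setMethod("show", "InferenceAdapter", function(object) {
    cat("InferenceAdapter:", object@name, "\n")
})

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nParalogs, "paralogs x",
        if (is.null(object@speciesTree)) object@nSpecies
        else length(object@speciesTree$tip.label),
        "species; mean paralog branch length", object@meanBranchLength,
        "\n  sequence length", object@seqLength, "(", object@model,
        "), seed", object@seed, "\n")
})
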
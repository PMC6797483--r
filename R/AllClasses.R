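#' @import methods
#' @importFrom stats rexp runif setNames cor complete.cases
#' @importFrom utils head write.table read.table combn
NULL

setOldClass("phylo")
setClassUnion("phyloOrNULL", c("phylo", "NULL"))

#' Pruned ancestor-divergence topology
#'
#' A full phylogeny pruned to one leaf per monophyletic orthoset (the
#' "integrated-out" clade ancestors). Orthosets whose sampled leaves were not
#' monophyletic contribute no ancestor leaf; every surviving internal node that
#' descended from such an orthoset's MRCA is flagged spurious, and paths
#' through spurious nodes are excluded from ensemble aggregation.
#'
#' @slot tree a rooted binary \code{phylo} whose tips are orthoset names.
#' @slot universe ordered character vector of all orthoset names in the
#'   analysis (the designated-ancestor universe of the RF* metric).
#' @slot missing orthoset names sampled in the source tree but lost to
#'   non-monophyletic reconstruction.
#' @slot spurious integer ids (ape numbering) of untrustworthy internal nodes
#'   of \code{tree}.
#' @slot monophyly data.frame with columns \code{orthoset},
#'   \code{monophyletic}, \code{nLeaves} describing the source tree.
#' @seealso [pruneToAncestors()], [rfStar()], [aggregateEnsemble()]
#' @export
setClass("PrunedTopology",
    representation(tree = "phylo", universe = "character",
                   missing = "character", spurious = "integer",
                   monophyly = "data.frame"))

setValidity("PrunedTopology", function(object) {
    tips <- object@tree$tip.label
    if (anyDuplicated(tips)) return("duplicate ancestor leaves")
    if (!all(tips %in% object@universe))
        return("ancestor leaves outside the orthoset universe")
    if (any(object@missing %in% tips))
        return("orthoset both present and missing")
    TRUE
})

#' Modified Robinson-Foulds comparison
#'
#' Component counts and normalized distance of the RF* metric between two
#' pruned topologies over a shared universe of N designated ancestors:
#' \deqn{RF^* = (x + y + z + z') / (2N - 6)}
#' where x/y count non-trivial splits unique to either side (restricted to the
#' shared ancestor leaves) and z/z' count ancestor leaves missing from one
#' topology but not the other.
#'
#' @slot x,y split counts unique to the first/second topology.
#' @slot z,zprime counts of ancestor leaves missing from the first/second
#'   topology only.
#' @slot N number of designated ancestors per topology.
#' @slot distance the normalized distance.
#' @slot classic TRUE when z = z' = 0 (the classic RF setting, distance in
#'   [0, 1]).
#' @export
setClass("RFStarResult",
    representation(x = "integer", y = "integer", z = "integer",
                   zprime = "integer", N = "integer", distance = "numeric",
                   classic = "logical"))

#' Per-pair path-length frequency distribution of an ensemble
#'
#' For every unordered pair of orthoset ancestors, the empirical distribution
#' of the number of internal nodes (root included) on the path between them,
#' aggregated over an ensemble of pruned topologies. Compromised observations
#' (missing leaf, or path through a spurious node) are excluded; frequencies
#' normalize per pair over that pair's valid observations.
#'
#' @slot universe ordered orthoset names (size N).
#' @slot pairs integer matrix, one row per unordered pair (indices into
#'   \code{universe}, first < second).
#' @slot counts integer matrix pairs x lengths; column L holds the number of
#'   ensemble members in which the pair was observed at path length L.
#' @slot valid per-pair totals of valid observations.
#' @slot ensembleSize number of ensemble members aggregated.
#' @seealso [aggregateEnsemble()], [sortedEntries()], [logFrequencyScore()]
#' @export
setClass("PathLengthDistribution",
    representation(universe = "character", pairs = "matrix",
                   counts = "matrix", valid = "numeric",
                   ensembleSize = "integer"))

setValidity("PathLengthDistribution", function(object) {
    if (nrow(object@pairs) != nrow(object@counts))
        return("pairs/counts row mismatch")
    if (length(object@valid) != nrow(object@counts))
        return("valid total per pair required")
    if (any(object@counts < 0)) return("negative counts")
    if (!isTRUE(all.equal(unname(rowSums(object@counts)), unname(object@valid))))
        return("valid totals must equal per-pair count sums")
    TRUE
})

#' Log-frequency score of a topology against an ensemble
#'
#' @slot value sum over leaf pairs of log observation frequency of the
#'   topology's path lengths (natural log, always <= 0).
#' @slot floored TRUE when any pair used the unobserved-length floor
#'   frequency 1 / (2 E_pair + 1).
#' @export
setClass("TopologyScore",
    representation(value = "numeric", floored = "logical"))

#' Partial reconstruction state of the branch-and-bound search
#'
#' A forest of disjoint rooted subtrees over the ancestor universe, the
#' lengths chosen for the leaf pairs completed so far, and the running score.
#'
#' @slot universe ordered ancestor names.
#' @slot subtrees list of internal subtree records (leaf indices, per-leaf
#'   internal-node counts to the subtree root, canonical Newick fragment).
#' @slot completedLengths integer vector, one entry per unordered pair
#'   (NA while the pair is still open).
#' @slot score running sum of log frequencies of completed paths.
#' @seealso [branchExtensions()], [projectedScore()], [reconstructNBest()]
#' @export
setClass("Assembly",
    representation(universe = "character", subtrees = "list",
                   completedLengths = "integer", score = "numeric"))

#' Ranked result of the N-best topology search
#'
#' @slot topologies list of \code{phylo} objects, best score first.
#' @slot newick canonical Newick strings parallel to \code{topologies}.
#' @slot scores log-frequency scores, non-increasing.
#' @slot complete TRUE when branch-and-bound ran to exhaustion (the result is
#'   then exactly the N best constructible topologies); FALSE when truncated
#'   by a budget.
#' @slot stats named integer vector: assemblies created, abandoned,
#'   deduplicated, completed.
#' @export
setClass("ReconstructionResult",
    representation(topologies = "list", newick = "character",
                   scores = "numeric", complete = "logical",
                   stats = "integer"))

#' Protein family dataset
#'
#' Sequences plus the orthoset assignment of every sequence, and (for
#' benchmarks) the true paralog divergence topology and true full phylogeny.
#'
#' @slot sequences an \code{AAStringSet}, one entry per labeled sequence.
#' @slot orthosets named character vector mapping sequence label to orthoset.
#' @slot trueTopology optional true paralog topology (\code{phylo}).
#' @slot trueTree optional true full phylogeny with branch lengths.
#' @export
setClass("FamilyDataset",
    representation(sequences = "AAStringSet", orthosets = "character",
                   trueTopology = "phyloOrNULL", trueTree = "phyloOrNULL"))

setValidity("FamilyDataset", function(object) {
    labs <- names(object@sequences)
    if (is.null(labs) || anyDuplicated(labs)) return("sequences must have unique labels")
    if (!all(labs %in% names(object@orthosets)))
        return("every sequence must be assigned to an orthoset")
    if (length(unique(object@orthosets[labs])) < 2L)
        return("at least 2 orthosets required")
    TRUE
})

#' Subsampling design
#'
#' @slot fraction per-orthoset sampling fraction in (0, 1]; the per-orthoset
#'   count is ceiling(fraction * n). NA when \code{count} is used.
#' @slot count fixed per-orthoset count; NA when \code{fraction} is used.
#' @slot replicates number of independent subsamples.
#' @slot seed RNG seed making the design fully reproducible.
#' @export
setClass("SubsampleSpec",
    representation(fraction = "numeric", count = "integer",
                   replicates = "integer", seed = "integer"))

setValidity("SubsampleSpec", function(object) {
    if (is.na(object@fraction) == is.na(object@count))
        return("exactly one of fraction/count must be set")
    if (!is.na(object@fraction) &&
        (object@fraction <= 0 || object@fraction > 1))
        return("fraction must be in (0, 1]")
    if (object@replicates < 1L) return("replicates >= 1 required")
    TRUE
})

#' Tree inference adapter
#'
#' Contract: a function taking an \code{AAStringSet} of homologous (gap-free,
#' equal-length or externally alignable) sequences and returning a
#' \code{phylo} whose tips are exactly the input labels. The built-in adapter
#' is neighbor-joining on uncorrected p-distances; external align-then-infer
#' pipelines are wrapped with [commandAdapter()].
#'
#' @slot name adapter label used in reports.
#' @slot infer the inference function.
#' @export
setClass("InferenceAdapter",
    representation(name = "character", infer = "function"))

#' Simulation parameters for synthetic paralog families
#'
#' @slot nParalogs number of paralogs (duplication leaves).
#' @slot meanBranchLength mean of the exponential branch lengths of the random
#'   paralog topology, substitutions/site.
#' @slot speciesTree species tree with branch lengths grafted below every
#'   paralog leaf (NULL: generate a birth-death tree with \code{nSpecies}
#'   tips).
#' @slot nSpecies tips of the generated species tree.
#' @slot speciesTreeHeight expected root-to-tip height of each grafted species
#'   copy, substitutions/site.
#' @slot rescaleRange uniform range of the per-paralog total-height rescaling
#'   factor (heterotachy between paralogs).
#' @slot perturbRange uniform range of the per-segment branch length
#'   perturbation factor.
#' @slot seqLength simulated sequence length, residues.
#' @slot rateClasses per-site-class substitution rate scaling factors.
#' @slot nSegments number of contiguous sequence segments cycling through
#'   \code{rateClasses}.
#' @slot model empirical amino-acid substitution model for simulation
#'   (deliberately different from anything the inference adapters use).
#' @slot seed RNG seed.
#' @export
setClass("SimulationParams",
    representation(nParalogs = "integer", meanBranchLength = "numeric",
                   speciesTree = "phyloOrNULL", nSpecies = "integer",
                   speciesTreeHeight = "numeric", rescaleRange = "numeric",
                   perturbRange = "numeric", seqLength = "integer",
                   rateClasses = "numeric", nSegments = "integer",
                   model = "character", seed = "integer"))

setValidity("SimulationParams", function(object) {
    if (object@nParalogs < 2L) return("nParalogs >= 2 required")
    if (object@meanBranchLength <= 0) return("meanBranchLength must be positive")
    if (object@seqLength < 1L) return("seqLength >= 1 required")
    if (any(object@rateClasses <= 0)) return("rate classes must be positive")
    TRUE
})
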
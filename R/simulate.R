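#' Construct simulation parameters
#'
#' Defaults mirror the benchmark design of this package: random paralog
#' divergence topologies with exponential branch lengths, a birth-death
#' species tree grafted below every paralog leaf with per-paralog height
#' rescaling (heterotachy) and per-segment perturbation, and
#' substitution-only protein evolution under an empirical model with
#' per-segment rate classes spanning a five-fold range.
#'
#' @param nParalogs number of paralogs.
#' @param meanBranchLength mean exponential branch length of the paralog
#'   topology (substitutions/site).
#' @param speciesTree optional \code{phylo} with branch lengths; when NULL a
#'   birth-death tree with \code{nSpecies} tips is generated.
#' @param nSpecies tips of the generated species tree.
#' @param speciesTreeHeight expected root-to-tip height of each grafted
#'   species copy (substitutions/site).
#' @param rescaleRange uniform range of the per-paralog height factor.
#' @param perturbRange uniform range of the per-branch perturbation factor.
#' @param seqLength simulated sequence length (residues).
#' @param rateClasses per-site-class rate scaling factors.
#' @param nSegments contiguous segments cycling through \code{rateClasses}.
#' @param model empirical substitution model for simulation (see
#'   \code{phangorn::simSeq}); deliberately different from anything the
#'   inference adapters assume.
#' @param seed RNG seed.
#' @return a [SimulationParams-class].
#' @export
simulationParams <- function(nParalogs = 15L, meanBranchLength = 0.7,
                             speciesTree = NULL, nSpecies = 66L,
                             speciesTreeHeight = 0.45,
                             rescaleRange = c(0.5, 1.5),
                             perturbRange = c(0.75, 1.25),
                             seqLength = 250L,
                             rateClasses = c(0.4, 0.8, 1.2, 2),
                             nSegments = 8L, model = "JTT", seed = 1L) {
    new("SimulationParams", nParalogs = as.integer(nParalogs),
        meanBranchLength = meanBranchLength, speciesTree = speciesTree,
        nSpecies = as.integer(nSpecies),
        speciesTreeHeight = speciesTreeHeight, rescaleRange = rescaleRange,
        perturbRange = perturbRange, seqLength = as.integer(seqLength),
        rateClasses = rateClasses, nSegments = as.integer(nSegments),
        model = model, seed = as.integer(seed))
}

#' Random rooted paralog divergence topology
#'
#' Sequential random attachment: starting from a two-leaf tree, each further
#' leaf is attached to a uniformly chosen edge (the position above the root
#' included), which makes every rooted binary topology on n leaves equally
#' likely. Branch lengths are i.i.d. exponential with the requested mean.
#'
#' @param n number of leaves (paralogs), >= 2.
#' @param meanBranchLength mean branch length (substitutions/site).
#' @param seed optional RNG seed.
#' @param labels leaf labels; default \code{P01, P02, ...}.
#' @return a rooted binary \code{phylo} with branch lengths.
#' @export
randomParalogTopology <- function(n, meanBranchLength = 0.7, seed = NULL,
                                  labels = sprintf("P%02d", seq_len(n))) {
    if (n < 2L) stop("need at least 2 paralogs", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    tree <- list(children = list(list(label = labels[1L], len = NA_real_),
                                 list(label = labels[2L], len = NA_real_)),
                 len = NA_real_)
    countNodes <- function(node) {
        if (.isLeaf(node)) return(1L)
        1L + sum(vapply(node$children, countNodes, integer(1L)))
    }
    attachAt <- function(node, pos, leaf) {
        # pos indexes nodes in preorder; attaching at a node bisects the edge
        # above it (pos 1 = above the root)
        rec <- function(nd, counter) {
            counter <- counter + 1L
            if (counter == pos)
                return(list(node = list(children = list(nd, leaf),
                                        len = NA_real_),
                            counter = counter, done = TRUE))
            if (.isLeaf(nd)) return(list(node = nd, counter = counter, done = FALSE))
            for (i in seq_along(nd$children)) {
                r <- rec(nd$children[[i]], counter)
                counter <- r$counter
                if (r$done) {
                    nd$children[[i]] <- r$node
                    return(list(node = nd, counter = counter, done = TRUE))
                }
                nd$children[[i]] <- r$node
            }
            list(node = nd, counter = counter, done = FALSE)
        }
        rec(node, 0L)$node
    }
    if (n > 2L) {
        for (k in 3:n) {
            leaf <- list(label = labels[k], len = NA_real_)
            pos <- sample.int(countNodes(tree), 1L)
            tree <- attachAt(tree, pos, leaf)
        }
    }
    phy <- .nestedToPhylo(tree)
    phy$edge.length <- rexp(nrow(phy$edge), rate = 1 / meanBranchLength)
    phy
}

#' Seedable birth-death species tree
#'
#' @param nTips number of species.
#' @param birth,death birth-death rates.
#' @param height root-to-tip height the ultrametric tree is scaled to.
#' @param seed optional RNG seed.
#' @return an ultrametric \code{phylo} with tips \code{s01, s02, ...}.
#' @export
speciesTree <- function(nTips = 66L, birth = 1, death = 0.5, height = 1,
                        seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    phy <- ape::rphylo(nTips, birth = birth, death = death)
    phy$tip.label <- sprintf("s%02d", seq_len(nTips))
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * height / h
    phy
}

#' Graft a species tree below every paralog leaf
#'
#' Each paralog leaf is replaced by an independent copy of the species tree:
#' the copy is rescaled in total height (to \code{speciesTreeHeight} times a
#' uniform draw from \code{rescaleRange}, emulating faster or slower
#' evolution of individual paralogs) and every branch is independently
#' perturbed by a uniform factor from \code{perturbRange}. Leaves are
#' labelled \code{paralog_species}. Pruning the grafted phylogeny back to
#' orthoset ancestors recovers exactly the paralog topology.
#'
#' @param paralogTree rooted binary \code{phylo} with branch lengths.
#' @param species species tree (\code{phylo} with branch lengths).
#' @param p a [SimulationParams-class] (rescale/perturb ranges and height).
#' @param seed optional RNG seed.
#' @return list with \code{tree} (the full phylogeny), \code{orthosets}
#'   (named character: leaf -> paralog) and \code{paralogTopology}.
#' @export
graftSpeciesTree <- function(paralogTree, species, p = simulationParams(),
                             seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(species$edge.length))
        stop("species tree needs branch lengths", call. = FALSE)
    h0 <- max(ape::node.depth.edgelength(species))
    nested <- .nestedFromPhylo(paralogTree)
    orthosets <- character(0L)
    graft <- function(node) {
        if (.isLeaf(node)) {
            para <- node$label
            copy <- species
            fac <- p@speciesTreeHeight *
                runif(1L, p@rescaleRange[1L], p@rescaleRange[2L]) / h0
            copy$edge.length <- copy$edge.length * fac *
                runif(length(copy$edge.length),
                      p@perturbRange[1L], p@perturbRange[2L])
            copy$tip.label <- paste(para, copy$tip.label, sep = "_")
            orthosets <<- c(orthosets,
                            setNames(rep(para, length(copy$tip.label)),
                                     copy$tip.label))
            sub <- .nestedFromPhylo(copy)
            sub$len <- node$len # paralog stem branch retained
            return(sub)
        }
        node$children <- lapply(node$children, graft)
        node
    }
    full <- .nestedToPhylo(graft(nested))
    list(tree = full, orthosets = orthosets, paralogTopology = paralogTree)
}

#' Simulate protein sequences along a phylogeny
#'
#' Substitution-only evolution under an empirical amino-acid model
#' (via \code{phangorn::simSeq}): the root sequence is drawn from the model's
#' stationary frequencies and sites evolve independently along branches. The
#' sequence is divided into \code{nSegments} contiguous segments whose
#' substitution rates cycle through \code{rateClasses}, emulating
#' conservation differences across a protein fold. With no indels the true
#' alignment is the sequence set itself, which is what allows distance-based
#' adapters to run without an external aligner.
#'
#' @param tree \code{phylo} with branch lengths (substitutions/site).
#' @param p a [SimulationParams-class].
#' @param seed optional RNG seed.
#' @return an \code{AAStringSet} named by the tree's tip labels.
#' @export
evolveSequences <- function(tree, p = simulationParams(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    segLen <- diff(round(seq(0, p@seqLength, length.out = p@nSegments + 1L)))
    segLen <- segLen[segLen > 0]
    rates <- rep_len(p@rateClasses, length(segLen))
    parts <- lapply(seq_along(segLen), function(i) {
        s <- phangorn::simSeq(tree, l = segLen[i], type = "AA",
                              model = p@model, rate = rates[i])
        as.character(s)
    })
    m <- do.call(cbind, parts)
    Biostrings::AAStringSet(setNames(apply(m, 1L, paste0, collapse = ""),
                                     rownames(m)))
}

#' Simulate a complete synthetic paralog family
#'
#' Chains [randomParalogTopology()], [speciesTree()] (unless one is
#' supplied), [graftSpeciesTree()] and [evolveSequences()] into a
#' benchmark-ready [FamilyDataset-class] carrying the true paralog topology.
#'
#' @param p a [SimulationParams-class].
#' @return a [FamilyDataset-class].
#' @examples
#' fam <- simulateFamily(simulationParams(nParalogs = 4L, nSpecies = 4L,
#'                                        seqLength = 60L, seed = 7L))
#' fam
#' @export
simulateFamily <- function(p = simulationParams()) {
    set.seed(p@seed)
    ptree <- randomParalogTopology(p@nParalogs, p@meanBranchLength)
    sp <- if (is.null(p@speciesTree)) {
        speciesTree(p@nSpecies, height = 1)
    } else p@speciesTree
    g <- graftSpeciesTree(ptree, sp, p)
    seqs <- evolveSequences(g$tree, p)
    new("FamilyDataset", sequences = seqs, orthosets = g$orthosets,
        trueTopology = .canonicalizePhylo(ptree), trueTree = g$tree)
}

#' NNI-perturbed topology ensemble
#'
#' A fast fixture standing in for inference noise: each member is the truth
#' after \code{intensity} random rooted nearest-neighbor interchanges.
#' Intensity 0 reproduces the truth exactly; increasing intensity lowers the
#' precision of the truth against the ensemble.
#'
#' @param truth \code{phylo}, Newick string, or [PrunedTopology-class].
#' @param k ensemble size (>= 1).
#' @param intensity number of random NNI moves per member (>= 0).
#' @param seed optional RNG seed.
#' @return list of [PrunedTopology-class] sharing the truth's leaf universe.
#' @export
perturbedEnsemble <- function(truth, k, intensity = 1L, seed = NULL) {
    if (k < 1L) stop("k must be >= 1", call. = FALSE)
    if (intensity < 0L) stop("intensity must be >= 0", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    if (is.character(truth)) truth <- readNewick(truth)
    if (is(truth, "PrunedTopology")) truth <- truth@tree
    truth <- .canonicalizePhylo(truth)
    universe <- sort(truth$tip.label, method = "radix")
    lapply(seq_len(k), function(i) {
        t <- truth
        for (m in seq_len(intensity)) t <- .rootedNNI(t)
        asPrunedTopology(t, universe)
    })
}

# One random rooted NNI move: pick an internal non-root node v, exchange its
# sibling with one of its children.
.rootedNNI <- function(phy) {
    nested <- .nestedFromPhylo(phy)
    paths <- list()
    collect <- function(node, path) {
        if (.isLeaf(node)) return(invisible(NULL))
        if (length(path) > 0L) paths[[length(paths) + 1L]] <<- path
        for (i in seq_along(node$children))
            collect(node$children[[i]], c(path, i))
        invisible(NULL)
    }
    collect(nested, integer(0L))
    if (length(paths) == 0L) return(phy) # 2-leaf tree: nothing to do
    path <- paths[[sample.int(length(paths), 1L)]]
    parentPath <- path[-length(path)]
    vIdx <- path[length(path)]
    getNode <- function(node, p) {
        for (i in p) node <- node$children[[i]]
        node
    }
    setNode <- function(node, p, value) {
        if (length(p) == 0L) return(value)
        node$children[[p[1L]]] <- setNode(node$children[[p[1L]]], p[-1L], value)
        node
    }
    parent <- getNode(nested, parentPath)
    v <- parent$children[[vIdx]]
    sIdx <- if (vIdx == 1L) 2L else 1L
    cIdx <- sample.int(length(v$children), 1L)
    sib <- parent$children[[sIdx]]
    child <- v$children[[cIdx]]
    v$children[[cIdx]] <- sib
    parent$children[[sIdx]] <- child
    parent$children[[vIdx]] <- v
    nested <- setNode(nested, parentPath, parent)
    .nestedToPhylo(.canonicalizeNested(nested))
}
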
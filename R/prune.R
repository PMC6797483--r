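#' Prune a full phylogeny to orthoset common ancestors
#'
#' Each orthoset whose sampled leaves form a clade is collapsed to a single
#' ancestor leaf named for the orthoset; degree-2 nodes arising from the
#' removal are suppressed. An orthoset whose sampled leaves are *not*
#' monophyletic yields no ancestor leaf: its leaves are deleted, it is
#' reported in \code{missingAncestors}, and every surviving internal node at
#' or below the MRCA of its sampled leaves is flagged spurious (their
#' existence depends on the offending arrangement, so paths through them are
#' excluded from ensemble aggregation).
#'
#' @param t a rooted binary \code{phylo} (see [readNewick()] for the rooting
#'   convention applied to unrooted inference output).
#' @param m named character vector mapping every leaf label of \code{t} to an
#'   orthoset name.
#' @param universe ordered character vector of all orthoset names of the
#'   analysis; defaults to the sorted orthosets sampled in \code{m}. Supply
#'   it explicitly when subsampling may drop whole orthosets.
#' @return a [PrunedTopology-class].
#' @examples
#' t <- readNewick("((a1,a2),(b1,(b2,c1)));")
#' m <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
#' pruneToAncestors(t, m)
#' @export
pruneToAncestors <- function(t, m, universe = NULL) {
    .checkBinaryRooted(t, "input phylogeny")
    tips <- t$tip.label
    if (!all(tips %in% names(m)))
        stop("leaves missing from the orthoset map: ",
             paste(head(setdiff(tips, names(m)), 5L), collapse = ", "),
             call. = FALSE)
    map <- m[tips]
    sampled <- sort(unique(unname(map)), method = "radix")
    if (is.null(universe)) universe <- sampled
    if (!all(sampled %in% universe))
        stop("orthosets outside the declared universe", call. = FALSE)

    ntip <- length(tips)
    sets <- .cladeSets(t)
    setKeys <- vapply(sets, paste, character(1L), collapse = "\r")
    osLeaves <- split(tips, unname(map))

    anchor <- setNames(rep(NA_integer_, length(sampled)), sampled)
    for (os in sampled) {
        key <- paste(sort(osLeaves[[os]], method = "radix"), collapse = "\r")
        hit <- which(setKeys == key)
        if (length(hit)) anchor[os] <- hit[1L]
    }
    mono <- !is.na(anchor)
    report <- data.frame(orthoset = sampled,
                         monophyletic = unname(mono),
                         nLeaves = lengths(osLeaves)[sampled],
                         row.names = NULL)
    if (sum(mono) < 2L)
        stop(errorCondition(
            paste("unprunable: fewer than 2 orthosets are monophyletic (",
                  sum(mono), ")"),
            class = c("unprunableError", "error", "condition")))

    # spurious source nodes: the full subtree of each non-monophyletic
    # orthoset's MRCA (conservative exclusion)
    spuriousSrc <- integer(0L)
    if (any(!mono)) {
        chains <- .ancestorChains(t)
        for (os in sampled[!mono]) {
            idx <- match(osLeaves[[os]], tips)
            common <- Reduce(intersect, chains[idx])
            mrca <- common[1L] # chains run parent -> root, first shared = MRCA
            below <- which(vapply(seq_len(ntip + t$Nnode), function(v) {
                v == mrca || mrca %in% chains[[v]]
            }, logical(1L)))
            spuriousSrc <- union(spuriousSrc, below[below > ntip])
        }
    }
    anchorOf <- setNames(rep(NA_character_, ntip + t$Nnode), NULL)
    for (os in sampled[mono]) anchorOf[anchor[os]] <- os
    dropLeaf <- tips %in% unlist(osLeaves[sampled[!mono]], use.names = FALSE)

    build <- function(phy) {
        kids <- .nodeDepths(phy)$children
        rec <- function(v) {
            if (!is.na(anchorOf[v]))
                return(list(label = anchorOf[v], len = NA_real_))
            if (v <= ntip) {
                if (dropLeaf[v]) return(NULL)
                # leaf of a monophyletic singleton orthoset is anchored above
                return(list(label = tips[v], len = NA_real_))
            }
            parts <- Filter(Negate(is.null), lapply(kids[[v]], rec))
            if (length(parts) == 0L) return(NULL)
            if (length(parts) == 1L) return(parts[[1L]])
            list(children = parts, len = NA_real_,
                 spurious = v %in% spuriousSrc)
        }
        rec(ntip + 1L)
    }
    nested <- build(t)
    nested <- .canonicalizeNested(nested)
    ptree <- .nestedToPhylo(nested)
    spur <- attr(ptree, "spurious")
    if (is.null(spur)) spur <- integer(0L)
    attr(ptree, "spurious") <- NULL
    new("PrunedTopology", tree = ptree, universe = universe,
        missing = sampled[!mono], spurious = as.integer(spur),
        monophyly = report)
}

#' Treat an already-reduced topology as a pruned topology
#'
#' Convenience constructor for trees whose leaves *are* the orthoset
#' ancestors (simulated paralog topologies, perturbed fixtures): all
#' ancestors present, nothing spurious.
#'
#' @param t a rooted binary \code{phylo} (or Newick string) over ancestor
#'   labels.
#' @param universe the designated-ancestor universe; defaults to the sorted
#'   tip labels.
#' @return a [PrunedTopology-class].
#' @export
asPrunedTopology <- function(t, universe = NULL) {
    if (is.character(t)) t <- readNewick(t)
    t <- .canonicalizePhylo(t)
    labs <- sort(t$tip.label, method = "radix")
    if (is.null(universe)) universe <- labs
    new("PrunedTopology", tree = t, universe = universe,
        missing = character(0L),
        spurious = integer(0L),
        monophyly = data.frame(orthoset = labs,
                               monophyletic = TRUE,
                               nLeaves = 1L))
}

#' JSON monophyly / pruning report
#'
#' @param x a [PrunedTopology-class].
#' @param file optional output path.
#' @return the JSON string, invisibly when written to file.
#' @export
pruningReportJSON <- function(x, file = NULL) {
    obj <- list(topology = canonicalNewick(x@tree),
                universe = x@universe,
                missing_ancestors = x@missing,
                n_spurious_nodes = length(x@spurious),
                monophyly = x@monophyly)
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
    js
}
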
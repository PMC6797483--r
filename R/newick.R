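#' Read a Newick string into a rooted binary topology
#'
#' Parses Newick text (with or without branch lengths) and canonicalizes the
#' result: children are ordered by their smallest leaf label, and any
#' multifurcation -- in particular the basal trifurcation produced by unrooted
#' inference tools -- is resolved deterministically by joining the first two
#' children (in canonical order) under a new node. Applying one convention to
#' every tree of an analysis keeps all leaf-to-leaf path lengths comparable.
#'
#' @param text a Newick string (must end in \code{;}).
#' @return a rooted binary \code{phylo}. Branch lengths are retained when
#'   present but carry no meaning for any topology-space operation in this
#'   package.
#' @examples
#' phy <- readNewick("(((A,B),((C,D),E)),F);")
#' canonicalNewick(phy)
#' @export
readNewick <- function(text) {
    phy <- tryCatch(ape::read.tree(text = text),
                    error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(phy))
        stop("malformed Newick: ", substr(text, 1L, 60L), call. = FALSE)
    if (anyDuplicated(phy$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                   collapse = ", "), call. = FALSE)
    .canonicalizePhylo(phy)
}

#' Canonical Newick serialization of a topology
#'
#' Children are ordered lexicographically by their smallest leaf label so that
#' identical topologies always serialize to identical strings; branch lengths
#' are omitted. \code{readNewick(canonicalNewick(t))} is the identity on
#' topology structure.
#'
#' @param t a \code{phylo} or [PrunedTopology-class].
#' @return a single Newick string.
#' @export
canonicalNewick <- function(t) {
    if (is(t, "PrunedTopology")) t <- t@tree
    .nestedNewickStr(.canonicalizeNested(.nestedFromPhylo(t)),
                     branchLengths = FALSE)
}

#' Write topologies to a Newick file
#'
#' @param t a \code{phylo}, [PrunedTopology-class], or a list of either.
#' @param file output path; when NULL the strings are returned invisibly.
#' @param branchLengths include branch lengths (only meaningful for trees that
#'   carry them, e.g. simulated phylogenies); canonical child order is applied
#'   either way.
#' @return the Newick strings, invisibly.
#' @export
writeNewick <- function(t, file = NULL, branchLengths = FALSE) {
    if (!is.list(t) || inherits(t, "phylo")) t <- list(t)
    txt <- vapply(t, function(x) {
        if (is(x, "PrunedTopology")) x <- x@tree
        .nestedNewickStr(.canonicalizeNested(.nestedFromPhylo(x)),
                         branchLengths = branchLengths)
    }, character(1L))
    if (!is.null(file)) writeLines(txt, file)
    invisible(txt)
}

#' Topology identity test
#'
#' @param a,b \code{phylo} or [PrunedTopology-class] objects.
#' @return TRUE when the rooted topologies are identical (branch lengths
#'   ignored).
#' @export
topologyEqual <- function(a, b) {
    identical(canonicalNewick(a), canonicalNewick(b))
}

#' Read an orthoset assignment table
#'
#' Two-column TSV (\code{sequence_id}, \code{orthoset}), with or without a
#' header line.
#'
#' @param file path to the TSV.
#' @return named character vector mapping sequence label to orthoset name.
#' @export
readOrthosetMap <- function(file) {
    df <- read.table(file, sep = "\t", header = FALSE,
                     col.names = c("sequence_id", "orthoset"),
                     colClasses = "character")
    if (identical(tolower(df$sequence_id[1L]), "sequence_id")) df <- df[-1L, ]
    if (anyDuplicated(df$sequence_id))
        stop("duplicate sequence ids in orthoset map", call. = FALSE)
    setNames(df$orthoset, df$sequence_id)
}

#' Write an orthoset assignment table
#'
#' @param map named character vector (label -> orthoset).
#' @param file output TSV path.
#' @export
writeOrthosetMap <- function(map, file) {
    write.table(data.frame(sequence_id = names(map), orthoset = unname(map)),
                file, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(file)
}

#' Enumerate all rooted binary topologies over a leaf set
#'
#' Exhaustive enumeration by sequential leaf attachment (every rooted binary
#' topology on n leaves is produced exactly once; there are (2n-3)!! of them).
#' Intended for oracle comparisons and exact small-instance work; n is capped
#' at 8.
#'
#' @param labels leaf labels (2 to 8 of them).
#' @return list of \code{phylo} objects in deterministic order.
#' @export
enumerateTopologies <- function(labels) {
    labels <- as.character(labels)
    n <- length(labels)
    if (n < 2L) stop("need at least 2 labels", call. = FALSE)
    if (n > 8L) stop("enumeration capped at 8 leaves", call. = FALSE)
    start <- list(list(children = list(list(label = labels[1L], len = NA_real_),
                                       list(label = labels[2L], len = NA_real_)),
                       len = NA_real_))
    trees <- start
    if (n == 2L) return(lapply(trees, function(x) .nestedToPhylo(.canonicalizeNested(x))))
    for (k in 3:n) {
        leaf <- list(label = labels[k], len = NA_real_)
        out <- list()
        for (tr in trees) {
            # attach above every node, including a new root above the old one
            out <- c(out, .attachEverywhere(tr, leaf))
        }
        trees <- out
    }
    lapply(trees, function(x) .nestedToPhylo(.canonicalizeNested(x)))
}

# All trees obtained by bisecting the edge above each node of `tree` (the
# root's virtual edge included) with a new parent of `leaf`.
.attachEverywhere <- function(tree, leaf) {
    res <- list(list(children = list(tree, leaf), len = NA_real_))
    if (.isLeaf(tree)) return(res)
    for (i in seq_along(tree$children)) {
        for (sub in .attachEverywhere(tree$children[[i]], leaf)) {
            mod <- tree
            mod$children[[i]] <- sub
            res <- c(res, list(mod))
        }
    }
    res
}
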
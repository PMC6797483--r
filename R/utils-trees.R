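# Internal recursive tree representation used for canonicalization, pruning
# and grafting. A node is a list:
#   leaf:     list(label = <chr>, len = <numeric, NA if absent>)
#   internal: list(children = list(<node>, ...), len = <numeric>,
#                  spurious = <lgl, optional>)
# All user-facing trees are ape "phylo" objects; these helpers are not exported.

.isLeaf <- function(node) !is.null(node$label)

.nestedFromPhylo <- function(phy) {
    ntip <- length(phy$tip.label)
    children <- vector("list", ntip + phy$Nnode)
    for (k in seq_len(nrow(phy$edge))) {
        p <- phy$edge[k, 1L]
        children[[p]] <- c(children[[p]], list(k))
    }
    elen <- phy$edge.length # may be NULL
    build <- function(v, inlen) {
        if (v <= ntip) {
            return(list(label = phy$tip.label[v], len = inlen))
        }
        kids <- lapply(children[[v]], function(k) {
            build(phy$edge[k, 2L],
                  if (is.null(elen)) NA_real_ else elen[k])
        })
        list(children = kids, len = inlen)
    }
    root <- ntip + 1L
    build(root, NA_real_)
}

.minLeaf <- function(node) {
    if (.isLeaf(node)) return(node$label)
    min(vapply(node$children, .minLeaf, character(1L)))
}

# Order children by smallest contained leaf label (radix order, locale
# independent) and resolve any multifurcation by repeatedly joining the first
# two children under a new zero-length node. This is the rooting convention
# applied to basal trifurcations of unrooted inference output.
.canonicalizeNested <- function(node) {
    if (.isLeaf(node)) return(node)
    kids <- lapply(node$children, .canonicalizeNested)
    keys <- vapply(kids, .minLeaf, character(1L))
    kids <- kids[order(keys, method = "radix")]
    while (length(kids) > 2L) {
        joined <- list(children = kids[1:2], len = 0)
        kids <- c(list(joined), kids[-(1:2)])
        keys <- vapply(kids, .minLeaf, character(1L))
        kids <- kids[order(keys, method = "radix")]
    }
    node$children <- kids
    node
}

.nestedNewickStr <- function(node, branchLengths = FALSE) {
    fmt <- function(n) {
        s <- if (.isLeaf(n)) {
            n$label
        } else {
            paste0("(", paste(vapply(n$children, fmt, character(1L)),
                              collapse = ","), ")")
        }
        if (branchLengths && !is.na(n$len)) s <- paste0(s, ":", format(n$len, digits = 10))
        s
    }
    paste0(fmt(node), ";")
}

# Convert nested form to phylo.  Returns the tree; if any internal node
# carries a `spurious` flag, the ids of flagged internal nodes (ape numbering)
# are attached as attribute "spurious".
.nestedToPhylo <- function(node) {
    tips <- character(0L)
    edges <- list()
    lens <- numeric(0L)
    spur <- integer(0L)
    nInternal <- 0L
    countInternal <- function(n) {
        if (.isLeaf(n)) return(invisible(NULL))
        nInternal <<- nInternal + 1L
        lapply(n$children, countInternal)
        invisible(NULL)
    }
    countInternal(node)
    ntipTotal <- 0L
    countTips <- function(n) {
        if (.isLeaf(n)) ntipTotal <<- ntipTotal + 1L
        else lapply(n$children, countTips)
        invisible(NULL)
    }
    countTips(node)
    nextTip <- 0L
    nextInt <- ntipTotal
    walk <- function(n) {
        if (.isLeaf(n)) {
            nextTip <<- nextTip + 1L
            tips[nextTip] <<- n$label
            return(nextTip)
        }
        nextInt <<- nextInt + 1L
        id <- nextInt
        if (isTRUE(n$spurious)) spur[length(spur) + 1L] <<- id
        for (child in n$children) {
            cid <- walk(child)
            edges[[length(edges) + 1L]] <<- c(id, cid)
            lens[length(lens) + 1L] <<- if (is.null(child$len)) NA_real_ else child$len
        }
        id
    }
    walk(node)
    phy <- list(edge = do.call(rbind, edges),
                tip.label = tips,
                Nnode = nInternal)
    if (!all(is.na(lens))) phy$edge.length <- ifelse(is.na(lens), 0, lens)
    class(phy) <- "phylo"
    attr(phy, "order") <- NULL
    if (length(spur)) attr(phy, "spurious") <- spur
    phy
}

# Rooted-binary canonical form of a phylo object (children ordered by smallest
# leaf label, multifurcations resolved deterministically).
.canonicalizePhylo <- function(phy) {
    .nestedToPhylo(.canonicalizeNested(.nestedFromPhylo(phy)))
}

.checkBinaryRooted <- function(phy, what = "topology") {
    ntip <- length(phy$tip.label)
    deg <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
    if (any(deg[(ntip + 1L):(ntip + phy$Nnode)] != 2L))
        stop(what, " must be a rooted binary tree; canonicalize with readNewick()/",
             "canonicalNewick() first", call. = FALSE)
    invisible(TRUE)
}

# Depth (edges from root) of every node, and children list.
.nodeDepths <- function(phy) {
    n <- length(phy$tip.label) + phy$Nnode
    depth <- integer(n)
    # preorder over edges: ape edge matrix is parent->child; process so that
    # parents are seen first
    ord <- order(phy$edge[, 1L])
    # safer: iterative BFS from root
    root <- length(phy$tip.label) + 1L
    kids <- vector("list", n)
    for (k in seq_len(nrow(phy$edge)))
        kids[[phy$edge[k, 1L]]] <- c(kids[[phy$edge[k, 1L]]], phy$edge[k, 2L])
    queue <- root
    depth[root] <- 0L
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in kids[[v]]) {
            depth[w] <- depth[v] + 1L
            queue <- c(queue, w)
        }
    }
    list(depth = depth, children = kids, root = root)
}

# Ancestor chain (internal node ids from parent up to the root) per node.
.ancestorChains <- function(phy) {
    n <- length(phy$tip.label) + phy$Nnode
    parent <- integer(n)
    for (k in seq_len(nrow(phy$edge))) parent[phy$edge[k, 2L]] <- phy$edge[k, 1L]
    root <- length(phy$tip.label) + 1L
    parent[root] <- NA_integer_
    chains <- vector("list", n)
    for (v in seq_len(n)) {
        ch <- integer(0L)
        p <- parent[v]
        while (!is.na(p)) { ch <- c(ch, p); p <- parent[p] }
        chains[[v]] <- ch
    }
    chains
}

# Leaf label sets (as character vectors) under every node.
.cladeSets <- function(phy) {
    ntip <- length(phy$tip.label)
    n <- ntip + phy$Nnode
    sets <- vector("list", n)
    for (v in seq_len(ntip)) sets[[v]] <- phy$tip.label[v]
    # postorder: process edges from deepest; repeat passes until stable
    info <- .nodeDepths(phy)
    ordNodes <- order(info$depth, decreasing = TRUE)
    for (v in ordNodes) {
        if (v <= ntip) next
        sets[[v]] <- sort(unlist(lapply(info$children[[v]], function(w) sets[[w]])),
                          method = "radix")
    }
    sets
}

.pairKey <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}
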
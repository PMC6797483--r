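figTree <- function() readNewick("(((A,B),((C,D),E)),F);")

test_that("path lengths count internal nodes, root included", {
    m <- pathLengthMatrix(figTree())
    expect_equal(m["A", "B"], 1L)
    expect_equal(m["D", "E"], 2L)
    expect_equal(m["E", "F"], 3L) # crosses the root
    expect_equal(m["B", "C"], 4L)
    # every entry agrees with the independent BFS oracle
    expect_equal(m, bfsPathLengths(figTree()))

    expect_equal(unname(pathLengthMatrix(readNewick("(A,B);"))["A", "B"]), 1L)
})

test_that("path matrices match the BFS oracle on random topologies", {
    set.seed(3)
    for (i in 1:25) {
        n <- sample(3:12, 1L)
        t <- randomTopo(paste0("L", seq_len(n)))
        m <- pathLengthMatrix(t)
        expect_equal(m, bfsPathLengths(t)[rownames(m), colnames(m)])
        expect_true(all(m[upper.tri(m)] >= 1L))
        expect_true(all(m[upper.tri(m)] <= 2L * n - 3L))
        expect_identical(m, t(m))
    }
})

test_that("topologyFromMatrix inverts pathLengthMatrix", {
    t <- figTree()
    expect_identical(canonicalNewick(topologyFromMatrix(pathLengthMatrix(t))),
                     "(((A,B),((C,D),E)),F);")
    set.seed(4)
    for (i in 1:60) {
        n <- sample(3:12, 1L)
        t <- randomTopo(paste0("L", seq_len(n)))
        back <- topologyFromMatrix(pathLengthMatrix(t))
        expect_true(topologyEqual(t, back))
    }
})

test_that("unrealizable matrices raise errors naming an entry", {
    m <- matrix(1L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    diag(m) <- 0L
    expect_error(topologyFromMatrix(m), "unrealizable.*\\(A,C,1\\)")
    m2 <- pathLengthMatrix(figTree())
    m2["A", "B"] <- m2["B", "A"] <- 5L
    expect_error(topologyFromMatrix(m2), "unrealizable")
})

test_that("topologies are identical iff their path matrices are equal", {
    # injectivity over exhaustive enumerations up to 6 leaves
    for (n in 4:6) {
        en <- enumWithPaths(n)
        keys <- apply(en$pl, 1L, paste, collapse = ",")
        expect_equal(anyDuplicated(keys), 0L)
        expect_equal(anyDuplicated(en$newick), 0L)
    }
})

test_that("path matrix TSV round-trips", {
    m <- pathLengthMatrix(figTree())
    f <- tempfile(fileext = ".tsv")
    writePathMatrix(m, f)
    expect_identical(readPathMatrix(f), m)
})

test_that("aggregation counts per-pair lengths with valid totals", {
    one <- asPrunedTopology(figTree())
    d <- aggregateEnsemble(rep(list(one), 10L))
    ent <- sortedEntries(d)
    expect_equal(nrow(ent), 15L) # n(n-1)/2 records, one length per pair
    expect_true(all(ent$frequency == 1))
    expect_true(all(d@valid == 10L))

    ens <- c(rep(list(asPrunedTopology("((A,B),C);")), 8),
             rep(list(asPrunedTopology("(A,(B,C));")), 2))
    d2 <- aggregateEnsemble(ens)
    ent2 <- sortedEntries(d2)
    ab1 <- ent2[ent2$leaf1 == "A" & ent2$leaf2 == "B", ]
    expect_equal(ab1$frequency[ab1$length == 1L], 0.8)
    expect_equal(ab1$frequency[ab1$length == 2L], 0.2)
    # per-pair frequencies sum to 1 wherever valid totals are positive
    sums <- tapply(ent2$frequency, paste(ent2$leaf1, ent2$leaf2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))

    expect_error(aggregateEnsemble(list()), "empty")
})

test_that("compromised paths are excluded member-wise", {
    good <- asPrunedTopology("((A,B),C);", c("A", "B", "C"))
    # member with B non-monophyletic: spurious MRCA subtree is the whole tree
    src <- readNewick("(((a1,a2),b1),(b2,(c1,c2)));")
    bad <- pruneToAncestors(src, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                                   c1 = "C", c2 = "C"),
                            universe = c("A", "B", "C"))
    d <- aggregateEnsemble(list(good, good, bad))
    # pairs with B: missing-leaf exclusion; pair (A,C): spurious-path exclusion
    expect_equal(unname(d@valid[rownames(d@counts) == "A|C"]), 2)
    expect_equal(unname(d@valid[rownames(d@counts) == "A|B"]), 2)
    expect_equal(d@ensembleSize, 3L)
})

test_that("uncompromised paths of a flawed member still contribute", {
    # D non-monophyletic but confined to one side: the (A,B) cherry survives
    src <- readNewick("(((a1,a2),(b1,b2)),((d1,(c1,c2)),(d2,e1)));")
    m <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C",
           d1 = "D", d2 = "D", e1 = "E")
    bad <- pruneToAncestors(src, m, universe = c("A", "B", "C", "D", "E"))
    expect_identical(missingAncestors(bad), "D")
    full <- asPrunedTopology("((A,B),((C,D),E));")
    d <- aggregateEnsemble(list(full, bad))
    expect_equal(unname(d@valid[rownames(d@counts) == "A|B"]), 2) # kept
    expect_equal(unname(d@valid[rownames(d@counts) == "C|E"]), 1) # spurious side
    expect_equal(unname(d@valid[rownames(d@counts) == "A|D"]), 1) # missing leaf
})

test_that("sorted entries are length-major and member-order invariant", {
    set.seed(9)
    ens <- perturbedEnsemble(randomTopo(LETTERS[1:6]), 15, 2, seed = 5)
    d <- aggregateEnsemble(ens)
    ent <- sortedEntries(d)
    expect_true(!is.unsorted(ent$length))
    byLen <- split(ent$frequency, ent$length)
    for (v in byLen) expect_true(all(diff(v) <= 1e-12))
    # permutation of the ensemble yields the same record multiset
    ent2 <- sortedEntries(aggregateEnsemble(rev(ens)))
    expect_equal(ent[order(ent$leaf1, ent$leaf2, ent$length), ],
                 ent2[order(ent2$leaf1, ent2$leaf2, ent2$length), ],
                 ignore_attr = TRUE)
})

test_that("subsetDistribution restricts pairs without rescaling", {
    ens <- perturbedEnsemble("((((A,B),C),D),E);", 10, 1, seed = 2)
    d <- aggregateEnsemble(ens)
    d3 <- subsetDistribution(d, c("A", "C", "E"))
    expect_identical(d3@universe, c("A", "C", "E"))
    expect_equal(nrow(d3@pairs), 3L)
    full <- sortedEntries(d); sub <- sortedEntries(d3)
    ac <- full[full$leaf1 == "A" & full$leaf2 == "C", c("length", "count")]
    ac2 <- sub[sub$leaf1 == "A" & sub$leaf2 == "C", c("length", "count")]
    expect_equal(ac, ac2, ignore_attr = TRUE)
})
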
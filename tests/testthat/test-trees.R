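test_that("readNewick parses, canonicalizes and round-trips", {
    phy <- readNewick("(((A,B),((C,D),E)),F);")
    expect_s3_class(phy, "phylo")
    expect_equal(length(phy$tip.label), 6L)
    expect_equal(phy$Nnode, 5L) # n leaves -> n-1 internal nodes
    expect_identical(canonicalNewick(phy), "(((A,B),((C,D),E)),F);")

    two <- readNewick("(A,B);")
    expect_equal(two$Nnode, 1L)

    # identical topologies serialize identically whatever the input order
    perms <- c("(F,(((D,C),E),(B,A)));", "((((C,D),E),(A,B)),F);",
               "(((B,A),(E,(D,C))),F);")
    for (p in perms)
        expect_identical(canonicalNewick(readNewick(p)),
                         "(((A,B),((C,D),E)),F);")

    expect_error(readNewick("((A,B"), "malformed")
    expect_error(readNewick("((A,A),B);"), "duplicate")
})

test_that("basal trifurcations resolve deterministically and round-trip", {
    t1 <- readNewick("(A,B,C);")
    expect_equal(t1$Nnode, 2L)
    expect_identical(canonicalNewick(t1), "((A,B),C);")
    # same resolution regardless of child order in the text
    expect_identical(canonicalNewick(readNewick("(C,B,A);")),
                     "((A,B),C);")
    # resolved tree is binary and stable under re-serialization
    expect_identical(canonicalNewick(readNewick(canonicalNewick(t1))),
                     canonicalNewick(t1))
})

test_that("pruneToAncestors collapses monophyletic orthosets", {
    p <- pruneToAncestors(readNewick("((a1,a2),(b1,b2));"),
                          c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
    expect_identical(canonicalNewick(p), "(A,B);")
    expect_length(missingAncestors(p), 0L)
    expect_true(all(monophylyReport(p)$monophyletic))

    # singleton orthosets count as trivially monophyletic
    p1 <- pruneToAncestors(readNewick("((a1,a2),(b1,c1));"),
                           c(a1 = "A", a2 = "A", b1 = "B", c1 = "C"))
    expect_setequal(ancestorLeaves(p1), c("A", "B", "C"))
})

test_that("non-monophyletic orthosets are dropped and flagged spurious", {
    t <- readNewick("(((a1,a2),b1),(b2,(c1,c2)));")
    m <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
    p <- pruneToAncestors(t, m)
    expect_setequal(ancestorLeaves(p), c("A", "C"))
    expect_identical(missingAncestors(p), "B")
    rep <- monophylyReport(p)
    expect_false(rep$monophyletic[rep$orthoset == "B"])
    # B's MRCA is the root, so the surviving internal node is spurious
    expect_length(spuriousNodes(p), 1L)

    # fully interleaved: nothing monophyletic
    expect_error(pruneToAncestors(readNewick("((a1,b1),(a2,b2));"),
                                  c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")),
                 class = "unprunableError")

    expect_error(pruneToAncestors(t, m[-1L]), "missing from the orthoset map")
})

test_that("pruning is invariant to the leaf order of the input text", {
    m <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
    texts <- c("(((a1,a2),(b1,b2)),(c1,c2));",
               "((c2,c1),((b2,b1),(a2,a1)));",
               "(((b1,b2),(a1,a2)),(c2,c1));")
    outs <- vapply(texts, function(x)
        canonicalNewick(pruneToAncestors(readNewick(x), m)), character(1L))
    expect_length(unique(outs), 1L)
})

test_that("rfStar is zero on identity and symmetric", {
    set.seed(42)
    for (i in 1:40) {
        n <- sample(4:12, 1L)
        labs <- paste0("O", seq_len(n))
        a <- asPrunedTopology(randomTopo(labs), labs)
        b <- asPrunedTopology(randomTopo(labs), labs)
        expect_equal(rfStar(a, a)@distance, 0)
        expect_equal(rfStar(a, b)@distance, rfStar(b, a)@distance)
        expect_gte(topologyAccuracy(a, b), 0)
        expect_lte(topologyAccuracy(a, b), 1)
    }
    u3 <- c("A", "B", "C")
    expect_error(rfStar(asPrunedTopology("((A,B),C);", u3),
                        asPrunedTopology("((A,C),B);", u3)),
                 "at least 4")
})

test_that("classic rfStar equals independent split-cut and phangorn oracles", {
    set.seed(7)
    for (i in 1:30) {
        n <- sample(4:8, 1L)
        labs <- LETTERS[seq_len(n)]
        a <- randomTopo(labs)
        b <- randomTopo(labs)
        r <- rfStar(asPrunedTopology(a, labs), asPrunedTopology(b, labs))
        sa <- cutSplits(a); sb <- cutSplits(b)
        expect_equal(r@x, length(setdiff(sa, sb)))
        expect_equal(r@y, length(setdiff(sb, sa)))
        expect_equal(r@distance, (r@x + r@y) / (2 * n - 6))
        expect_true(r@classic)
        # independent library oracle on the same pair
        expect_equal(r@x + r@y,
                     as.integer(phangorn::RF.dist(ape::unroot(a),
                                                  ape::unroot(b))))
    }
})

test_that("missing ancestor leaves enter through the z terms", {
    u <- LETTERS[1:5]
    full <- asPrunedTopology("(((A,B),C),(D,E));", u)
    # same topology with A lost to non-monophyly
    part <- new("PrunedTopology", tree = readNewick("((B,C),(D,E));"),
                universe = u, missing = "A", spurious = integer(0L),
                monophyly = data.frame(orthoset = u,
                                       monophyletic = u != "A",
                                       nLeaves = 2L))
    r <- rfStar(part, full)
    expect_equal(r@z, 1L)        # missing from the first but not the second
    expect_equal(r@zprime, 0L)
    expect_false(r@classic)
    # restricted to {B,C,D,E} both reduce to ((B,C),(D,E)): x = y = 0
    expect_equal(r@x + r@y, 0L)
    expect_equal(r@distance, 1 / (2 * 5 - 6))
    # symmetric counterpart swaps z and z'
    r2 <- rfStar(full, part)
    expect_equal(r2@zprime, 1L)
    expect_equal(r2@distance, r@distance)
})

test_that("accuracy is 1 on identity, 0 at maximal distance", {
    en <- enumWithPaths(6)
    ref <- asPrunedTopology(en$trees[[1L]])
    expect_equal(topologyAccuracy(ref, ref), 1)
    # exhaustive search for a pair sharing no splits
    dists <- vapply(en$trees, function(t)
        rfStar(ref, asPrunedTopology(t))@distance, numeric(1L))
    expect_equal(max(dists), 1)
    worst <- asPrunedTopology(en$trees[[which.max(dists)]])
    expect_equal(topologyAccuracy(ref, worst), 0)
})

test_that("one NNI on 15 ancestors costs 2/24 accuracy", {
    labs <- sprintf("O%02d", 1:15)
    cat1 <- paste0(paste(rep("(", 14), collapse = ""), labs[1L], ",", labs[2L],
                   ")", paste(paste0(",", labs[3:15], ")"), collapse = ""), ";")
    t1 <- readNewick(cat1)
    # exchange O01's sibling O02 with the cherry's aunt O03: one split changes
    cat2 <- sub("O01,O02),O03", "O01,O03),O02", cat1, fixed = TRUE)
    t2 <- readNewick(cat2)
    a <- topologyAccuracy(asPrunedTopology(t1), asPrunedTopology(t2))
    expect_equal(a, 1 - 2 / (2 * 15 - 6))
})

test_that("precision averages RF* over the ensemble", {
    labs <- LETTERS[1:8]
    ref <- asPrunedTopology("(((((((A,B),C),D),E),F),G),H);", labs)
    expect_equal(topologyPrecision(ref, rep(list(ref), 10L)), 1)
    expect_error(topologyPrecision(ref, list()), "non-empty")
    # members at distance 0.2 and 0.4 (denominator 2*8-6 = 10): one and two
    # independent NNI exchanges on the caterpillar
    d1 <- asPrunedTopology("(((((((A,C),B),D),E),F),G),H);", labs)
    d2 <- asPrunedTopology("(((((((A,C),B),E),D),F),G),H);", labs)
    expect_equal(rfStar(ref, d1)@distance, 0.2)
    expect_equal(rfStar(ref, d2)@distance, 0.4)
    expect_equal(topologyPrecision(ref, list(d1, d2)), 1 - mean(c(0.2, 0.4)))
})
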
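test_that("branch extensions realize exactly the permitted joins", {
    # two singletons with an observed cherry
    d <- aggregateEnsemble(rep(list(asPrunedTopology("(A,B);")), 4L))
    a <- newAssembly(d)
    ext <- branchExtensions(a, d)
    expect_length(ext, 1L)
    expect_identical(ext[[1L]]@subtrees[[1L]]$str, "(A,B)")
    expect_equal(ext[[1L]]@score, 0)

    # joining (C,D) with E completes D<->E and C<->E at length 2
    ens <- rep(list(asPrunedTopology("((C,D),E);")), 5L)
    d2 <- aggregateEnsemble(ens)
    a2 <- newAssembly(d2)
    cherry <- Filter(function(x) any(vapply(x@subtrees, function(s)
        identical(s$str, "(C,D)"), logical(1L))), branchExtensions(a2, d2))
    expect_length(cherry, 1L)
    ext2 <- branchExtensions(cherry[[1L]], d2)
    expect_length(ext2, 1L) # only ((C,D),E): other joins imply unobserved lengths
    expect_identical(ext2[[1L]]@subtrees[[1L]]$str, "((C,D),E)")
})

test_that("joins implying unobserved cross-pair lengths are never generated", {
    set.seed(14)
    for (i in 1:8) {
        ens <- perturbedEnsemble(randomTopo(LETTERS[1:4]), 8, 1, seed = 40 + i)
        d <- aggregateEnsemble(ens)
        ent <- sortedEntries(d)
        observed <- paste(ent$leaf1, ent$leaf2, ent$length)
        a <- newAssembly(d)
        for (x in branchExtensions(a, d)) {
            st <- entryStatuses(x, d)
            done <- st[st$status == "completed", ]
            expect_true(all(paste(done$leaf1, done$leaf2, done$length)
                            %in% observed))
        }
        # brute force: every unordered singleton pair is proposed iff its
        # cherry length (1) was observed
        exp_joins <- sum(ent$length == 1L)
        expect_length(branchExtensions(a, d), exp_joins)
    }
})

test_that("a single-topology ensemble reconstructs itself with score zero", {
    t <- "(((A,B),((C,D),E)),F);"
    d <- aggregateEnsemble(rep(list(asPrunedTopology(t)), 7L))
    r <- reconstructNBest(d, 1L)
    expect_true(isComplete(r))
    expect_identical(r@newick, t)
    expect_equal(topologyScores(r), 0)
})

test_that("the 80/20 three-leaf ranking matches exhaustive scoring", {
    d <- aggregateEnsemble(c(rep(list(asPrunedTopology("((A,B),C);")), 8),
                             rep(list(asPrunedTopology("(A,(B,C));")), 2)))
    r <- reconstructNBest(d, 3L)
    # ((A,C),B) is not constructible: (A,C) was never observed at length 1
    expect_identical(r@newick, c("((A,B),C);", "(A,(B,C));"))
    expect_equal(topologyScores(r),
                 c(log(.8) + log(1) + log(.8), log(.2) + log(1) + log(.2)))
})

test_that("reconstruction equals the exhaustive oracle on random ensembles", {
    set.seed(2024)
    for (i in 1:12) {
        n <- sample(5:6, 1L)
        ens <- if (i %% 2 == 0L) {
            lapply(1:8, function(j) asPrunedTopology(randomTopo(LETTERS[1:n])))
        } else {
            perturbedEnsemble(randomTopo(LETTERS[1:n]), 12, 2)
        }
        d <- aggregateEnsemble(ens)
        rr <- reconstructNBest(d, 10L)
        expect_true(isComplete(rr))
        expectMatchesOracle(rr, oracleTopN(d, 10L))
    }
})

test_that("identical inputs give identical ranked output across runs", {
    ens <- perturbedEnsemble("((((A,B),C),(D,E)),F);", 15, 2, seed = 77)
    d <- aggregateEnsemble(ens)
    r1 <- reconstructNBest(d, 8L)
    r2 <- reconstructNBest(d, 8L)
    expect_identical(r1@newick, r2@newick)
    expect_identical(r1@scores, r2@scores)
    expect_identical(r1@stats, r2@stats)
})

test_that("every ensemble member scores no better than the top topology", {
    set.seed(31)
    for (i in 1:5) {
        ens <- perturbedEnsemble(randomTopo(LETTERS[1:6]), 10, 2, seed = 300 + i)
        d <- aggregateEnsemble(ens)
        top <- reconstructNBest(d, 1L)@scores[1L]
        for (m in ens)
            expect_lte(scoreValue(logFrequencyScore(m, d)), top + 1e-9)
    }
})

test_that("budget truncation returns a prefix-consistent subset", {
    ens <- perturbedEnsemble(randomTopo(LETTERS[1:6]), 15, 2, seed = 55)
    d <- aggregateEnsemble(ens)
    full <- reconstructNBest(d, 10L)
    trunc <- reconstructNBest(d, 10L, budget = 30L)
    expect_false(isComplete(trunc))
    expect_true(all(trunc@newick %in% full@newick) ||
                length(trunc@newick) == 0L)
    if (length(trunc@newick))
        expect_identical(match(trunc@newick, full@newick),
                         sort(match(trunc@newick, full@newick)))
    expect_error(reconstructNBest(d, 0L), ">= 1")
})

test_that("clade frequencies count recapitulated ancestral nodes", {
    t <- readNewick("((A,B),(C,D));")
    cf <- cladeFrequencies(rep(list(t), 4L))
    expect_true(all(cf$frequency == 1))

    # cherry (A,B) in 3 of 4 topologies
    tops <- lapply(c("((A,B),(C,D));", "(((A,B),C),D);", "(((A,B),D),C);",
                     "(((A,C),B),D);"), readNewick)
    cf2 <- cladeFrequencies(tops)
    expect_equal(cf2$frequency[cf2$clade == "A,B"], 0.75)
    expect_equal(cf2$frequency[cf2$clade == "A,B,C,D"], 1)

    expect_error(cladeFrequencies(list(t, readNewick("((A,B),(C,E));"))),
                 "mixed leaf universes")
    ann <- cladeAnnotatedNewick(t, cf2)
    expect_match(ann, "0.75")
})

test_that("distributions with uncovered pairs are rejected", {
    good <- asPrunedTopology("((A,B),C);", c("A", "B", "C"))
    src <- readNewick("(((a1,a2),b1),(b2,(c1,c2)));")
    bad <- pruneToAncestors(src, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                                   c1 = "C", c2 = "C"),
                            universe = c("A", "B", "C"))
    d <- aggregateEnsemble(list(bad)) # all pairs compromised or missing
    expect_error(reconstructNBest(d, 1L), "no valid observations")
})
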
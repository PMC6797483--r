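test_that("random paralog topologies have the right shape and seed contract", {
    t <- randomParalogTopology(15, 0.7, seed = 3)
    expect_length(t$tip.label, 15L)
    expect_equal(t$Nnode, 14L)
    expect_length(t$edge.length, 28L)
    expect_identical(ape::write.tree(randomParalogTopology(8, 0.5, seed = 9)),
                     ape::write.tree(randomParalogTopology(8, 0.5, seed = 9)))
    expect_false(identical(
        ape::write.tree(randomParalogTopology(8, 0.5, seed = 1)),
        ape::write.tree(randomParalogTopology(8, 0.5, seed = 2))))
    expect_error(randomParalogTopology(1), "at least 2")
})

test_that("branch lengths are exponential with the requested mean", {
    set.seed(17)
    # 10^4 draws: 360 trees x 28 edges
    bl <- unlist(lapply(1:360, function(i)
        randomParalogTopology(15, 0.7)$edge.length))
    se <- sd(bl) / sqrt(length(bl))
    expect_lt(abs(mean(bl) - 0.7), 3 * se)
})

test_that("grafting replaces every paralog leaf by a species copy", {
    pt <- randomParalogTopology(15, 0.7, seed = 5)
    sp <- speciesTree(66, seed = 6)
    g <- graftSpeciesTree(pt, sp, simulationParams(), seed = 7)
    expect_length(g$tree$tip.label, 990L) # 15 paralogs x 66 species
    expect_equal(length(g$orthosets), 990L)
    expect_equal(length(unique(unname(g$orthosets))), 15L)

    # pruning the grafted phylogeny recovers the paralog topology exactly
    p <- pruneToAncestors(g$tree, g$orthosets)
    expect_true(topologyEqual(prunedTree(p), pt))
    expect_true(all(monophylyReport(p)$monophyletic))

    # heterotachy: per-paralog species copies end up with different heights
    dm <- ape::node.depth.edgelength(g$tree)
    tipd <- dm[seq_along(g$tree$tip.label)]
    perOrtho <- tapply(tipd, unname(g$orthosets[g$tree$tip.label]), mean)
    expect_gt(diff(range(perOrtho)), 0)
})

test_that("sequence evolution is seeded and collapses at zero branch length", {
    tr <- randomParalogTopology(5, 0.5, seed = 2)
    p <- simulationParams(seqLength = 120L, seed = 4L)
    s1 <- evolveSequences(tr, p, seed = 8)
    s2 <- evolveSequences(tr, p, seed = 8)
    expect_identical(as.character(s1), as.character(s2))
    expect_equal(unique(Biostrings::width(s1)), 120L)

    tr0 <- tr
    tr0$edge.length <- rep(1e-12, length(tr0$edge.length))
    s0 <- evolveSequences(tr0, p, seed = 8)
    expect_length(unique(as.character(s0)), 1L)
})

test_that("pairwise divergence grows with path length in expectation", {
    set.seed(12)
    tr <- randomParalogTopology(8, 0.25, seed = 13)
    p <- simulationParams(seqLength = 400L)
    s <- evolveSequences(tr, p, seed = 14)
    pd <- as.matrix(ape::dist.gene(as.matrix(s), method = "percentage"))
    td <- ape::cophenetic.phylo(tr)[rownames(pd), colnames(pd)]
    ut <- upper.tri(pd)
    expect_gt(cor(pd[ut], td[ut], method = "spearman"), 0.5)
})

test_that("simulated families are reproducible end to end", {
    p <- simulationParams(nParalogs = 4L, nSpecies = 4L, seqLength = 60L,
                          seed = 77L)
    f1 <- simulateFamily(p)
    f2 <- simulateFamily(p)
    expect_identical(as.character(f1@sequences), as.character(f2@sequences))
    expect_true(topologyEqual(f1@trueTopology, f2@trueTopology))
    expect_true(all(names(f1@sequences) %in% names(f1@orthosets)))
})

test_that("NNI perturbation intensity degrades precision monotonically", {
    truth <- "(((A,B),(C,D)),(E,F));"
    ens0 <- perturbedEnsemble(truth, 20, 0, seed = 5)
    expect_true(all(vapply(ens0, function(x)
        topologyEqual(prunedTree(x), readNewick(truth)), logical(1L))))
    d0 <- aggregateEnsemble(ens0)
    expect_equal(scoreValue(logFrequencyScore(truth, d0)), 0)
    tp <- asPrunedTopology(truth)
    expect_equal(topologyPrecision(tp, ens0), 1)

    # mild noise: the truth is still the top-scoring reconstruction
    ens1 <- perturbedEnsemble(truth, 100, 1, seed = 6)
    r <- reconstructNBest(aggregateEnsemble(ens1), 1L)
    expect_identical(r@newick[1L], canonicalNewick(readNewick(truth)))

    # precision trend over intensity (Monte-Carlo, fixed seeds)
    prec <- vapply(c(0L, 1L, 3L, 6L), function(k)
        topologyPrecision(tp, perturbedEnsemble(truth, 40, k, seed = 50 + k)),
        numeric(1L))
    expect_equal(prec[1L], 1)
    expect_lt(prec[4L], 1)
    expect_lt(cor(c(0, 1, 3, 6), prec), 0)
})
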
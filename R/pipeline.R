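#' Construct a family dataset
#'
#' @param sequences an \code{AAStringSet} (or named character vector) of
#'   protein sequences.
#' @param orthosets named character vector mapping every sequence label to an
#'   orthoset name, or a path to a two-column TSV (see [readOrthosetMap()]).
#' @param trueTopology optional true paralog topology (\code{phylo} or
#'   Newick string) for benchmarking.
#' @param trueTree optional true full phylogeny.
#' @return a [FamilyDataset-class].
#' @export
familyDataset <- function(sequences, orthosets, trueTopology = NULL,
                          trueTree = NULL) {
    if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
    if (is.character(orthosets) && length(orthosets) == 1L &&
        file.exists(orthosets))
        orthosets <- readOrthosetMap(orthosets)
    if (is.character(trueTopology)) trueTopology <- readNewick(trueTopology)
    new("FamilyDataset", sequences = sequences, orthosets = orthosets,
        trueTopology = trueTopology, trueTree = trueTree)
}

#' Construct a subsampling design
#'
#' @param fraction per-orthoset fraction in (0, 1]; the sampled count is
#'   \code{ceiling(fraction * n)} so at least one sequence per orthoset is
#'   always kept. Mutually exclusive with \code{count}.
#' @param count fixed per-orthoset count.
#' @param replicates number of independent subsamples.
#' @param seed RNG seed.
#' @return a [SubsampleSpec-class].
#' @examples
#' subsampleSpec(fraction = 0.9, replicates = 50, seed = 1)  # precision design
#' subsampleSpec(count = 30, replicates = 1000, seed = 1)    # ensemble design
#' @export
subsampleSpec <- function(fraction = NA_real_, count = NA_integer_,
                          replicates = 1L, seed = 1L) {
    new("SubsampleSpec", fraction = as.numeric(fraction),
        count = as.integer(count), replicates = as.integer(replicates),
        seed = as.integer(seed))
}

#' Subsample sequences from every orthoset
#'
#' Draws \code{replicates} independent subsets; within each, every orthoset
#' contributes exactly its target count (ceiling(fraction * n) or the fixed
#' count), sampled without replacement. Fully reproducible from the design
#' seed.
#'
#' @param f a [FamilyDataset-class].
#' @param s a [SubsampleSpec-class].
#' @return list of character vectors of sequence labels, one per replicate.
#' @export
setMethod("subsampleFamily", signature("FamilyDataset", "SubsampleSpec"),
          function(f, s) {
    labs <- names(f@sequences)
    byOrtho <- split(labs, unname(f@orthosets[labs]))
    target <- vapply(byOrtho, function(x) {
        n <- length(x)
        k <- if (is.na(s@fraction)) {
            s@count
        } else {
            # ceiling keeps >= 1 sequence for tiny orthosets; the cap at n-1
            # guarantees that a fractional subsample actually drops something
            # (a jackknife with all sequences carries no resampling noise)
            k0 <- as.integer(ceiling(s@fraction * n))
            if (s@fraction < 1) max(1L, min(n - 1L, k0)) else k0
        }
        if (k > n)
            stop("target count ", k, " exceeds orthoset size ", n,
                 call. = FALSE)
        k
    }, integer(1L))
    set.seed(s@seed)
    lapply(seq_len(s@replicates), function(r) {
        unlist(lapply(names(byOrtho), function(o)
            sample(byOrtho[[o]], target[o])), use.names = FALSE)
    })
})

#' Built-in distance-based inference adapter
#'
#' Neighbor-joining on uncorrected p-distances of the (already homologous,
#' gap-free) sequences. Model-free by design -- deliberately unrelated to the
#' empirical model used to simulate sequences -- and fast enough to run
#' hundreds of replicates per family without external tools.
#'
#' @return an [InferenceAdapter-class].
#' @export
builtinAdapter <- function() {
    new("InferenceAdapter", name = "nj-pdistance",
        infer = function(seqs) {
            m <- as.matrix(seqs)
            d <- ape::dist.gene(m, method = "percentage")
            phy <- ape::nj(d)
            # midpoint rooting: deterministic, and does not break clades that
            # are connected in the unrooted tree (an arbitrary basal
            # resolution can root inside an orthoset)
            .canonicalizePhylo(phangorn::midpoint(phy))
        })
}

#' External align-then-infer command adapter
#'
#' Wraps any shell pipeline that reads a FASTA file and writes a Newick file.
#' The template must contain the placeholders \code{{input}} and
#' \code{{output}}, e.g.
#' \code{"mafft --auto {input} > {input}.aln && fasttree -wag {input}.aln > {output}"}.
#'
#' @param template shell command template.
#' @param name adapter label for reports.
#' @return an [InferenceAdapter-class].
#' @export
commandAdapter <- function(template, name = "command") {
    force(template)
    new("InferenceAdapter", name = name,
        infer = function(seqs) {
            dir <- tempfile("adapter")
            dir.create(dir)
            on.exit(unlink(dir, recursive = TRUE), add = TRUE)
            fin <- file.path(dir, "input.fasta")
            fout <- file.path(dir, "output.nwk")
            Biostrings::writeXStringSet(seqs, fin)
            cmd <- gsub("{output}", fout, gsub("{input}", fin, template,
                                               fixed = TRUE), fixed = TRUE)
            status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
            if (status != 0L || !file.exists(fout))
                stop("adapter command failed (exit ", status, "): ", cmd,
                     call. = FALSE)
            phy <- ape::read.tree(fout)
            if (!setequal(phy$tip.label, names(seqs)))
                stop("adapter output leaves do not match the input labels",
                     call. = FALSE)
            if (!is.null(phy$edge.length)) phy <- phangorn::midpoint(phy)
            .canonicalizePhylo(phy)
        })
}

#' Build an ensemble of pruned subsampled topologies
#'
#' For every subsample replicate: run the inference adapter, canonicalize the
#' returned tree, and prune it to orthoset ancestors. Replicates in which
#' fewer than two orthosets are monophyletic are skipped (recorded in the
#' \code{skipped} attribute). The per-orthoset monophyly rate across
#' replicates is attached as the \code{monophylyRates} attribute; orthosets
#' falling below \code{monoThreshold} trigger a warning, since an ancestor
#' that is not consistently recovered as monophyletic cannot be considered
#' robustly inferred.
#'
#' @param f a [FamilyDataset-class].
#' @param s a [SubsampleSpec-class].
#' @param adapter an [InferenceAdapter-class].
#' @param monoThreshold minimum acceptable monophyly rate (default 0.95).
#' @param universe orthoset universe; defaults to all orthosets of \code{f}.
#' @return list of [PrunedTopology-class] with attributes
#'   \code{monophylyRates} and \code{skipped}.
#' @export
setMethod("buildEnsemble",
          signature("FamilyDataset", "SubsampleSpec", "InferenceAdapter"),
          function(f, s, adapter, monoThreshold = 0.95, universe = NULL) {
    if (is.null(universe))
        universe <- sort(unique(unname(f@orthosets[names(f@sequences)])),
                         method = "radix")
    subsets <- subsampleFamily(f, s)
    ensemble <- list()
    skipped <- integer(0L)
    monoNum <- setNames(numeric(length(universe)), universe)
    monoDen <- setNames(numeric(length(universe)), universe)
    for (r in seq_along(subsets)) {
        seqs <- f@sequences[subsets[[r]]]
        phy <- tryCatch(adapter@infer(seqs), error = function(e)
            stop("inference failed on replicate ", r, ": ",
                 conditionMessage(e), call. = FALSE))
        pt <- tryCatch(pruneToAncestors(phy, f@orthosets, universe = universe),
                       unprunableError = function(e) NULL)
        if (is.null(pt)) {
            # still record monophyly on the raw tree
            skipped <- c(skipped, r)
            rep <- tryCatch(.monophylyOnly(phy, f@orthosets), error = function(e) NULL)
        } else {
            ensemble[[length(ensemble) + 1L]] <- pt
            rep <- pt@monophyly
        }
        if (!is.null(rep)) {
            monoDen[rep$orthoset] <- monoDen[rep$orthoset] + 1
            monoNum[rep$orthoset] <- monoNum[rep$orthoset] + rep$monophyletic
        }
    }
    rates <- ifelse(monoDen > 0, monoNum / monoDen, NA_real_)
    low <- names(rates)[!is.na(rates) & rates < monoThreshold]
    if (length(low))
        warning("orthosets monophyletic in fewer than ",
                round(100 * monoThreshold), "% of replicates: ",
                paste(low, collapse = ", "), call. = FALSE)
    attr(ensemble, "monophylyRates") <- rates
    attr(ensemble, "skipped") <- skipped
    ensemble
})

# monophyly report without requiring a prunable tree
.monophylyOnly <- function(phy, m) {
    tips <- phy$tip.label
    map <- m[tips]
    sampled <- sort(unique(unname(map)), method = "radix")
    sets <- .cladeSets(phy)
    setKeys <- vapply(sets, paste, character(1L), collapse = "\r")
    osLeaves <- split(tips, unname(map))
    mono <- vapply(sampled, function(os) {
        paste(sort(osLeaves[[os]], method = "radix"), collapse = "\r") %in% setKeys
    }, logical(1L))
    data.frame(orthoset = sampled, monophyletic = unname(mono),
               nLeaves = lengths(osLeaves)[sampled], row.names = NULL)
}

#' Run the full ensemble reconstruction pipeline
#'
#' (1) infer and prune the all-sequence topology; (2) measure its precision
#' against a high-fraction subsample ensemble; (3) aggregate a larger,
#' sparser subsample ensemble into path-length frequency distributions;
#' (4) enumerate the N best-scoring topologies by branch-and-bound;
#' (5) annotate the result set with clade frequencies; (6) when the true
#' topology is known, report the accuracy of the all-sequence topology and of
#' every reconstructed topology.
#'
#' @param f a [FamilyDataset-class].
#' @param precisionSpec [SubsampleSpec-class] for the precision ensemble
#'   (classically ~90 percent, tens of replicates).
#' @param ensembleSpec [SubsampleSpec-class] for the reconstruction ensemble
#'   (classically ~50 percent, hundreds to thousands of replicates).
#' @param adapter an [InferenceAdapter-class].
#' @param nBest topologies to reconstruct.
#' @param budget optional assembly budget for [reconstructNBest()].
#' @param monoThreshold monophyly warning threshold.
#' @param outDir optional directory; when given, trees (Newick) and a JSON
#'   report are written there.
#' @return a list: \code{allSequence} (PrunedTopology), \code{precision},
#'   \code{distribution}, \code{reconstruction} (ReconstructionResult),
#'   \code{cladeFrequencies}, \code{monophylyRates}, and -- when the truth is
#'   known -- \code{accuracyAllSequence} and \code{accuracyTopologies}.
#' @export
runPipeline <- function(f, precisionSpec, ensembleSpec, adapter,
                        nBest = 50L, budget = Inf, monoThreshold = 0.95,
                        outDir = NULL) {
    universe <- sort(unique(unname(f@orthosets[names(f@sequences)])),
                     method = "radix")
    allTree <- adapter@infer(f@sequences)
    allPruned <- pruneToAncestors(allTree, f@orthosets, universe = universe)

    precEns <- buildEnsemble(f, precisionSpec, adapter,
                             monoThreshold = monoThreshold,
                             universe = universe)
    precision <- topologyPrecision(allPruned, precEns)

    reconEns <- buildEnsemble(f, ensembleSpec, adapter,
                              monoThreshold = monoThreshold,
                              universe = universe)
    d <- aggregateEnsemble(reconEns)
    # ancestors with pairs never validly observed are not high-confidence and
    # cannot be placed by the search; exclude them (their absence from the
    # reconstructed topologies is penalized by the z terms of RF*)
    keep <- d@universe
    repeat {
        dk <- if (length(keep) == length(d@universe)) d
              else subsetDistribution(d, keep)
        zp <- which(dk@valid == 0)
        if (!length(zp)) { d2 <- dk; break }
        bad <- table(dk@universe[as.vector(dk@pairs[zp, ])])
        worst <- names(bad)[bad == max(bad)]
        worst <- sort(worst, method = "radix")[length(worst)]
        keep <- setdiff(keep, worst)
        if (length(keep) < 2L)
            stop("fewer than 2 ancestors with valid observations", call. = FALSE)
    }
    recon <- reconstructNBest(d2, nBest, budget = budget)
    cf <- cladeFrequencies(recon)

    report <- list(allSequence = allPruned,
                   precision = precision,
                   nPrecisionReplicates = length(precEns),
                   nEnsembleReplicates = length(reconEns),
                   distribution = d,
                   reconstruction = recon,
                   cladeFrequencies = cf,
                   excludedAncestors = setdiff(d@universe, keep),
                   monophylyRates = attr(reconEns, "monophylyRates"))
    if (!is.null(f@trueTopology)) {
        truth <- asPrunedTopology(f@trueTopology, universe)
        report$accuracyAllSequence <- topologyAccuracy(truth, allPruned)
        report$accuracyTopologies <- vapply(recon@topologies, function(t)
            topologyAccuracy(truth, asPrunedTopology(t, universe)), numeric(1L))
    }
    if (!is.null(outDir)) .writePipelineReport(report, outDir)
    report
}

.writePipelineReport <- function(report, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeNewick(report$allSequence, file.path(outDir, "all_sequence.nwk"))
    writeLines(report$reconstruction@newick,
               file.path(outDir, "topologies.nwk"))
    write.table(report$cladeFrequencies,
                file.path(outDir, "clade_frequencies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    distributionJSON(report$distribution,
                     file.path(outDir, "distribution.json"))
    obj <- list(all_sequence_topology = canonicalNewick(report$allSequence),
                precision = report$precision,
                n_precision_replicates = report$nPrecisionReplicates,
                n_ensemble_replicates = report$nEnsembleReplicates,
                scores = report$reconstruction@scores,
                complete = report$reconstruction@complete,
                stats = as.list(report$reconstruction@stats),
                monophyly_rates = as.list(report$monophylyRates))
    if (!is.null(report$accuracyAllSequence)) {
        obj$accuracy_all_sequence <- report$accuracyAllSequence
        obj$accuracy_topologies <- report$accuracyTopologies
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(outDir, "report.json"))
    invisible(outDir)
}
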
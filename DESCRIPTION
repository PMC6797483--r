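Package: EnsembleTopo
Title: Ensemble Reconstruction of Paralog Divergence Topologies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs paralog divergence topologies from ensembles of
    phylogenies inferred from ortholog subsamples. Full phylogenies are pruned
    to the common ancestors of ortholog sets ("orthosets"), compared with a
    modified Robinson-Foulds distance that tolerates non-monophyletic
    reconstructions, and summarised as leaf-to-leaf path-length frequency
    distributions. A branch-and-bound search under a log-frequency objective
    enumerates the N topologies most consistent with the ensemble, and an
    observable precision statistic tracks the (hidden) accuracy of a
    single-alignment reconstruction. Includes a seedable simulator of paralog
    families (random duplication topologies, grafted species trees,
    substitution-only protein evolution) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Phylogenetics, Software, SequenceMatching
Config/testthat/edition: 3
RoxygenNote: 7.3.3
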
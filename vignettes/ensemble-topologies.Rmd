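---
title: "Ensemble reconstruction of paralog divergence topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble reconstruction of paralog divergence topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsembleTopo)
```

## The problem and the model

Reconstructing how the paralogs of a protein family diverged is hard:
likelihood-based inference from a single alignment of all available
sequences is sensitive to exactly which sequences were chosen and how they
were aligned, and with short protein sequences the objective function often
cannot separate competing topologies. EnsembleTopo implements an ensemble
strategy around that weakness. The ancestors of interest are the common
ancestors of *orthosets* -- sets of orthologs that each represent one
paralog. Reconstruction of the clades below those ancestors is deliberately
sacrificed ("integrated out"): full trees are pruned so that each
monophyletic orthoset becomes a single ancestor leaf, and all analysis
happens on these reduced *paralog divergence topologies*.

Three quantities drive the method:

* **RF\*** -- a modified, normalized Robinson-Foulds distance
  $(x+y+z+z')/(2N-6)$ over $N$ designated ancestors. $x$ and $y$ count
  non-trivial unrooted splits unique to either topology after restriction to
  the ancestors present in both; $z$ and $z'$ count ancestors lost to
  non-monophyletic reconstruction on one side only. With complete, properly
  formed topologies ($z = z' = 0$) it reduces to the classic normalized RF
  distance on $[0,1]$.
* **Accuracy** = $1 - RF^*(\mathrm{true}, \mathrm{reconstructed})$;
  observable only in simulation.
* **Precision** = $1 - \langle RF^*(\text{all-sequence},
  \text{subsampled})\rangle$ over an ensemble of trees inferred from ~90%
  subsamples of each orthoset; observable always, and used as a proxy for
  the accuracy of the all-sequence reconstruction.

A rooted topology is equivalently represented by its matrix of leaf-to-leaf
**path lengths**, where the length of a path is the number of internal
nodes on it, the root included when traversed. Note the unit: a cherry has
path length 1, and many libraries would instead report edge counts. The
equivalence is constructive in both directions (`pathLengthMatrix()`,
`topologyFromMatrix()`), and the matrix form is what makes ensembles
aggregable: across an ensemble of pruned topologies, each unordered
ancestor pair accumulates an empirical distribution of observed path
lengths (`aggregateEnsemble()`).

A candidate topology $t$ is scored against the ensemble by the
log-frequency objective

$$\mathrm{score}(t) = \sum_{\text{pairs } (i,j)} \log f_{ij,L_{ij}(t)},$$

the sum over all ancestor pairs of the log observation frequency of that
pair's path length in $t$. The score is 0 exactly when every path of $t$
was observed with frequency 1 and decreases as $t$ incorporates rarer
paths. `reconstructNBest()` enumerates the $N$ best-scoring topologies by
branch and bound: partial states ("assemblies") hold a forest of built
subtrees; joining two subtrees under a new internal node is permitted only
if every leaf pair completed by the join takes a length that was actually
observed; and an admissible projected score -- the running score plus each
open pair's best still-achievable log frequency -- prunes states that can
no longer beat the current $N$-th best completed topology.

## Handling non-monophyletic reconstructions

Real (and noisy simulated) trees occasionally fail to recover an orthoset
as a clade. Such an orthoset yields no ancestor leaf; it is recorded in
`missingAncestors()` and enters comparisons through the $z$ terms of RF\*.
Every surviving internal node at or below the MRCA of the offending leaves
is flagged *spurious* -- its existence depends on the offending arrangement
-- and ensemble aggregation drops any path through a spurious node while
keeping the member's untainted paths. Because a scattered orthoset often has
its MRCA at the root, a badly non-monophyletic member can contribute
nothing; this is the conservative reading, and it is why per-pair
frequencies normalize over each pair's *valid* observations rather than
over the ensemble size (pairs with different numbers of compromised
observations stay comparable). An ancestor whose pairs end up with no valid
observations at all cannot be considered high-confidence; the pipeline
excludes it from reconstruction and lets the $z$ terms penalize its absence
when accuracies are computed.

## Numerical and procedural choices

* **Rooting.** Inference tools emit unrooted trees. Adapter output is
  midpoint-rooted (deterministic, branch-length based) before
  canonicalization: an arbitrary resolution of the basal trifurcation can
  place the root *inside* an orthoset clade that is perfectly connected in
  the unrooted tree, manufacturing spurious non-monophyly. For
  branch-length-free Newick text, `readNewick()` instead resolves
  multifurcations deterministically by joining the first two children in
  canonical leaf order; one convention is applied to every tree of an
  analysis so all path lengths share a frame.
* **Canonical form.** Children are ordered by their smallest leaf label
  (radix/C collation), so identical topologies serialize to identical
  Newick strings; these strings also serve as the deduplication keys that
  prevent the same construction state from being expanded twice. The
  incompatible-entry status of an assembly is a function of its forest, so
  the forest key alone suffices.
* **Unobserved-length floor.** Scoring a topology outside the ensemble's
  support uses a per-pair floor frequency $1/(2E_{\text{pair}}+1)$ ($E$ =
  valid observations), strictly below any observable frequency $\ge 1/E$.
  This keeps scores finite (so externally supplied topologies, e.g. an
  all-sequence tree, can be ranked against reconstructions) without
  disturbing the ranking of supported topologies *per pair*; note a floored
  topology can still outrank a supported topology whose other pairs are
  rare, which is the intended behavior of a sum of log frequencies.
* **Search order and ties.** The entry list sorts by increasing length,
  then decreasing frequency, then pair label; completeness of the search
  does not depend on this order (the suite checks the search against
  exhaustive enumeration). Expansion is best-first by projected score, so
  truncated runs (assembly budget) return a correctly ordered prefix of the
  complete result. Scores equal up to $10^{-9}$ are treated as tied --
  float summation order would otherwise make co-optimal topologies at the
  bound seed-dependent -- and final ties order by canonical Newick.
* **Subsampling.** The per-orthoset target is $\max(1, \min(n-1,
  \lceil f \cdot n\rceil))$ for fraction $f < 1$: the ceiling keeps at
  least one sequence from tiny orthosets, and the $n-1$ cap guarantees a
  fractional jackknife actually drops something (with 8 orthologs,
  $\lceil 0.9 \times 8 \rceil = 8$ would silently disable resampling).
* **RF\* domain.** $N < 4$ is an error (no informative splits), not a 0/0.

## The synthetic family generator

`simulateFamily()` produces benchmark families with a known truth:

1. a random rooted paralog topology by sequential random attachment
   (uniform over rooted binary shapes) with i.i.d. exponential branch
   lengths -- `meanBranchLength`, in substitutions/site, is the main
   difficulty dial (the benchmark grid spans 0.3-1.2);
2. a seedable birth-death species tree (`ape::rphylo`, birth 1, death 0.5;
   66 tips by default, 8 in the desk-scale benchmark) grafted below every
   paralog leaf, each copy rescaled to height `speciesTreeHeight` times a
   Uniform(0.5, 1.5) per-paralog factor (heterotachy between paralogs) with
   every branch further perturbed by Uniform(0.75, 1.25);
3. substitution-only protein evolution (`phangorn::simSeq`) under JTT with
   8 contiguous segments cycling through rate classes (0.4, 0.8, 1.2, 2.0)
   -- a five-fold range emulating conservation structure across a fold. The
   built-in inference adapter is deliberately model-free (neighbor-joining
   on uncorrected p-distances), mirroring the realistic situation where the
   inference model does not match the generating process.

`speciesTreeHeight` defaults to 0.45 substitutions/site, set by the rule
"as much ortholog heterogeneity as the high-confidence-ancestor premise
allows": beyond that height orthosets stop
being overwhelmingly monophyletic under subsampled NJ inference, which
breaks the method's premise; far below it, orthologs are nearly identical
and subsampling carries no information.

What the generator does *not* emulate is as important as what it does:

* **No indels, hence no alignment step.** Simulated sequences are exactly
  aligned by construction. In real analyses, realignment of every subsample
  is a dominant source of ensemble variance; desk-scale precision therefore
  varies much less than it would with an align-then-infer adapter, and the
  precision-accuracy correlation is correspondingly weaker than what
  full-scale analyses with external aligners can show. Tests passing on
  these fixtures validate the algorithms, not the field behavior of
  alignment pipelines.
* **One species tree for all paralogs**, i.e. pure
  duplications-then-speciations; no gene loss, no co-orthology.
* **Site independence** and a single empirical exchange matrix.

## Scale of the shipped analyses

The test-suite experiment runs 30 families of 6 paralogs x 8 orthologs
(250 residues), with 20 precision replicates at 90% and 200 reconstruction
replicates at 50% -- sizes chosen so a complete run of the suite stays in
the minutes range while still exercising every pipeline stage end to end.
The full-scale design the package defaults point at (15 paralogs x 66
orthologs, 50 precision replicates, 1000-replicate ensembles) runs the same
code paths.

## Known limitations

* The branch-and-bound search is exact but exponential in the number of
  ancestors; it is intended for the pruned problem (tens of ancestors at
  most), not for full trees. Budgeted runs return a flagged,
  correctly-ordered prefix.
* Reconstruction emits topologies only; branch lengths for a chosen
  topology should be optimized afterwards by an external tool.
* Precision measured with a deterministic distance adapter on gap-free
  sequences is an optimistic, low-variance version of the statistic; see
  the generator caveats above.
* No reconciliation with a species tree is attempted, and non-monophyletic
  orthosets are excluded rather than repaired.
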
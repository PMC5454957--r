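---
title: "Prioritizing disease genes by random walk with restart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes by random walk with restart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrprio)
```

## The problem

For many complex diseases — uveitis, the motivating case for this package,
is one — a few dozen genes are validated by experiment or by repeated
association, while the broader genetic architecture is unknown. Because
interacting proteins tend to share function, a weighted protein–protein
interaction (PPI) network is a natural substrate for extending a validated
gene set: genes that sit close to many known disease genes in the network
are plausible new candidates. `rwrprio` implements a complete pipeline of
this kind: a random walk with restart (RWR) ranks every gene in the network
by proximity to the seed set, a permutation test removes genes that rank
highly under *any* seed set, and two association filters keep only
candidates with direct, high-confidence links to the validated genes.

The package operates on STRING-style inputs: a weighted edge list whose
integer combined scores lie in \[150, 999\], a seed list of validated gene
identifiers, and a GMT file of term→gene annotations (GO terms and KEGG
pathways, treated as one concatenated term collection).

## The walk

Let $W$ be the symmetric score matrix of the network and
$A = W D^{-1}$ its column-normalized form, so that entry $(i, j)$ is the
probability that a walker at node $j$ steps to neighbor $i$, proportional
to the edge score. With $P_0$ uniform over the $m$ seed genes
($1/m$ each, zero elsewhere), the walk iterates

$$P_{i+1} = (1 - r)\,A P_i + r P_0,$$

stopping at the first iterate with
$\lVert P_{t+1} - P_t \rVert_{L1} < 10^{-6}$. The update is sometimes
written with the transpose of the row-normalized transition matrix applied
to the probability column vector; that is the same operator, and it is the
only normalization under which each iterate remains a probability vector
(mass conservation is enforced by a test invariant, and the iterative
solution is checked against a dense linear solve of
$(I - (1-r)A)P = rP_0$ on small graphs). The restart probability
$r = 0.8$ keeps the walk tightly anchored to the seeds; convergence is
geometric at rate $1 - r$, so a tolerance of $10^{-6}$ is reached in a few
dozen iterations and the 10,000-iteration cap is a pure safety net.

Genes with stationary probability strictly above $10^{-5}$ are the *RWR
genes*. Seed genes are excluded from this list by default (the goal is
novel candidates; a flag restores them).

## The permutation filter

High RWR probability can reflect network topology — hubs and their
satellites score well from almost any seed set — rather than disease
proximity. The permutation test draws 1000 node sets of the seed-set size
uniformly from all network nodes, re-runs the walk for each (the transition
matrix is fixed; only $P_0$ changes), and for each RWR gene counts the
permutations $\Theta$ whose probability strictly exceeds the gene's
probability under the true seeds:

$$p(g) = \Theta / 1000.$$

Genes with $p < 0.05$ survive as *candidate genes*. Ties do not increment
$\Theta$, which is anti-conservative at the margin; p-values live on the
grid $\{0, 1/n, \dots, 1\}$ and a 0 is reported as "<0.001" at 1000
permutations. No multiple-testing correction is applied — the filter
reproduces the raw-p-value selection of the published design, a documented
limitation. Permutation sets are drawn from all nodes (the true seeds are
not excluded), from a single seeded RNG stream; the drawn sets are retained
in the result object for audit.

## The association filters

Two scores tie each candidate back to the validated genes directly.

**Maximum interaction score.**
$\mathrm{MIS}(g) = \max\{S(g, g') : g' \text{ a seed}\}$, the best STRING
score on an edge from $g$ to any seed, 0 if there is none. The default
threshold is 900 — STRING's highest-confidence cutoff — applied
*inclusively* ($\ge 900$). The published description uses "larger than" in
one place and "no less than" in its pseudo-code; we follow the pseudo-code,
and the choice is configurable (at full scale the smallest surviving MIS
was 916, so both readings select the same genes).

**Maximum function score.** For each gene, an enrichment-score vector
$ES(g)$ holds one value per annotation term: the upper-tail hypergeometric
probability that $g$'s direct network neighbors are over-represented among
the term's genes, as
`-log10(phyper(numWdrawn - 1, numW, numB, numDrawn, lower.tail = FALSE))`.
The sampling universe is every network node carrying at least one
annotation, which makes `numW + numB` a meaningful whole; neighbors count
regardless of edge weight; terms with no annotated neighbor score 0; tail
probabilities are floored at $10^{-300}$ so scores stay finite. The
functional relatedness of two genes is the cosine of their score vectors,

$$\Gamma(g, g') = \frac{ES(g) \cdot ES(g')}{\lVert ES(g)\rVert\,\lVert ES(g')\rVert} \in [0, 1],$$

defined as 0 when either vector is all zero, so genes with unannotated
neighborhoods simply fail the filter. $\mathrm{MFS}(g)$ is the maximum
$\Gamma$ against any seed; candidates need $\mathrm{MFS} > 0.8$ (strict).
Survivors of both filters are the *core genes*, the pipeline's final
output. Enrichment vectors are computed lazily for candidates and seeds
only.

## Evaluation

`cross_validate()` partitions the seed list into $k$ near-equal random
folds (146 identifiers at $k = 5$ give sizes 30, 29, 29, 29, 29), runs the
entire pipeline — walk, permutation test, MIS, MFS — on the training folds
only, and scores the core genes against the held-out fold:

$$\mathrm{recall} = \frac{TP}{TP + FN},\quad
  \mathrm{precision} = \frac{TP}{TP + FP},\quad
  F_1 = \frac{2\,\mathrm{recall}\cdot\mathrm{precision}}{\mathrm{recall} + \mathrm{precision}},$$

with zero-denominator metrics defined as 0. The comparator is
guilt-by-association (`gba_predict()`): each seed contributes its $k$
highest-scoring neighbors (ties by identifier), the union minus the seeds
is the prediction, and `gba_grid_search()` scans
$k \in \{1,\dots,10, 20, \dots, 100\}$ per fold, reporting the F1-best $k$
with ties toward the smallest.

The exported `uveitis_cv_reference` table carries the fold-level metrics
reported for the full-scale uveitis analysis (STRING v9.1, 146 seeds).
Recomputing $F_1$ from each fold's printed recall and precision reproduces
the printed $F_1$ at three decimals on RWR folds 2, 4 and 5 and GBA folds
1 and 5; folds 1 and 3 of the RWR column differ by one unit in the third
decimal, consistent with the original averaging of unrounded values. The
column means reproduce the reported averages 0.287 / 0.141 / 0.189, and the
mean of the recomputed per-fold $F_1$ also rounds to 0.189. These checks
pin down the metric arithmetic; the full-scale counts themselves (3641 RWR
genes → 1231 candidates → 56 core genes) require the STRING v9.1 download,
the 146-identifier seed list and a frozen GO/KEGG snapshot, and are
deliberately out of the test suite's scope.

## The synthetic benchmark

`synthetic_spec()` describes a desk-scale fixture with the structure the
method assumes: an Erdős–Rényi background (default 60 nodes, edge
probability 0.05, scores 150–500) plus a planted 10-gene module (edge
probability 0.8, scores 850–999, a spanning cycle guaranteeing
connectivity), and an annotation layer in which three "module terms" each
annotate 80% of the module plus a couple of background genes, alongside 20
random background terms. Scores are integers, matching STRING; fixtures are
deterministic functions of the spec's RNG seed; and
`write_synthetic_fixtures()` emits the exact external formats (links file
with both edge directions, seed list, GMT, JSON truth), so tests exercise
the real parsers. `split_module_seeds()` plays the cross-validation game at
fixture scale: half the module seeds the walk, the other half is the
recovery target.

What the generator does *not* emulate: the heavy-tailed degree
distribution, the size, and the correlated annotation structure of a real
interactome. Passing the recovery tests shows the pipeline's machinery is
correct and that it finds planted structure of the assumed kind; it is not
evidence about performance on real networks, for which the reference
cross-validation table is the relevant anchor.

### Choice of scale for recovery tests

Recovery tests run the generator at 200 nodes (all other defaults
unchanged, permutations reduced to 200 and the probability threshold
relaxed to $10^{-4}$ for the smaller mass scale). The reason is a property
of the permutation null, visible analytically: a random seed set of size
$m$ contains any fixed gene with probability $m/n$, and a gene inside the
seed set receives probability near $r/m$ — far above any non-seed gene. A
gene's permutation p-value therefore has floor $\approx m/n$. With 5
training seeds on 60 nodes that floor is 0.083, above $\alpha = 0.05$, and
the filter empties regardless of effect size; at 200 nodes the floor is
0.025, and the full-scale regime (146/20,770 ≈ 0.007) is approximated.
The 60-node default remains right for parser, walk and
probability-separation tests, which do not pass through the permutation
filter.

## Numerical and degenerate-input choices

* Strict inequalities where the published rules state them: probability
  threshold ($>$), $\Theta$ counting ($>$), $\alpha$ ($<$), MFS ($>$);
  inclusive MIS ($\ge$).
* Ordering is fully deterministic: probability descending with identifier
  tie-breaks for RWR genes; p-value, then probability, then identifier for
  candidates and core genes; byte-identical outputs across reruns with the
  same configuration and RNG seed are an acceptance property.
* Conflicting duplicate edge scores are an error (corrupt input should
  surface), self-loops are dropped with a warning, and empty stage outputs
  are logged, not fatal.
* An empty annotation map is allowed: every MFS is 0 and the core stage
  selects nothing, which is the honest answer.
* A gene in a component containing no seed has probability 0 and is simply
  never selected.

## Problem sizes used by the test suite

Unit fixtures use 10–100 nodes; oracle comparisons (dense linear solve,
brute-force permutation loop, combinatorial hypergeometric enumeration) run
at 50, 10 and ≤ 25 nodes/universe respectively; recovery properties use 20
generator seeds at 200 nodes with 200 permutations. The full suite and the
acceptance script each complete in well under a minute on one CPU.
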
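---
title: "Contrast-pattern detection of protein complexes: model and design notes"
author: "ContrastComplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-pattern detection of protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContrastComplex)
```

## The model

A PPI network is an undirected simple graph of protein IDs; a candidate
complex is any nonempty node set, read as the induced subgraph
$C = (V_c, E_c)$. The working hypothesis is discriminative rather than
generative: known complexes and random subgraphs occupy different regions
of a 22-dimensional feature space, and the contrast between the two
classes — not density alone — is what identifies a complex. This matters
because genuine complexes can be sparse ($den(C) \approx 0.4$) and can be
heavily wired into the rest of the network, which defeats
density/separation-based clustering.

### Feature space

For each subgraph we compute node size; density
$den(C) = 2|E_c| / (|V_c|(|V_c|-1))$; mean, maximum and (population)
variance of four per-node statistics on the induced subgraph — degree
normalized by $|V_c| - 1$, degree correlation (mean degree of a node's
within-subgraph neighbors divided by its own degree), the local clustering
coefficient, and the Cytoscape-style topological coefficient (mean
shared-neighbor count over partner nodes, scaled by own degree); the
largest eigenvalues of the induced adjacency and combinatorial Laplacian
matrices; and mean/max/variance of the members' sequence length and
molecular weight. Conventions for degenerate cases: a singleton has all
topology statistics 0; per-node ratios are 0 for isolated or degree-1
nodes where undefined; attribute features are 0 when no attribute table is
supplied. Normalizing degrees to $[0,1]$ keeps the degree group comparable
across subgraph sizes (it also makes the mean normalized degree coincide
with density — the two features are kept separate so the registry remains
stable if the normalization ever changes). The registry of 22 names is
versioned into every model; prediction refuses a model whose registry
differs from the build.

### Discretization

Features are discretized into 10 equal-width bins per feature, with the
bin edges fitted on the pooled training data
$D = D_p \cup D_n$ (known complexes plus random subgraphs). Value $v$ maps
to $\lfloor (v - lo)/w \rfloor$ clipped into $[0, 9]$: the observed
maximum falls in the top bin rather than an 11th bin, out-of-range values
at prediction time clip to the boundary bins, and a feature that was
constant at fit time maps everything to bin 0. Ten equal-width bins are a
deliberate bias-variance compromise: finer bins fragment a small positive
class, coarser bins blur the contrast.

### Noise-tolerant emerging patterns

With items = (feature, bin) pairs, an itemset $X$ (at most one item per
feature) is an NEP from background $D_1$ to target $D_2$ when
$supp_{D_1}(X) \le \delta_1$, $supp_{D_2}(X) \ge \delta_2$, and no proper
subset of $X$ satisfies the first condition. Minimality is what makes the
patterns parsimonious: once an itemset is already rare in the background,
any extension is redundant. The miner is a depth-first search over items
ordered by ascending background support; branches are pruned when target
support drops below $\delta_2$ (support is anti-monotone) and extension
stops when rarity is reached. Because support is anti-monotone, the
minimality clause only needs checking against the maximal proper subsets.
Items of features that are single-binned across $D$ occur in every
instance and are excluded from the universe; this provably cannot change
the result (such an item can never make a set rare, and any superset
containing it is non-minimal). An exhaustive enumerator
(`bruteForceNEPs`) applies the definition literally and serves as the
correctness oracle in the test suite; the two implementations are compared
on hundreds of randomized instances.

Defaults $\delta_1 = 0.1$, $\delta_2 = 0.7$. The rarity threshold tolerates
10% label noise in the background class; the frequency threshold demands
that a pattern describe a clear majority of its class. Both are exposed on
the API and CLI.

### Scores

The aggregate score of $G$ w.r.t. a class is
$\sum_{e \subseteq Ins(G)} supp(e)$ over that class's NEPs — the canonical
support-sum aggregate of emerging-pattern classifiers, and the only
per-pattern quantity the model stores. Because the two classes can have
very different numbers of NEPs, each aggregate is normalized by a *base
score*: the median aggregate over the class's own training instances (even
counts average the central pair). If the median is 0 the smallest strictly
positive instance score is used, and 1 if all are zero — a guard chain
that keeps normalization defined for tiny pattern sets; it warns loudly
when triggered. The clustering score is

$$f(G) = \frac{norm_p(G)}{norm_p(G) + norm_n(G)},$$

with $f = 0$ when both normalized scores are 0 ("matches nothing we know
about either class" is treated as "not a complex"). This ratio is the
simplest form satisfying the two identities that define the score's
semantics: $f > 1/2 \iff norm_p > norm_n$, and $f = 1 \iff norm_n = 0$
with $norm_p > 0$.

### Search

Seeds are processed in decreasing network degree (ties lexicographic)
among proteins not yet covered by an emitted complex. From $C =
\{seed\}$, each iteration selects the single neighbor $v$ maximizing
$edgeNum(v, C)$ (ties lexicographic) and accepts $C' = C \cup \{v\}$ iff
$f(C') \ge f(C)$ **and** $avedeg(C') > avedeg(C)$; the first rejection
ends growth — no backtracking and no second-best fallback. The
average-degree condition is evaluated first: the conjunction is
unchanged, and the cheap test avoids a feature extraction at the final,
rejected step. Grown clusters pass the output filter $f > 1/2$,
$|C| \ge 3$ (mirroring the removal of 1–2 protein complexes from training
catalogues). Every processed seed is marked visited whether or not it
produced a complex; without this bookkeeping a network containing
proteins that never join any complex would never terminate under a
literal "every protein occurs in some found complex" stopping rule.
Finally, pairs of results with overlap $\omega \ge 0.8$ are merged
iteratively (highest $\omega$ first, ties by lexicographic member lists),
and the merged catalogue is re-filtered to $f > 1/2$ and the minimum
size, so the emitted-complex contract holds even if a merged union drifts
below the threshold. The 0.8 merge default follows the convention of the
overlap-merging clustering literature; it is configurable.

## Training-set construction

Positive instances are catalogue complexes intersected with the network's
node set; survivors with fewer than 3 members and exact-duplicate member
sets are dropped. Negatives are drawn as uniform node sets — deliberately
*not* forced-connected subgraphs: random connected subgraphs of a sparse
network are far denser than uniform sets and would blur exactly the
contrast the patterns rely on. Each negative's size is resampled from the
empirical positive size list, which reproduces the positive size
distribution without estimating a power-law exponent; a draw identical to
a positive member set is rejected and redrawn (the minimal guard against
label noise — partial overlap is allowed). The ratio is 20 negatives per
positive by default. Negatives are frozen per seed: the same seed gives a
bit-identical training set, model file, and downstream predictions.

## The synthetic benchmark

`generateBenchmark` emulates the statistical structure the method assumes:
a sparse Erdős–Rényi background (default 300 proteins, edge probability
0.02), 20 node-disjoint planted complexes with sizes following a truncated
power law on $[3, 10]$ (exponent 2 — complex catalogues are dominated by
small complexes), internal edge probability 0.8 (dense regime) or ~0.4
(sparse regime) plus a random spanning path so every planted complex is
connected, and 2 outward attachment edges per complex so complexes are not
trivially separated components. Sequence lengths are log-normal (median
~400 residues, a realistic protein-length scale) with molecular weight a
linear 0.11 kDa/residue map. Note the spanning path raises the realized
density of small sparse complexes above the nominal edge probability
(a size-4 "density 0.4" complex still carries its 3 tree edges).

What the generator does **not** emulate: the heavy-tailed degree
distribution of real PPI networks, shared subunits between complexes
(planted sets are disjoint), experimental false positives/negatives
structured by study bias, and correlated protein attributes. Passing the
recovery tests therefore demonstrates the machinery — features, mining,
scoring, search, evaluation — under controlled conditions, not
performance on any real interactome.

Problem sizes used by the test suite and the acceptance script (300-node
benchmarks, 10-complex training splits, 200 miner-vs-oracle instances
capped at 6 features × 4 bins × 40 rows, 100 matching instances capped at
7×7) were chosen to exercise every code path at desk scale while keeping
a full run in the order of a minute.

## Numerical and tie-breaking choices

* Population variance (divide by $n$) so singletons have variance 0.
* Spectral features via exact symmetric eigendecomposition; clique
  closed forms ($\lambda_1(A) = n-1$, $\lambda_1(L) = n$) are recovered to
  machine precision.
* All set-valued outputs (member lists, NEP collections) are sorted
  canonically so equal inputs give byte-identical files.
* The MMR matching is an exact maximum-weight bipartite matching
  (igraph's solver), never greedy; it is verified against exhaustive
  enumeration. Edges are included for every $\omega > 0$, not only
  $\omega \ge 0.25$: the matching and the matching-threshold measures are
  deliberately decoupled.
* Clustering-wise PPV uses $\sum_{ij} T_{ij}$ as denominator; predictions
  sharing no protein with any reference contribute nothing to either sum,
  and a fully disjoint prediction set yields PPV = Acc = 0 with a warning
  rather than an error.
* F1 is the harmonic mean $2PR/(P+R)$, defined as 0 when both components
  are 0.

## Known limitations

* With very small positive classes the frequency threshold becomes the
  binding constraint: $\delta_2 = 0.7$ over 10 positives requires 7
  instances to share a bin, so heterogeneous (especially sparse) training
  complexes can yield an empty positive pattern set, in which case no
  subgraph can score above $1/2$ and nothing is emitted. The training
  summary and the model object surface the pattern counts precisely so
  this state is visible; lowering $\delta_2$ (or enlarging the training
  catalogue) is the remedy. The acceptance script's sparse-regime numbers
  quantify this boundary on the synthetic benchmark.
* Scoring a subgraph far outside the training feature ranges relies on
  boundary-bin clipping; the score remains defined but the contrast
  semantics weaken.
* The greedy growth has no backtracking: a single bad maximal-edge
  candidate ends the path. This is faithful to the search design but
  makes recovery sensitive to attachment noise around small complexes.
* Edge weights are read and stored for format fidelity but are not used
  by the algorithm, which is topology- and attribute-based.
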
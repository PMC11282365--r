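---
title: "Methods: mining and reusing node ages from published chronograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and reusing node ages from published chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronograft)
```

## The problem

Chronograms — phylogenies whose branch lengths are proportional to absolute
time — are expensive to build: they need curated alignments, fossil
calibrations and specialist dating software. At the same time, thousands of
peer-reviewed chronograms already exist in the literature. chronograft treats
those published trees as a queryable data resource: given a set of species
names and a target topology, it finds every stored chronogram that shares at
least two of the names, extracts the implied divergence times, summarizes
them per node, and uses the summaries as *secondary calibrations* to date the
target.

The workflow is: **resolve names → search the database → congruify ages onto
the target → summarize per node → filter conflicts → date by even spacing**.
Each step is an exported function returning a tibble or a `phylo`, so the
whole pipeline is also available as `date_topology()` and as shell commands
(`inst/cli/chronograft.R`).

## Data model

A *chronogram* here is a rooted, ultrametric `ape::phylo` with branch
lengths in millions of years (Myr). Node ages are depths below the present:
tips at 0, the root oldest. Every source chronogram is stored pruned to the
matched taxa as a **patristic distance matrix**: total tip-to-tip time. For
an ultrametric tree the entry for a pair equals exactly twice the age of the
pair's MRCA, so node ages are recovered by halving matrix entries. Matrices
make age lookup for arbitrary pairs O(1) and are the unit of exchange
between the search, summary and calibration steps.

**Ultrametricity tolerance.** Published newick files carry rounding noise,
so a tree qualifies as a chronogram when its root-to-tip path sums agree to
a *relative* tolerance of 1e-6. Beyond that the tree is rejected with an
error rather than silently rescaled: stretching someone's published branch
lengths would manufacture ages that were never estimated.

## Name resolution

Matching depends entirely on names, so the package standardizes them against
a local, versioned taxonomy table (id, parent id, canonical name, rank,
synonyms). Resolution is a deterministic cascade: exact canonical match,
then synonym lookup, then fuzzy match by normalized edit-distance similarity
(threshold 0.90; one typo in a binomial of typical length scores about
0.95, two typos fall below). Ties prefer a candidate in the same genus, then
the lexicographically smallest. The cascade is intentionally local — no
network service — so resolutions are reproducible against a pinned taxonomy
version. The same canonicalization is applied to database tip labels at load
time; this is what lets a study published under a synonym contribute
calibrations to a query phrased with the accepted name (in the bundled
six-species example, the five data points for the parent node of
*Schoeniclus elegans* exist only because the query's *Emberiza elegans* is
resolved to it).

Fuzzy matching is never applied to database tips, only to user input: a
typo in a query is the user's to make, but silently rewriting the database
would corrupt provenance.

Inclusive names (genus and above) are either expanded to all species-rank
descendants — excluding subspecific variants — or excluded from the query
with a notice, under the `get_species` flag.

## Congruification

To transfer an age from a source matrix to the target topology, the two
trees must agree that the node exists. For a target internal node `v`, let
`S` be the query taxa shared with the source that descend from `v`. `v`
receives a calibration when:

1. `v` is the target MRCA of `S` (so `v` is the node the shared taxa
   actually witness, not merely an ancestor of it), and
2. the source MRCA of `S` has no *other* shared taxa below it (the source
   does not interleave the clade with taxa the target places elsewhere).

The age assigned is half the source-matrix entry of a witness pair spanning
the source MRCA; with several candidate pairs the lexicographically smallest
is reported, which makes output deterministic. Nodes failing either check
simply yield no row — topological conflict is expressed as missing data, not
as an error. Congruifying a chronogram's own matrix onto its own topology
recovers every internal node age exactly, which the test suite exercises on
hundreds of random trees.

Internal nodes are named `n1, n2, ...` with `n1` the root and the rest in
preorder following the target tree's own child ordering. The ordering of
children is therefore part of the target's identity; the bundled example
stores its topology in the orientation that yields the conventional
`n1`..`n5` labels.

## Summaries and the SDM matrix

Per-node ages are summarized with min, quartiles, median, mean, max,
sample variance (n−1 denominator) and SD. Quartiles use the linear
interpolation convention `h = (n-1)p + 1` (R's default type 7). Alongside
the per-node path, whole matrices can be combined cellwise (mean, median,
min, max) over the matrices containing each pair; cells with no data stay
`NA` — no imputation.

The super-distance-matrix (SDM) summary deforms each matrix by a positive
scale factor before averaging, minimizing

$$\sum_p \sum_{(i,j)} \big(\alpha_p d_p(i,j) - \mu_{ij}\big)^2,
\qquad \mu_{ij} = \tfrac{1}{|P_{ij}|}\sum_{q \in P_{ij}} \alpha_q d_q(i,j),$$

subject to $\sum_p \alpha_p = P$. The objective is an exact quadratic form
in the scales, so the minimizer is obtained from the KKT linear system in
one solve (tolerance is machine precision; the test suite cross-checks
against direct numeric minimization). Only scale deformation is supported;
the additive terms of the full SDM formulation are out of scope and
documented as such. SDM requires its inputs to form a single *grove*:
connected components of the graph whose edges join matrices sharing at
least `n = 2` taxa. Grove detection is exposed as `find_groves()` /
`pick_grove()` (default choice: most taxa; `criterion = "trees"` switches to
most trees), and `build_supertree()` clusters the SDM matrix with
average-linkage agglomeration (pairwise-available averaging across missing
cells) to propose a combined topology when the user supplies none.

## Filtering and even-spacing dating

Calibrations must decrease strictly from root to tips. The filter runs
root-down first — discarding any node whose age is ≥ its nearest *retained*
ancestor's — then tip-up, discarding ages ≤ any retained descendant's. The
order matters when a chain conflicts in both directions; root-down-first
means the more inclusive node wins, which matches the convention of
discarding ages "older than a parent node". Every decision is recorded
(`used`, `discarded:older-than-ancestor`,
`discarded:younger-than-descendant`) and surfaces in the provenance output.

The dater (`bladj()`) fixes calibrated ages and assigns each uncalibrated
internal node an age by even spacing: for a node that is the k-th of m
unfixed nodes on the path from its nearest fixed ancestor (age a) to its
chosen fixed descendant (age d, tips counting as fixed at 0), the age is
`a − (a − d)·k/(m+1)`. The fixed descendant is the one reachable through the
fewest unfixed nodes; ties go to the oldest candidate, then the smallest
descendant label. On an unbranched chain this reduces to the classic evenly
spaced interpolation; on branching trees each node interpolates along its
own nearest-descendant path, which keeps the rule local, deterministic and
order-independent. The output is exactly ultrametric (path sums equal the
root age to machine precision) and reproduces fixed ages exactly. The exact
node-visit order of other even-spacing implementations when several fixed
descendants tie is undocumented, so small age differences against them are
possible on polytomous or deeply uncalibrated trees.

**Root age policy.** Even spacing needs a root age. A user-supplied value
always wins; otherwise the root's own retained summary age is used;
otherwise the default is deterministic — 1.1 × the oldest retained
calibration — with a conspicuous warning, because a silently random root in
a dating tool undermines reproducibility. A randomized fallback (uniform
between the oldest calibration and 1.5 × it) is available behind an explicit
seed for users who prefer an agnostic draw.

## Cross-validation

`cross_validate_study()` implements leave-one-study-out validation: each
chronogram of the held-out study is treated as an undated topology,
calibrated from all *other* studies (exclusion at study granularity, so a
study never informs itself through a second chronogram), summarized with
the **mean** — deliberately, as cross-validation conventionally averages the
available estimates — filtered, and re-dated. The report gives per-study
Pearson correlations of original vs estimated ages and per-depth-bin mean
signed error, which exposes the typical pattern of underestimating deep
nodes. With a duplicate of the held-out study present, recovery is exact
and the correlation is 1 — the degenerate case the tests pin down.

## Synthetic data

Two generators support testing and exploration:

- `small_example_db()` rebuilds the six-species passerine worked example:
  nine source chronograms across six studies, each constructed on the
  minimal topology consistent with the node ages it contributes (records
  witnessing a single pair are two-tip cherries), a taxonomy with the
  *Emberiza*/*Schoeniclus* synonym, and the five-node target topology. It is
  the single source of truth for the worked-example tests; the trees are
  synthetic reconstructions from the published age table, not the original
  files.
- `random_db()` draws pure-birth (Yule) trees over random taxon subsets,
  with root ages uniform on 10–50 Myr — a realistic span for family-level
  chronograms — under a fixed seed. `finch_like_taxonomy()` /
  `finch_like_db()` scale this up to a synthetic family of 289 species for
  stress tests; the names are invented.

What the generators emulate: taxon overlap structure, synonym indirection,
age disagreement between studies, and scale differences. What they do not:
real topological conflict patterns, non-ultrametric published files,
calibration-quality heterogeneity, or the actual curated database behind the
published case studies — so passing tests demonstrate algorithmic
correctness, not that any particular empirical dataset will be reproduced.
Problem sizes in the test suite (trees of 4–15 tips, hundreds of seeded
replicates, a 40-species synthetic family) were chosen to exercise every
code path while keeping the full suite fast on a laptop.

## Numerical choices and limitations

- Distance comparisons inside congruification use relative tolerance 1e-6,
  matching the chronogram validation tolerance.
- Witness pairs, grove picks, tie-breaks and node naming are all
  deterministic; two runs of the same configuration produce byte-identical
  outputs.
- Missing cells in summary matrices propagate; downstream consumers must
  handle `NA`.
- Variance of a single age is reported as `NA`, not 0.
- The package does not run external dating programs; even-spacing is the
  only dater. Penalized-likelihood and Bayesian dating, and inferring
  branch lengths from sequence data, are out of scope.
- Summary chronograms inherit the quality of their sources: conflicting or
  biased source chronograms yield conflicted summaries. The per-node
  dispersion statistics and the cross-validation report are the tools to
  inspect that, and results should always be read against the source
  citations the provenance output lists.
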
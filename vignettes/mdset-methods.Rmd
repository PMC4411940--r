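---
title: "Minimum dominating sets and essentiality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum dominating sets and essentiality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominet)
```

## The scientific setting

A binary protein interaction network is an undirected simple graph
$G = (V, E)$ whose nodes are proteins and whose edges are experimentally
observed pairwise interactions (yeast-two-hybrid style). A *minimum
dominating set* (MDSet) is a smallest set $S \subseteq V$ such that every
protein is either in $S$ or interacts with a member of $S$: a smallest set of
topologically placed proteins that "covers" the whole network in one step.
The size of $S$ — the domination number — is unique; the set itself
generally is not.

The package's central question is how domination interacts with gene
essentiality. Proteins are stratified into three sets: *essential* proteins
(an externally supplied list, intersected with the network), *MDSet*
proteins, and their intersection, the *e-MDSet*. The analysis battery then
quantifies, for each stratum, degree-dependent enrichment, betweenness
bottleneck enrichment, impact on network connectivity under targeted
deletion, protein complex participation, intra/inter-complex interaction
enrichment, and functional class (COG-letter) enrichment.

## The binary program and its solver

Membership indicators $x_v \in \{0, 1\}$ solve

$$\min \sum_{v \in V} x_v \quad \text{s.t.} \quad
x_v + \sum_{w \in \Gamma(v)} x_w \ge 1 \;\; \forall v \in V,$$

where $\Gamma(v)$ is the set of interaction partners of $v$. An isolated
node's constraint degenerates to $x_v \ge 1$, so isolated proteins are
always members.

`solve_mdset()` solves this program exactly by branch-and-bound implemented
in C++:

* **Incumbent.** The greedy max-coverage heuristic (`greedy_mdset()`)
  supplies the initial upper bound; it is also exposed on its own, with the
  guarantee that its output always dominates.
* **Branching.** The search views the program as set cover (candidate sets
  are closed neighborhoods). It picks an undominated node with the fewest
  remaining dominators and branches over them, excluding already-tried
  candidates — a standard inclusion/exclusion scheme that keeps the tree
  finite without symmetric duplicates.
* **Bounds.** The lower bound is the larger of the counting bound
  $\lceil u / \max_v |N[v]| \rceil$ on the $u$ still-undominated nodes and a
  greedy packing of nodes with pairwise disjoint dominator sets.
* **Reduction.** At the root, any candidate whose closed neighborhood is
  contained in another remaining candidate's is discarded (swapping it for
  the witness never worsens a solution). On sparse networks with many
  degree-1 proteins this removes a large share of the search space.
* **Time limit.** If optimality is not proven within `time_limit` seconds,
  the incumbent is returned with status `"feasible-upper-bound"` and the
  proven bound and gap recorded in `solver_info`; dense-core scale-free
  graphs at a few thousand nodes typically end this way, while
  configuration-model and real sparse topologies often solve to proven
  optimality quickly. The returned set always passes `verify_dominating()`.

Optimal dominating sets are non-unique, so all tie-breaking is pinned to
sorted node order, making the returned set a deterministic function of the
network. `order = "random"` re-solves under a seeded random node
permutation; comparing downstream statistics across such re-solves measures
their sensitivity to the particular optimum. `brute_force_mdset()`
(enumeration in increasing cardinality, 20-node guard) is the independent
oracle the test suite holds the solver to.

## Resampling statistics

All enrichment tests share one convention: empirical tail probabilities use
the plus-one rule $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + R)$,
so $p \in (0, 1]$ and the smallest reportable value at $R$ randomizations is
$1/(R+1)$. Every stochastic function takes an explicit seed and restores the
caller's RNG state; a fixed seed reproduces results bit for bit.

**Degree enrichment** (`degree_enrichment_curve()`). Proteins are grouped
into cumulative bins $N_{\ge k}$ (degree at least $k$) and the marked
proteins among them counted, $N_{i, \ge k}$. The null redraws the same
number of marked proteins uniformly without replacement. The enrichment
statistic is defined in the literature as an average of per-randomization
ratios $N_{i,\ge k} / N^r_{i,\ge k}$, which is undefined whenever a null
draw yields zero; the package's default is therefore the numerically stable
ratio of observed to mean null count, with the mean-of-ratios variant
(zero-draws skipped and counted) available via `stat = "mean-of-ratios"`.
Both are recorded in the result's attributes. The default threshold grid is
$k = 1, \dots, k_{\max}$ restricted to bins holding at least 10 proteins
(`min_bin`); thresholds with empty bins report `NA` rather than erroring.

**Bottlenecks** (`betweenness_centrality()`, `bottleneck_set()`).
Betweenness is the unnormalized geodesic count
$c_B(v) = \sum_{s \ne t \ne v} \sigma_{st}(v) / \sigma_{st}$ over unordered
pairs; pairs in different components contribute zero. Bottlenecks are the
top 20% of proteins by $c_B$ (a conventional cut), $\lceil 0.2 n \rceil$ of
them, with ties at the cut again resolved by node order. Their enrichment
with a stratum is a fixed-target overlap test (`set_overlap_enrichment()`):
the null redraws the stratum's size uniformly from the node set, whose
overlap count is exactly hypergeometric — the implementation draws from
that distribution directly.

**Fisher overlap** (`fisher_overlap()`) is the one-sided (enrichment)
hypergeometric tail for the e-MDSet count given the network, MDSet and
essential-set sizes, exact to the precision of `phyper`.

**Complex participation** (`participation_coefficients()`). With $n_{i,s}$
the number of links protein $i$ has to members of complex $s$ out of $N$
complexes, $P_i = \sum_s (n_{i,s} / \sum_s n_{i,s})^2 \in [1/N, 1]$.
Catalog complexes may overlap; a partner belonging to several complexes
increments each of them, and the denominator is the sum of the $n_{i,s}$,
so the formula is applied literally under multi-membership. Proteins with
no complexed partner are reported as undefined (`NA`), not zero. Strata are
compared by a two-sided Wilcoxon rank-sum test (exact for two small
tie-free samples, normal approximation with tie correction otherwise).

**Intra/inter-complex interactions** (`count_complex_interactions()`,
`complex_null_enrichment()`). Among interactions internal to a focal
stratum, an edge is *intra* when its endpoints share at least one complex,
*inter* when both endpoints are complexed but share none, and *excluded*
when an endpoint belongs to no complex (the three counts always sum to the
stratum's internal edge count). The null preserves the catalog's complex
sizes and refills each complex independently, sampling without replacement
within a complex from the universe of proteins appearing in at least one
real complex — a size-preserving reassignment. Edges with an endpoint
outside that universe can never be classified and are excluded from both
observed and null counts. Whether edges with one un-complexed endpoint
should instead count as inter is genuinely ambiguous; the exclusion rule
was chosen because the null only ever reassigns complexed proteins, and the
classification rule is recorded so both variants can be compared.

**Functional classes** (`class_enrichment()`). Classes are single letters
(COG style); a protein may carry several. Observed counts are per class
over the focal stratum. The default null permutes the multiset of codes
across annotated universe proteins while preserving each protein's number
of codes — the closest reading of reassigning "the same number of classes
to each protein" — so per-protein code counts and global class totals are
conserved exactly in every draw. A marginal-resampling variant
(`null = "marginal"`) is available. The universe is the annotated network
proteins, not a genome.

**Robustness** (`deletion_trajectory()`, `compare_trajectories()`). Victims
are sorted once by degree in the intact network (descending, ties by node
order) and deleted successively; after each step the remaining graph's
component count (isolates included) and the cumulative removed-interaction
count are recorded. The static order follows the described procedure
("sort, then delete successively"); adaptive recomputation of degrees is
available behind `recompute = TRUE` but is not the default. The comparison
set for the e-MDSet is the equally sized set of highest-degree essential
proteins.

## The synthetic study generator

`generate_study()` produces a complete, self-consistent test bed: network,
essential list, complex catalog and class annotation, plus the planted
truth. Its defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_nodes` | 1200 | the scale of a bacterial Y2H interactome |
| topology | preferential attachment, `m = 2` | heavy-tailed degrees, mean degree near 4 |
| `essential_fraction` | 0.30 | essential-gene fractions in curated lists |
| `essential_degree_coupling` | 1.0 | a moderate centrality–lethality coupling |
| `n_complexes`, sizes | 40, 3–20 | small-to-mid complexes, overlap allowed |
| `intra_complex_edge_boost` | 0.10 | complexes are denser than background |
| `focal_intra_bias` | 0.15 | essential co-members wire preferentially |
| `class_alphabet` | 20 COG-like letters | typical COG breadth |
| `class_degree_bias` | `J = 1` | translation machinery is hub-enriched |

Essentiality is planted per protein with probability
$\mathrm{logit}^{-1}(\alpha + \beta \log k)$, degree-0 proteins treated as
degree 1; $\alpha$ is calibrated by root finding so the expected fraction
matches the target within 0.01, and an unattainable combination of target
and $\beta$ raises a diagnostic error. Crucially, essentiality is a
function of degree only — never of MDSet membership — so any e-MDSet
contrast the analyses find is emergent rather than hard-wired, and the test
suite asserts recovery of the *planted* degree coupling while treating
e-MDSet contrasts qualitatively. Complex membership is degree-biased
(weight $k + 1$) so participation coefficients have nondegenerate support;
class labels are drawn from a softmax over per-class biases evaluated at
log-degree. One global seed feeds a fixed sub-stream per planter, so adding
a planter leaves earlier draws unchanged, and a config reproduces its study
byte for byte.

What the generator does *not* emulate: experimental false
positives/negatives and their bait/prey asymmetries, date-hub/party-hub
correlation structure, paralog redundancy in essentiality, curated-complex
size distributions, or cross-organism incongruence. Passing recovery tests
on this generator therefore demonstrates that the statistics detect the
signals they claim to detect at realistic scales — not that any particular
biological conclusion transfers to a real interactome.

## Numerical and design choices

* Identifiers are case-sensitive opaque strings; no symbol mapping.
  Mismatched namespaces surface as low-overlap warnings, not errors.
* Parsers drop self-loops and collapse duplicate/reversed pairs, reporting
  counts; normalization is idempotent. Comments start with `#`.
* All "essential" counts downstream use the intersection with network
  nodes, since genome-wide lists exceed any Y2H network.
* Degenerate inputs are contracts, not crashes: empty gene sets warn and
  propagate zero overlaps; empty degree bins and proteins without complexed
  partners report `NA`; an empty focal set yields zero counts with
  undefined ratios.
* Test problem sizes are chosen to keep the full suite fast while leaving
  the oracles meaningful: solver-vs-enumeration on 200 random graphs of up
  to 14 nodes, betweenness-vs-enumeration up to 30 nodes, calibration and
  recovery simulations at 400–2000 nodes with 200–2000 randomizations, and
  recovery rates over 20–50 seeds. The planted-signal strengths asserted in
  the suite (degree coupling $\beta = 1.5$; intra-complex boost 0.6 with
  focal bias 0.4 over 40 complexes of size 5–12; class bias 2.0 on `J`)
  are the documented strengths at which ≥ 90% single-test detection is the
  designed behavior.

## Known limitations

* Proving optimality on large networks with a dense low-degree core (e.g.
  pure preferential attachment with minimum degree 2) can exceed any
  reasonable time budget; results are then explicit upper bounds with a
  reported gap. Networks with many degree-1 proteins — the realistic Y2H
  regime — reduce well and usually solve exactly.
* A single MDSet is analyzed per run. The randomized-order mode probes
  non-uniqueness but the package deliberately does not enumerate all
  optima.
* The intra/inter null conditions on the catalog's size profile only; it
  does not preserve protein-level complex-membership counts.
* Betweenness uses exact unweighted geodesics; no approximation is offered,
  so very large networks pay the full all-pairs cost.
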
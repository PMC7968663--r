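---
title: "Methods: the drug-target network landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the drug-target network landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtnet)
```

# The model

dtnet analyses a directed graph $G = (V, E)$ in which nodes are drugs and
the macromolecular targets they bind, and each edge points from a drug to
one of its targets. Three structural features distinguish these networks
from generic bipartite graphs, and the package is organised around them:

* **Dual-role compounds.** Some entities (metal ions, nucleotide cofactors,
  endogenous signalling molecules) appear both as drugs and as targets of
  other drugs. A single such node destroys the drug/target bipartition, so
  `check_bipartite()` reports two separate facts: whether the role sets are
  disjoint (the operative criterion for these landscapes) and whether the
  undirected graph is 2-colorable at all, with an odd-cycle witness when it
  is not.
* **Heavy-tailed degrees.** The number of targets per drug ($k_{out}$) and
  drugs per target ($k_{in}$) both resemble truncated power laws
  $P(k) = A k^{-\gamma}$ with exponents below 2, i.e. dominated by a few
  large hubs.
* **A giant weak component plus a fringe.** One weakly connected component
  typically holds around 90% of nodes; most of the remaining components are
  single drug-target pairs (size 2), often targeting pathogen proteins.

# Ingestion and filtering

`parse_drugbank_xml()` reads a DrugBank-style full-database export. The
analysis set is restricted to *approved* drugs — operationalized as the
drug's group list containing the token `approved`, case-insensitively,
because group metadata is the only machine-readable proxy for regulatory
approval in that dialect; drugs with mixed group lists such as
`approved; withdrawn` are kept. Partners in the `enzyme`, `carrier` and
`transporter` categories are excluded by default: those proteins transform
or transport the drug rather than being functionally altered by it. Every
rejected record is counted and reported, never silently dropped. Targets
of all organisms are retained, since the isolated fringe of real networks
is largely made of antimicrobials and antivirals with pathogen targets.
Self-loops (a compound that is its own target) are kept by default and
removable via `filter_spec(drop_self_loops = TRUE)`.

Identifier handling: matching and deduplication use a canonical key
(whitespace-trimmed, case-folded); the original display strings are
preserved. Tables are sorted by drug then target key in C-locale order so
every downstream artifact is byte-reproducible.

Dual-role resolution in `build_network()` merges a drug and a target whose
canonicalized *names* coincide. Name-matching is conservative and
deliberate: the source database keys drugs and target proteins in
different identifier namespaces, so names are the only shared handle. The
merge is switchable (`merge_dual_roles = FALSE`) for strict two-namespace
analyses.

# Topology

Degrees, distributions and fits follow the standard conventions:

* `mean_degree()` is $2|E|/|V|$ (each directed edge contributes one
  adjacency to both endpoints).
* `degree_distribution()` computes $P(k)$ over nodes with $k \ge 1$;
  zero-degree nodes cannot enter a log-log fit and are counted in metadata
  instead. Both normalizations discussed for such data are available: all
  degree-positive nodes, or one role's nodes only (drugs for $k_{out}$,
  targets for $k_{in}$ — the default used by the pipeline).
* `fit_power_law()` defaults to ordinary least squares of $\log P(k)$ on
  $\log k$ with $k_{min} = 1$. The straight-line fit is the method most
  consistent with published exponents below 2 for this kind of data —
  discrete maximum likelihood rarely yields $\gamma < 2$ on unbounded
  support. The Clauset-style discrete MLE (Hurwitz-zeta normalization,
  truncated-series evaluation with an Euler-Maclaurin tail) is provided as
  a cross-check; tests require it to recover $\gamma \in \{1.5, 2, 2.5\}$
  within $\pm 0.05$ at $10^5$ samples.
* `clustering_profile()` implements $C_i = 2E_i / (k_i (k_i - 1))$ on the
  undirected view, with $C_i = 0$ when $k_i < 2$. On a strictly bipartite
  graph every $C_i$ is zero; non-zero clustering can only be introduced by
  dual-role merges. $C(k)$ is binned by exact degree, with no logarithmic
  binning.

# Centralities

All four measures are computed from first principles and validated against
independent oracles (explicit path enumeration, Floyd-Warshall, dense
eigendecomposition) in the test suite.

* **Degree centrality** is $k/(n-1)$.
* **Closeness** uses breadth-first distances and the Wasserman-Faust
  component-scaled convention for disconnected graphs:
  $C(v) = \frac{|R(v)|}{\sum_{u \in R(v)} d(u,v)} \cdot \frac{|R(v)|}{n-1}$,
  where $R(v)$ is the set of nodes that reach $v$ in the chosen sense.
  The damping factor keeps nodes of small components from outranking the
  giant component's nodes, which is what makes maxima on realistic
  landscapes land in the $10^{-2}$ range rather than near 1.
* **Betweenness** is exact Brandes-style shortest-path counting
  ($\sigma(s,t|v)/\sigma(s,t)$ summed over ordered pairs, endpoints
  excluded), normalized by $(n-1)(n-2)$; the undirected sense accumulates
  each unordered pair from both endpoints, which reproduces the
  conventional $2/((n-1)(n-2))$ normalization with the same divisor.
* **Eigenvector centrality** runs power iteration on the undirected
  adjacency of one weakly connected component, from the uniform positive
  vector, normalizing every step, until the max-norm change falls below
  `tol` (default $10^{-10}$, capped at `max_iter`, default $10^6$). A unit
  diagonal shift is applied internally: it leaves eigenvectors untouched
  while breaking the $\pm\lambda$ degeneracy of exactly bipartite
  components, for which plain power iteration would oscillate. Nodes
  outside the chosen component score 0 and the returned vector has unit
  Euclidean norm. Starting from the leading eigenvector itself — sometimes
  suggested — is circular; the uniform start is positive, hence
  non-orthogonal to the Perron vector, which guarantees convergence.

Direction conventions are explicit flags because the conventional choices
differ per metric on a near-bipartite directed graph: closeness defaults
to incoming-path distances (heavily drugged targets lead), betweenness to
the directed graph (only dual-role compounds can be interior vertices of
directed paths, which is why that ranking surfaces them), eigenvector to
the undirected view (pure drugs can rank highly only there). These
defaults are inferences about what makes the respective rankings
informative, not properties of the algorithms; all senses are switchable.

Rankings (`top_nodes()`, `top_coregulated()`) break ties lexicographically
by node id so reruns and platforms agree.

# Communities

`modularity_score()` computes Newman-Girvan modularity on the undirected,
unweighted view, with the resolution parameter multiplying the null-model
term: $Q = \sum_c \left[ e_c/m - \gamma_{res} (d_c/2m)^2 \right]$.
`cluster_multilevel()` is the two-phase multilevel heuristic: seeded
random visit order, each node moved to the neighbouring community with the
highest positive gain (gain ties broken by smallest community label),
passes repeated to exhaustion, then communities aggregated into
super-nodes (intra-community weight as self-loops) and the phase rerun
until $Q$ stops increasing. Isolated nodes stay singleton communities.
The per-level $Q$ trace is recorded and asserted non-decreasing. Because
the heuristic is stochastic, the partition is a function of
(graph, resolution, seed); `n_restarts` runs a best-of-N search when a
single run's local optimum is a concern. On graphs small enough for
exhaustive enumeration of all set partitions the seeded runs reach the
global optimum in at least 95% of runs, which is the regime the test
suite checks; no such guarantee exists at scale.

# Coregulation and the minimal covering drug set

Two drugs are *coregulated* when they are in-neighbours of at least one
common target. `drug_projection()` materializes the weighted drug-drug
graph (weight = number of distinct shared targets); partner counts are its
unweighted degrees.

`dominating_set_reduction()` seeks a small drug subset that keeps every
target covered: starting from all drug-role nodes, it draws one retained
drug uniformly at random per iteration (default 100,000) and discards it
if every target keeps at least one other in-neighbour, otherwise keeps it
— a failed draw still consumes an iteration. Read literally, a finite
random-draw budget can leave removable drugs behind, so the implementation
adds a deterministic final sweep (each retained drug attempted once, in
seeded random order), after which the result is provably minimal: removing
any single retained drug breaks coverage. The sweep is optional
(`minimality_sweep = FALSE`) for strict replication of the purely random
procedure. Dual-role nodes participate as drugs through their out-edges
and as coverage-requiring targets through their in-edges. The retained
set is a *minimal* covering set, not a minimum one; tests compare its size
against exact minimum set covers from exhaustive search on instances of
up to 12 drugs, where minimal sets are never smaller than the optimum.

# Enrichment

`enrich()` is the generic hypergeometric over-representation test against
a user-supplied term-to-node annotation table, with Benjamini-Hochberg
adjustment by default. No annotation corpus is bundled, and the background
set is an explicit required input, because every p-value is conditional on
it; the web-service-based annotation tooling used in the original analyses
of such networks is proprietary and out of scope.

# The synthetic generator

`generate_interactions()` emulates the features the analysis consumes:
truncated power-law out-degrees for drugs and in-degrees for targets
(direct inverse-CDF sampling on $[1, k_{max}]$), bipartite stub matching
with the larger stub total trimmed by random unit decrements (degrees
above 1 first), parallel-edge collapse, dual-role injection (randomly
promoted targets gain 1-3 out-edges), and appended isolated drug-target
pairs. Stub matching was chosen over preferential attachment because it
controls both marginal exponents directly, which is exactly what the
fitting stage estimates. Everything is deterministic given the seed.

`landscape_preset()` fixes the study-scale conditions: 2106 core drugs,
2593 core targets, $\gamma_{out} = 1.47$, $\gamma_{in} = 1.6$, 13
dual-role nodes and 94 isolated pairs, with $k_{max} = 32$ calibrated once
by matching the expected stub totals of the truncated laws to roughly
9300 edges. The preset reproduces scale, degree shape, near-bipartiteness
and component structure; it does **not** reproduce community structure or
covering-set sizes of curated data, because stub matching is maximally
random given the margins — real pharmacology concentrates drugs on
receptor families, which raises modularity and lowers the covering-set
fraction relative to a degree-matched random graph. Passing tests on the
preset therefore demonstrate correctness of the computations and fidelity
of the emulated margins, not biological realism of mesoscale structure.

Two details matter when interpreting generator-based checks. First,
parallel-edge collapse deflates realized hub degrees slightly, so
invariants are asserted on realized degrees. Second, stub-total balancing
trims whichever side oversamples; a parameter-recovery experiment for one
margin must therefore oversupply the *other* side (the recovery tests use
$\gamma_{in} = 1.2$ with a large target pool so the out-degrees under
study are never trimmed).

# Problem sizes and numerical choices

The test suite works at the scales where its oracles are exact:
path-enumeration betweenness on 200 random graphs of up to 10 nodes,
Floyd-Warshall distances up to 15 nodes, dense eigendecomposition at 12
nodes, exhaustive partition search up to 8 nodes, exhaustive set cover up
to 12 drugs, and 2-coloring enumeration up to 10 nodes. Statistical
checks use 50 generator seeds at 5000 drugs for exponent recovery and
$10^5$ samples for the MLE. The acceptance script runs the full pipeline
at the preset's paper scale (about 4900 nodes and 9700 edges), where every
stage completes in seconds on one CPU; the dense all-pairs distance matrix
is the one stage left off by default at that size.

Other numerical conventions: power-iteration tolerance $10^{-10}$ on the
max-norm step change; modularity gain threshold $10^{-12}$ to stop
floating-point jitter from cycling the local phase; Hurwitz zeta evaluated
with 2000 explicit terms plus an Euler-Maclaurin correction; all sorting
in C locale via radix order. Degenerate inputs are errors, not guesses:
empty graphs have no mean degree, all-zero degree vectors no distribution,
fewer than 3 support points no power-law fit, and a target with no drug
in-neighbour no covering set.

# Known limitations

* Exact betweenness is $O(|V||E|)$; the dense distance matrix is
  $O(|V|^2)$ memory. Both are fine at the tens-of-thousands-of-edges scale
  this package targets, but no approximate or sampled variants are
  provided.
* The multilevel heuristic inherits the resolution limit of modularity;
  small communities merged at resolution 1 may be separable at higher
  resolutions.
* The dual-role matcher is exact-name; synonyms or salt forms that differ
  textually will not merge.
* The covering-set procedure reports one minimal set per seed;
  characterizing the distribution of attainable sizes requires running
  several seeds, which the reduction's seed argument makes cheap.
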
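---
title: "Methods: hub roles, modality and link centrality in interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub roles, modality and link centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

This vignette documents the models, statistics and numerical choices behind
`hubnet`, in the spirit of a methods section: what each quantity is, which
assumptions it carries, and which design decisions were genuinely open.

## 1. The date/party question and avPCC

A *hub* is a high-degree protein, operationalised either as degree at or
above a fixed threshold (classically 5) or as the top *p* percent of nodes
by degree.  In top-percent mode we find the smallest degree cutoff that
captures at least *p* percent of nodes and keep **whole degree classes**:
the returned set may exceed *p* percent, because cutting inside a degree
class would be an arbitrary tie-break among topologically identical nodes.

For a hub *h* with partners *j*, the **avPCC** is the mean of the Pearson
correlations `pairwise_pcc(x_h, x_j)` over all partners with a usable
profile.  Partners missing from the expression matrix, or with fewer than
two shared finite conditions, or with a constant surviving profile, are
*excluded from the average and counted* (`n_partners_used`) rather than
scored zero: scoring them zero would drag every poorly measured hub towards
the "date" side, confounding data incompleteness with biology.

Classification applies a threshold (default 0.5): avPCC at or above the
threshold is *party*, below is *date*.  The boundary is closed on the party
side; equality at the threshold is not specified by the conventional
definition, and closing the party side matches the phrasing "above the
threshold is party" while keeping the rule deterministic.  avPCC is always
computed against a single expression data set: classifying a hub as party
if it exceeds the threshold in *any one* of several data sets (the original
rule) makes the call dependent on the number and size of data sets
examined, which is one of the methodological weaknesses this package is
built to probe.

## 2. Modality of the avPCC distribution

Claims that hub avPCC values are bimodal motivate the date/party split, so
the package offers two complementary views.

**Kernel densities at varying widths.**  `kde_density()` evaluates a
Gaussian kernel estimate with kernel standard deviation *h* on a 512-point
grid spanning `[min - 3h, max + 3h]`; `count_modes()` counts strict
interior maxima, collapsing plateaus.  Apparent bimodality that exists only
in a narrow band of bandwidths is a smoothing artefact, not a population
feature; `mode_count_sweep()` makes that explicit.  There is no canonical
bandwidth grid for this diagnostic, so the sweep is a user argument rather
than a default baked into the code.  Numerically, density values below
`1e-10` of the maximum are treated as zero before mode counting:
floating-point wiggle in tails of order `1e-300` would otherwise register
as spurious modes.

**Hartigan's dip.**  The dip of a sample is the smallest sup-norm distance
between its empirical CDF and any *unimodal* CDF — a distribution function
convex up to its mode and concave afterwards, with a jump permitted at the
mode.  Zero means perfectly unimodal; well-separated two-cluster samples
approach the maximum of 1/4, and the minimum attainable value for n
distinct points is 1/(2n).  The implementation (in C++) refines a modal
interval: on the current window it builds the greatest convex minorant of
the lower staircase corners and the least concave majorant of the upper
corners, measures the largest gap between the two hull curves at hull
vertices (the u/l corner asymmetry grants the one free jump at the mode),
and either stops — the accumulated outside deviations already dominate — or
shrinks the window to the gap's location, accumulating the deviations of
the empirical CDF from the hulls outside the new window.  The dip is half
the final accumulated value.  Two subtleties motivated the test oracle
shipped with the package: the convex and concave pieces are *coupled*
through slope persistence across the mode, so any decoupled "fit each side
separately" shortcut is too permissive; and tied values let the fitted CDF
jump at a tied mode, absorbing the full tie mass.  The test suite therefore
checks the implementation to 1e-9 against an independent linear-programming
oracle (a small two-phase simplex over piecewise-linear unimodal CDFs with
the mode searched over data points, gap midpoints and both tails) on a
randomised small-sample suite, besides the exact pins dip({0,0,1,1}) = 1/4
and dip({0,1,2,3}) = 1/8.

The dip is location/scale invariant but *not* invariant under general
monotone transforms: any distinct-valued sample can be monotonically mapped
onto an equally spaced grid, whose dip is the minimal 1/(2n).  The tests
assert the affine invariance that actually holds.

**Bootstrap p-value.**  `dip_pvalue()` draws `n_bootstrap` uniform(0,1)
samples of the same size — the canonical reference null for the dip test,
as the uniform is the "flattest" unimodal distribution — and reports
`(1 + #{D_b >= D_obs}) / (1 + B)`.  The add-one rule avoids reporting p = 0
at finite replicates.  10,000 replicates give stable p-values; tests use
fewer where only calibration, not precision, is at stake.

## 3. Betweenness, path length and deletion experiments

Betweenness uses the unordered-pair, unnormalised convention: each
connected pair {s, t} distributes unit weight equally over all shortest s–t
paths, and a node (excluding endpoints) or link accumulates the weight of
the paths through it.  Two exact identities follow and are asserted on
every test graph: node betweennesses sum to Σ(d(s,t) − 1) and link
betweennesses to Σ d(s,t), over connected unordered pairs.  A corollary
worth singling out: the only link at a degree-1 node lies on exactly the
N−1 shortest paths from that node to the rest of a connected network, so
pendant edges carry betweenness exactly N−1 — the origin of the spike seen
in link-betweenness distributions of sparse interactomes, which is a
finite-size bookkeeping effect and not biology.  The synthetic generator
plants pendants precisely so this spike exists in test data.

**Characteristic path length (CPL)** is the mean shortest-path length over
finite pairs only.  A graph with no finite pair yields `NaN`, never 0 —
reporting 0 would make total fragmentation look like perfect connectivity.
Note the finite-pair convention means CPL can *drop* when a removal
disconnects distant parts; deletion trajectories therefore also record
component counts and the largest component size.

**Deletion experiments** remove targets one at a time in decreasing
*original* degree (ties by node name) and record CPL and component
statistics after every removal.  Original rather than recomputed degree
makes the order independent of the deletion path and hence reproducible;
recomputed-degree ordering is a different experiment the data does not
force on us.  `exclude_top_bc()` implements the outlier probes: drop the k
highest-betweenness targets, or drop targets whose betweenness exceeds the
maximum over a reference set (e.g. the party hubs).  The scientific point
being tested: if removing a date-hub set fragments the network but the
same set minus one or a few extreme-betweenness members does not, the
"date hubs are global connectors" conclusion rests on those few proteins,
not the class.

## 4. Communities and role cartography

Communities maximise the resolution-tunable Potts/modularity quality
\[
Q_\gamma = \sum_{ij}\Big[\frac{A_{ij}}{2m} -
\gamma\,\frac{k_i k_j}{(2m)^2}\Big]\,\delta(c_i, c_j),
\]
with the configuration-model null — the standard Reichardt–Bornholdt
formulation, equal to Newman–Girvan modularity at γ = 1.  The sum runs over
ordered pairs including i = j in the null term, which is what makes the
one-community partition score exactly 0.  Optimisation is greedy local
moves plus aggregation (Louvain, via igraph, at the given resolution),
followed by an in-package single-node local-move refinement sweep in a
seeded random node order, restarted `n_restarts` times; the best partition
additionally must beat the all-singletons and one-community baselines.
Tiny graphs expose a real weakness of aggregation-only optimisation —
deterministic merges can land in a local optimum that single moves cannot
escape — which is why the randomised refinement runs from both the Louvain
output and a singleton initialisation; the test suite checks the result
attains the exhaustively enumerated optimum on all connected graphs of up
to 8 nodes in a fixed random suite.  Partition labels are canonicalised
(decreasing size, ties by smallest member) so partitions are comparable
across runs.  γ is exposed everywhere: community counts grow with γ, and
conclusions about roles should be checked across resolutions rather than
at a single magic value.

Role statistics follow the classical cartography.  Within-community degree
is normalised per community, \(z_i = (\kappa_i - \bar\kappa_c)/\sigma_c\),
with the *population* standard deviation (the community is the whole
population, not a sample).  If σ_c = 0 — every member has the same
within-community degree, common in small or ring-like communities — z is
set to 0: the node is exactly average in its community, and the choice
keeps the per-community zero-mean identity true vacuously.  The
participation coefficient is \(P_i = 1 - \sum_s (\kappa_{is}/k_i)^2\), 0
for purely internal nodes, with P = 0 for isolated nodes.  The seven roles
split non-hubs (z < 2.5) at P = 0.05 / 0.625 / 0.80 and community hubs
(z ≥ 2.5) at P = 0.30 / 0.75, boundaries closed on the lower-numbered
side; these numeric boundaries are the published cartographic convention —
they are admittedly arbitrary region borders, which is why the package
reports raw (z, P) alongside the role label.

**Partition comparison** across data sets prunes each community to the
common node set, then averages the per-node Jaccard distance
\(1 - |g_1 \cap g_2| / |g_1 \cup g_2|\); role overlap is the share of
common nodes keeping the same role label.  Pruning first is essential:
without it, nodes absent from one data set would masquerade as community
disagreement.

## 5. Functional similarity of interactions

Annotations are ancestor-closed (a protein annotated with a term carries
all its ancestors), and each term is weighted by its set information
content over the annotated universe P:
\(\mathrm{SIC}(t) = -\log(|P_t|/|P|)/\log|P|\), natural logarithm.  The
normalisation by log|P| keeps SIC in [0, 1] and comparable across
universes of different size; the base cancels in the similarity ratio.
The functional similarity of two proteins is the SIC-weighted
intersection-over-union of their closed sets.  Degenerate corner: when
every term in the union has SIC 0 (e.g. a one-leaf ontology where every
term annotates everything), the ratio is 0/0; the package returns 1 for
identical sets and 0 otherwise, the limit consistent with both the
"identical sets are maximally similar" and "a shared universal root means
nothing" requirements.

`betweenness_similarity_correlation()` correlates log link betweenness
with either interactor expression PCC or functional similarity, pairwise
over links where the target is defined and betweenness is positive, and
reports the Fisher z-score \(\mathrm{atanh}(r)\sqrt{n-3}\) with a
two-sided normal p-value.  Pearson and Spearman are both available since
the log-betweenness scale is heavy-tailed; on monotone constructions they
agree in sign.

## 6. What the synthetic data does and does not emulate

The generators define the study conditions for all tests:

- `planted_modular_graph()` — a stochastic block model with within/between
  probabilities `p_in`/`p_out` plus uniformly attached degree-1 pendants.
  Recovery tests use sizes (30, 30, 30) with p_in = 0.4, p_out = 0.02, an
  assortative regime where the planted partition is clearly detectable;
  date/party recovery uses 40 planted hubs (ρ = 0.8 vs 0.0, one per
  12-node community, p_in = 0.8, p_out = 0.005) at 100 conditions; the
  link-similarity analysis uses 12 communities of 40 nodes tuned to ≈5,000
  links.
- `simulate_expression()` — partners mix their assigned hub's standard
  normal profile with independent noise, \(x_j = \rho x_h +
  \sqrt{1-\rho^2}\,\varepsilon_j\), so E[PCC] ≈ ρ and avPCC is a nearly
  unbiased, concentrated estimate of ρ.  Any monotone link between the
  planted parameter and avPCC would do for the analyses; linear Gaussian
  mixing is the simplest with an exact expected correlation.  Partners are
  assigned to the nearest designated hub by graph distance (ties to the
  first hub in sorted order), unreachable nodes get pure noise.
- `simulate_ontology()` — a random tree of fixed depth; each protein draws
  one leaf, preferring its community's leaf with probability `p_bias`.
  Community-biased annotation makes cross-community links simultaneously
  high-betweenness and low-similarity, which is the qualitative structure
  behind the negative betweenness–similarity correlation.

Real interactomes differ in ways these generators deliberately ignore:
heavy-tailed degree distributions, overlapping and nested complexes,
correlated assay noise and ascertainment bias, non-Gaussian expression, a
DAG (not tree) ontology with multiple annotations per protein.  Passing
tests therefore demonstrate algorithmic correctness and the stated
statistical behaviour under the planted model — not that any biological
conclusion transfers to a particular data set.  One global integer seed
per generator call, propagated through R's RNG, makes every synthetic
object byte-reproducible.

## 7. Numerical choices and problem sizes

- Dip: exact rational-free floating arithmetic on hulls; termination is by
  the monotone modal-interval shrink, with an iteration cap that is never
  reached in practice.  Samples must have n ≥ 4 and at least two distinct
  values.
- Bootstrap calibration tests use 500 trials × 500 replicates at n = 200,
  a size at which the suite's null rejection rate at α = 0.05 is stably
  inside [0.02, 0.09] while the whole suite stays fast.
- Betweenness oracle comparisons run on 200 random graphs of up to 30
  nodes (tolerance 1e-9); exhaustive community optima on connected graphs
  of up to 8 nodes (Bell(8) = 4140 partitions).
- Greedy refinement accepts a move only if it improves quality by more
  than 1e-12, avoiding tie-cycling; restarts differ only through the
  seeded RNG, so `detect_communities()` is deterministic given its seed.
- The pipeline (`run_full_analysis()`) writes each stage as a TSV plus one
  JSON report embedding the configuration and seeds; reruns with the same
  configuration are byte-identical, which the tests assert.

## 8. Known limitations

- The Louvain-plus-refinement optimiser is a heuristic; optimality is
  verified only at small scale, and at realistic scale the usual caveats
  about modularity's resolution limit and degenerate near-optimal
  landscapes apply.
- The dip bootstrap assumes exchangeable, effectively continuous data;
  heavily tied avPCC values (e.g. from very few conditions) make the
  uniform null conservative.
- SIC-based similarity inherits annotation-corpus bias: sparsely annotated
  proteins get noisy similarities, and the toy generator's one-leaf-per-
  protein annotation is far sparser than real corpora.
- CPL on fragmenting graphs is reported over surviving finite pairs; it is
  not a monotone damage measure on its own and should be read together
  with the component statistics, as the deletion tables do.
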
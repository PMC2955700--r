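---
title: "Laying out fragmented networks with fragnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laying out fragmented networks with fragnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 5)
set.seed(1)
```

## The problem

Similarity networks in systems biology — genes linked by pathway
co-membership, proteins by physical interaction, markers by correlated
behaviour — are usually built by thresholding a matrix of pairwise scores.
The resulting graphs are rarely connected: they shatter into dozens or
hundreds of small components. Classical force-directed layouts
(Fruchterman–Reingold and relatives) only see the edges, so they place those
components arbitrarily relative to each other. Two unrelated groups of genes
can end up adjacent on the page, and readers will infer a relation that does
not exist.

fragnet addresses this with a two-stage layout. Given an undirected network
$G = (V, E)$ with components $V_1, \dots, V_p$ and a $|V| \times |V|$
dissimilarity matrix $D = (d_{ij})$:

1. **Internal layout.** Each component is laid out independently with the
   Fruchterman–Reingold (FR) algorithm, and its coordinate system is centered:
   $\sum_{v_i \in V_k} \mathbf{v}_i = 0$.
2. **Placement.** Each component is then treated as a rigid body — it may be
   translated and rotated but not deformed — and the bodies are arranged so
   that proximity between components reflects the dissimilarities between
   their member vertices.

The vertex positions never stop honouring the component structure (a chain
stays a chain), while the global arrangement carries the extra information in
$D$. The dissimilarities can come from the same scores that defined the edges
or from an entirely different source (in our protein-interaction example
below, functional similarity places components whose *edges* are physical
interactions).

## The physical model (exact engine)

The placement problem is modelled as a spring system. Vertices of *different*
components are joined by springs whose rest lengths are the dissimilarities;
by Hooke's law the force a spring exerts on vertex $i$ at global position
$\mathbf{g}_i$ is

$$\mathbf{F}_{ij} = \bigl(d_{ij} - \lVert \mathbf{g}_i - \mathbf{g}_j \rVert\bigr)
  \frac{\mathbf{g}_i - \mathbf{g}_j}{\lVert \mathbf{g}_i - \mathbf{g}_j \rVert},
  \qquad
  \mathbf{g}_i = R(\phi_k)\,\mathbf{v}_i + K \mathbf{c}_k,$$

where $\mathbf{c}_k$ and $\phi_k$ are the center and orientation of the
component containing $i$, and $K$ is a global scaling factor ($K = 1$ in the
exact engine). With equal vertex masses and infinite friction (no momentum),
each iteration moves component $k$ by a step proportional to the mean force
on its vertices and rotates it by a step proportional to the net torque over
its moment of inertia $\sum_i \lVert \mathbf{v}_i \rVert^2$. The simulation
stops when the largest per-vertex force drops below `force_tol`.

Two implementation notes:

* **Springs within a component cancel.** Summing forces over *all* vertex
  pairs or over cross-component pairs only gives the same translation and
  rotation steps: internal spring pairs obey Newton's third law, and their
  torques vanish because the force is parallel to the separation vector.
  The package sums cross-component pairs only and asserts the equivalence in
  its test suite on random instances.
* **Step normalization.** Each vertex carries one spring per vertex outside
  its component, so net forces grow linearly with that count and a fixed
  step constant would diverge on larger instances. The applied step is
  therefore divided by the number of outside vertices, which makes the
  update stable independently of instance size while preserving the
  proportionality of the step law. With the default
  `step_c = step_phi = 0.1` the total stress
  $\sum_{i<j}\,(d_{ij} - \lVert \mathbf{g}_i - \mathbf{g}_j \rVert)^2$
  (cross-component pairs) decreases monotonically on the instances we test.

Coincident global positions make the spring direction undefined; the package
substitutes a unit direction chosen by a deterministic hash of the vertex
pair, so results remain bit-reproducible regardless of evaluation order.

## The fast approximation

Simulating all $O(|V|^2)$ springs at every step is slow. The approximation
replaces vertex-level placement with component-level placement:

1. **Component distances.** $\delta_{kl}$ is the mean of $d_{ij}$ over all
   cross pairs $v_i \in V_k$, $v_j \in V_l$ — the average-linkage distance
   of hierarchical clustering.
2. **MDS.** The centers $\mathbf{c}_k$ are embedded in the plane by SMACOF,
   the majorization algorithm for the raw stress
   $\sum_{k<l} (\delta_{kl} - \lVert \mathbf{c}_k - \mathbf{c}_l \rVert)^2$.
   Majorization guarantees the stress never increases between iterations —
   the test suite asserts this on every run. Initialization is seeded-random
   in the unit disk by default; a classical-scaling (Torgerson) start is
   available via `fragviz_config(mds_init = "torgerson")` and is the natural
   choice when $D$ is believed to be nearly Euclidean.
3. **Scaling.** MDS sees only centers, so component sizes must be bridged to
   center spacing: $K = \bar v / \bar g$, the ratio of the mean
   intra-component pairwise vertex distance $\bar v$ (averaged over
   components with at least two vertices; the quantity is undefined for
   singletons) to the mean pairwise center distance $\bar g$. Centers enter
   global coordinates as $K\mathbf{c}_k$, which sizes the components "as
   large as possible without too much overlap": average spacing equals
   average component size. A bounding-circle overlap count is reported as a
   diagnostic; no overlap removal is applied.
4. **Rotation.** Orientations are optimized by sweeping over components in
   ascending index order and applying the torque-derived rotation step of
   the exact engine, computed in the scaled system with the original
   $d_{ij}$ as rest lengths (positions are scaled; rest lengths are not).
   To escape local minima the step direction is *reversed* with probability
   $e^{-1/T_t}$, where the temperature decays geometrically per sweep
   ($T_t = t_0 \cdot \gamma^{t-1}$, default $t_0 = 1$, $\gamma = 0.9$, 50
   sweeps). A reversed move is accepted unconditionally — deliberately
   worsening moves are the point of annealing — while a regular move is
   reverted if it fails to lower the stress, so with $t_0 = 0$ the phase is
   a strictly greedy descent. Reflections are not searched: components may
   rotate but never mirror.

Two degeneracies are handled exactly rather than approximately. A network
with a single component skips placement entirely, so the pipeline output is
bit-identical to a plain whole-graph FR layout with the same seed (the
per-component seed of component 1 *is* the user seed by construction). A
network of isolated vertices has only trivial internal layouts; the
component distances equal $D$, no scaling or rotation applies ($K = 1$ with
a warning when called directly), and the result is exactly SMACOF MDS of
$D$.

## Internal layouts

`fr_layout()` follows the classical formulation: attraction $d^2/k$ on
edges, repulsion $k^2/d$ between all pairs, ideal length
$k = \sqrt{\text{area}/n}$ on a unit-square frame, displacement capped by a
linearly cooling temperature, initial positions uniform in the unit square
from the per-component seed. Two deliberate choices:

* The initial displacement cap is 0.3 frame widths rather than the
  customary 0.1. Small cycles started from a crossed random configuration
  otherwise freeze into the fold; the hotter start lets them unfold, and a
  6-cycle then reaches equal edge lengths (within 5%) from any seed we test.
* Positions are not clamped to the frame (the layout is recentered
  afterwards, so the frame only sets the length unit). Edge lengths at
  equilibrium are therefore about $0.5$–$0.9$ layout units for the small
  components typical of fragmented networks — a scale worth keeping in mind
  when interpreting $K$, see below.

Default 500 iterations per component: components in thresholded biological
networks are small (tens of vertices at most), so convergence is cheap.

## Evaluation

`layout_correlation()` scores a layout by the Pearson correlation between
the entries of $D$ and the Euclidean distances of the corresponding vertices
in the layout, over **all** vertex pairs, intra- and inter-component alike.
It is invariant to rigid motions and uniform scaling of the layout; an
arbitrary placement scores near zero. `fragmentation_sweep()` runs the
experiment design that probes fragmentation: thresholding one similarity
matrix at increasing cutoffs (isolated vertices kept, so the vertex set is
fixed), laying out each network with several methods under shared seeds, and
reporting mean correlation, component count and average local clustering
coefficient per threshold. `nearest_component_links()` produces the overlay
of each component's most similar components, rendered as background lines
whose widths scale with similarity (`render_svg()`, `autoplot()`).

## Synthetic benchmark instances

No real gene-network distance matrix ships with the package; instead two
generators produce instances with planted ground truth whose statistical
shape mimics thresholded biological similarity data.

`planar_instance()` samples group centers at least `between_spread` apart
in a square of side `2 * between_spread` (rejection sampling; a regular
circle is the fallback), scatters points around them with Gaussian spread
`within_spread`, and uses the *exact* Euclidean distances as $D$ — so $D$
is perfectly planar-embeddable (MDS can reach zero stress, useful for
recovery tests) and satisfies the triangle inequality exactly. The network
thresholds the similarity $s = 1/(1+d)$ at a connection radius of
`0.75 * within_spread`, which shatters each group into several components
of roughly 2–10 vertices on the default 60-point instance — the degree of
fragmentation seen in thresholded gene-function networks (our motivating
examples have 72 vertices in 28 components and 240 in 54). Defaults:
4 groups, `within_spread = 0.5`, `between_spread = 4`.

`block_dissimilarity()` builds the complementary non-Euclidean case: a
near-ultrametric block matrix with `d_within` inside blocks, a scalar or
block-level matrix of `d_between` across blocks, and bounded uniform jitter.
Thresholding midway between the two levels makes every block one clique
component, so the component structure equals the planted structure by
construction.

What these generators do *not* emulate: heavy-tailed component-size
distributions, missing or censored similarity values, and the systematic
non-metricity of score matrices assembled from heterogeneous databases.
Passing tests on these instances therefore demonstrates correctness of the
machinery and qualitative behaviour (informed placement beats arbitrary
placement; the approximation tracks the simulation), not performance claims
on any particular real data set.

### When do the two engines agree?

The scaling rule forces mean center spacing to equal mean component size
$\bar v$, while the exact engine spaces components at the scale of $D$
itself. The engines therefore produce comparably good layouts exactly when
those scales are commensurate — when typical dissimilarities are of order
$\bar v \approx 0.5$–$1$ layout units, as they are for bounded score-derived
distances (Jaccard-type distances live in $[0, 1]$). Our agreement
benchmark uses block instances in that regime: 14 blocks of 2–3 vertices,
`d_within = 0.3`, block distances spread over $[0.5, 1.0]$ from random
planar block centers, jitter 0.05. On Euclidean instances whose distances
dwarf the layout unit, the approximation compresses the global structure
(small $K$) and its correlation falls below the exact engine's — a real
limitation of the rule of thumb, not of the implementation.

## A worked example

```{r example, eval = FALSE}
library(fragnet)

inst <- planar_instance(seed = 1) # 60 vertices, 4 planted groups
lay <- fragviz_layout(inst$network, inst$D, seed = 1)
glance(lay)
# fragmented into ~26 components; correlation ~0.5 vs ~0.1 for plain FR
fr <- run_layout_method("fr", inst$network, inst$D, seed = 1)
layout_correlation(fr, inst$D)$pearson_r

# overlay the two most similar components of each component
delta <- component_distances(inst$D, find_components(inst$network))
autoplot(lay, links = nearest_component_links(delta), label_components = TRUE)
```

## Numerical choices and problem sizes

* SMACOF: relative stress-change tolerance `1e-8`, at most 300 iterations;
  distances below `1e-12` are treated as zero in the majorization weights.
* Exact engine: `force_tol = 1e-4` (units of $D$), at most 2000 iterations;
  a divergent state (non-finite positions) aborts with an error rather than
  returning garbage.
* Ties in the nearest-component overlay break toward the lower component
  index; the rotation sweep visits components in ascending index order.
* The test suite exercises instances of up to 60 vertices (oracle
  equivalence on 50 random instances, 20 agreement instances, a 5-point
  threshold sweep at 20 repetitions, a 200-vertex null check with 100
  random layouts) — sizes chosen so the full suite completes in a few
  minutes on one CPU while still covering the fragmentation regime of
  interest.
* Every random draw is seeded; identical inputs and seeds give bit-identical
  coordinates, and the per-component FR seeds are derived from the user seed
  so that component 1 reproduces the user seed exactly.

## Known limitations

* Rigid components are the design premise: when a component's internal FR
  shape poorly matches the metric structure of its vertices in $D$, the
  global correlation is bounded by that mismatch. MDS on the full matrix
  will score higher on strongly Euclidean data.
* The scaling rule of thumb trades global distance fidelity for readability
  (components sized like their spacing); see the agreement discussion above.
* The rotation phase optimizes one angle at a time and can settle in joint
  local minima; annealing mitigates but does not eliminate this.
* Only connected undirected simple graphs without edge weights are
  supported inside components; directed and weighted variants are out of
  scope.
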
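---
title: "Methods: higher-order topology of cortical connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: higher-order topology of cortical connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotopo)
```

# The model

neurotopo analyses a directed synaptic connectome — a simple directed
graph on neurons, with integer synapse counts as edge weights — through
its *directed flag complex*. A directed simplex of dimension $d$ is a
motif of $d + 1$ distinct neurons that admits a numbering from $0$ (the
*source position*) to $d$ (the *target position*) such that a connection
runs from every lower- to every higher-numbered member. Every edge is a
1-simplex; a feed-forward triangle is a 2-simplex. Because the flag
complex is determined entirely by the adjacency structure, enumeration
needs only the graph, and the motif statistics scale to networks with
hundreds of thousands of edges.

The package implements, around this primitive:

* **Divergence profiles.** The fraction of *unique* neurons occupying
  each position of a dimension's simplices, normalised to the source
  position. A rising profile means few shared sources feed many distinct
  targets — divergent feed-forward flow. The *target dimension* of a
  network is the dimension where this trend peaks (ties resolve to the
  lower dimension: the more conservative, smaller motif).
* **Inhibition relative to simplices.** Sparse tensors counting synapses
  between each simplex position and each interneuron, their
  position-summed reductions $M'_{ei}$, $M'_{ie}$, and the disynaptic
  inhibition matrix $I = M'_{ei} M_{ie}'^{\top}$, whose $(i, j)$ entry is
  the synapse-weighted number of E→I→E paths from simplex $i$ to simplex
  $j$. Its symmetry is scored as
  $\mathbb{S} = \mathrm{var}(I - I^{\top}) / \mathrm{var}(I)$ over
  off-diagonal entries: $0$ for perfect symmetry, $2$ in expectation for
  statistically independent entries.
* **Disinhibition.** A hypergeometric test for interneurons whose
  out-degree onto other interneurons exceeds a null that preserves each
  neuron's total out-degree and the pooled inhibitory target fraction.
* **Simplex groups.** Louvain clustering of the source-side
  (positions 0–2) and target-side (last three positions) overlap
  matrices into *source groups* and *target groups*, and a group-level
  network of mean overlap (excitation) and shuffled-control-exceedance
  fractions (inhibition).
* **Neighbourhood complexity.** The Wasserstein-1 distance between the
  degree distribution of a node's neighbourhood subgraph and that of the
  same node's neighbourhood in a configuration-model control.
* **Rewiring.** A plasticity-inspired rule that removes edges confined
  to low dimensions and adds edges between strong high-dimensional
  participants.

# Conventions and parameter choices

**Distance model.** Connection probability decays exponentially with
soma distance, $P(d) = a\,e^{-d/b}$, with amplitude $a \in (0, 1]$ and
length constant $b > 0\ \mu m$, fitted separately for the four
synapse-class pathways (E→E, E→I, I→E, I→I). The decay convention is
deliberate: a growing exponential cannot remain a probability at large
distances, and with the decay form $P(d) \le a \le 1$ everywhere, the
parameters always define a valid model. Fits use nonlinear least squares
on per-bin empirical probabilities (20 µm bins up to the 99th percentile
pair distance, bins weighted by pair counts) rather than a likelihood
fit, because the binned probabilities are the quantity the model is
meant to reproduce. The bin width is configurable; 20 µm resolves the
~100 µm length constants of cortical connectivity with several points
per e-fold while keeping thousands of pairs per bin at the problem sizes
used here.

**Reciprocal pairs.** Reciprocal connections are stored as two
independent directed edges, and a reciprocally connected pair yields one
1-simplex per direction — standard directed flag complex semantics.

**Subvolume grids.** Excitatory neurons join a subnetwork when their
soma falls inside a rectangle in the horizontal plane, with half-open
bounds `[min, max)` so that a grid with shift equal to the rectangle
width tiles the volume and assigns every neuron exactly once; the
vertical axis is unbounded. Inhibitory neurons are by default admitted
regardless of position, because they are analysed relative to the
excitatory simplices and clipping them to the rectangle would create
artificial edge effects; a finite margin variant exists for volumes
where the full inhibitory population would be disproportionate.

**Symmetry and correlations on off-diagonal entries.** The diagonal of
$I - I^{\top}$ is identically zero and the diagonal of $I$ measures
self-inhibition, not inhibition *between* simplices, so both the
symmetry score and the overlap–inhibition correlations are computed over
off-diagonal entries only. Population (not sample) variances are used;
the ratio is identical under either convention.

**Synapse weighting.** The disynaptic matrix counts synapse-weighted
paths by default, matching the definition of the tensors it is built
from; a `binarize` flag switches to counting interneuron partners, the
variant relevant when per-connection synapse counts are unavailable or
untrusted.

**The disinhibition test.** For interneuron $j$ with total out-degree
$d_j^{ttl}$ and inhibitory out-degree $d_j^{inh}$, the p-value is the
hypergeometric survival probability of drawing at least $d_j^{inh}$
inhibitory targets when $d_j^{ttl}$ targets are drawn without
replacement from the pooled $\sum_i d_i^{ttl}$ slots containing
$\sum_i d_i^{inh}$ inhibitory ones. The number of draws must be the
neuron's own out-degree for the null to "keep the total outdegrees of
individual neurons"; a version that omits the draw count is not a
well-defined distribution, so this is the interpretation implemented.
The default flagging threshold ($p \le 10^{-6}$) isolates the clearly
disinhibitory tail at realistic interneuron counts.

**Group-level inhibition percentile.** Whether a simplex pair's
disynaptic strength is "significant" is decided against the 95th
percentile of a column-shuffle ensemble. The comparison is per pair by
default — each pair against its own shuffle distribution — which is the
stricter reading; a pooled-percentile option exists for small shuffle
ensembles, where per-pair order statistics are noisy.

**Column-shuffle null.** The interneuron columns of $M'_{ei}$ and
$M'_{ie}$ are permuted by two *independent* uniform permutations
(independence is the weaker, safer null). Each simplex keeps its
inhibitory in- and out-totals exactly; note that the global sum of $I$
is *not* invariant under independent permutations, because the pairing
of E→I and I→E columns changes.

**Neighbourhood complexity.** The degree flavour inside the
neighbourhood subgraph is total degree (in + out) by default,
configurable to in- or out-degree. Equal-size samples reduce the W1
distance to the mean absolute difference of sorted samples; unequal
sizes use the CDF-difference integral. One configuration-model instance
is used per run by default; the caveat worth knowing is that
neighbourhood *sizes* can differ slightly between graph and control —
double-edge swaps preserve in- and out-degrees but not the number of
reciprocal partners, which affects the in∪out union size.

**Rewiring.** Within a step, edge dimensions and participation counts
are computed once on the pre-step graph, matching the stated order of
operations (classify, remove, then add); removal does not feed back into
the addition weights. Pairs disconnected by this step's removals are
eligible for addition — they are unconnected at addition time. Additions
are sampled without replacement by sequential draws with
renormalisation. The reference schedule is one step at the middle
dimension threshold ($D = 3$, $m = 2000$) followed by three source-side
steps ($D = 2$, $m = 10000$, positions $\{0, 1\}$); the edge fraction
this rewires depends on the host graph and is reported, not asserted.

**Activity synthesis.** Target pairwise correlations are injected with
per-edge shared latent Gaussian factors, which makes any monotone
profile feasible without requiring a globally positive-definite target
matrix (the direct Gaussian construction is also available and errors
when its matrix is not PD). Traces are shifted per node to be
nonnegative, which leaves Pearson correlations untouched. Z-scoring of
correlations happens within session against all valid pairs before
pooling across sessions; raw correlations are emitted alongside.

# What the synthetic generator emulates — and what it does not

The generator produces the statistical structure the analyses assume: a
uniform soma point cloud in a cortical slab; exponential
distance-dependent connectivity per pathway; planted divergent
feed-forward motifs (source positions drawn with reuse from a small
pool, target positions mostly unique from a large pool, so the
unique-fraction profile rises towards the target; pool members are
placed in a canonical order within each motif, so no two motifs plant
reciprocal edges between shared sources); inhibitory wiring whose E→I
probability increases towards source positions and I→E probability
towards target positions, optionally with more synapses per connection
on strongly biased edges; partial E–I reciprocity (`reciprocity`,
default 0.4: a sampled E→I connection is mirrored I→E with that
probability, reflecting the strong overexpression of bidirectional
pyramidal–interneuron pairs in cortical tissue — it is this reciprocity
that couples disynaptic inhibition to shared sources); a disinhibitory
interneuron subclass wired preferentially onto other interneurons; and
activity traces whose pairwise correlation rises with edge simplex
dimension.

It does **not** emulate morphology (no axon/dendrite geometry, no
layer structure, no cell-type-specific subcellular targeting), synapse
sizes, proofreading artefacts, or the marginal degree distributions of
any specific electron-microscopy reconstruction. Passing tests on this
generator therefore show that the statistics *recover planted structure
of the asserted kind at desk scale*; they do not certify effect sizes
on real reconstructions.

Default study conditions used by the test suite and the worked
examples: 300 excitatory and 80 inhibitory neurons in a
400 × 300 × 400 µm slab (matching one analysis rectangle's footprint);
pathway parameters $a = 0.08$–$0.15$, $b = 100$–$120$ µm, typical of
local cortical connectivity; 25 planted motifs of dimension 5 over a
source pool of 4 and target pool of 120; inhibitory bias strengths 3;
disinhibitory fraction 0.15 (the observed share of inhibitory-targeting
cells in cortex is 15–17%). The distance-model recovery fixture uses
2000 neurons so that the 10% parameter-recovery tolerance is binding
rather than generous. The acceptance-scale Erdős–Rényi control uses the
full 14559 nodes and 819869 edges, enumerated to dimension 4 without
listing, which runs in seconds in compiled code.

# Numerical choices

* Simplex enumeration is compiled (Rcpp): ordered cliques are extended
  through sorted-array intersections of out-neighbourhoods; counting is
  exact, and listing above a guard dimension (default 10) requires an
  explicit opt-in because tuple lists, unlike counts, can exhaust
  memory.
* The triad-census estimator samples connected triads uniformly by
  drawing an undirected edge and a third node, rejecting disconnected
  triads, and accepting with probability inversely proportional to the
  triad's undirected edge count; estimates scale class frequencies by
  the exact connected-triad total (wedges minus twice the triangles).
  Exact enumeration is used whenever the total is at most the sample
  budget.
* Louvain clustering runs on the overlap matrix with zeroed diagonal
  (self-overlap is not affinity); it is greedy, so a seed fixes the
  result, and a restart option keeps the best-modularity partition.
* Zero-variance guards: symmetry scores, correlations and divergence
  profiles return missing values with warnings on degenerate inputs
  (all-zero matrices, empty dimensions, constant vectors) rather than
  NaNs.
* All generators and stochastic analyses take explicit seeds, restore
  the caller's RNG state, and derive per-stage child seeds from a root
  seed within the 32-bit range.

# Known limitations

* Neuron ids are held as doubles; identifiers above $2^{53}$ (as raw
  electron-microscopy segment ids can be) would lose precision and
  should be remapped before import.
* The configuration model resets synapse counts to 1; degree
  preservation refers to the binary graph.
* The rewiring rule covers excitatory edges only, by design: rewiring
  inhibitory connectivity is exactly what the rule is known not to
  capture.
* Querying remote connectome services, mesh/skeleton handling, calcium
  deconvolution and session co-registration are out of scope; activity
  enters as traces or precomputed correlation matrices.
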
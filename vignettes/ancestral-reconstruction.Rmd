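---
title: "Reconstructing ancestral gene orders under the DCJ-indel model"
author: "GenomeParsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene orders under the DCJ-indel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomeParsimony)
```

# The problem

Given a rooted phylogeny whose leaves carry extant genomes — sequences of
oriented markers (genes, synteny blocks) on linear and circular
chromosomes — the small parsimony problem asks for genomes at the internal
nodes minimizing the total tree distance
$d_T = \sum_{(A,B)\in E} d(A,B)$.  This package solves the *weighted small
parsimony linearization problem* for **natural genomes** (markers may occur
in any number of copies, anywhere, in any orientation) under the
**DCJ-indel** distance: operations are double-cut-and-join rearrangements
(inversions, translocations, fusions, fissions, circularizations) and
segmental insertions/deletions of arbitrary length.

Ancestral nodes are not reconstructed from nothing: upstream tools propose
*candidate adjacencies* per ancestor, possibly conflicting and possibly
weighted by confidence.  Such a candidate set is a *degenerate genome*;
choosing a conflict-free subset that covers every marker extremity is a
*linearization*.  The optimization selects one linearization per ancestor
so that

$$\sum_{(\mathbb{D}_i,\mathbb{D}_k)\in E}\Big(\alpha\,
d_{\mathrm{DCJ\text{-}ID}}(\mathbb{L}_i,\mathbb{L}_k,\equiv)\;+\;
(\alpha-1)\sum_{ab\in\mathcal{A}(\mathbb{L}_i)\cup\mathcal{A}(\mathbb{L}_k)}
w(ab)\Big)$$

is minimized, with $\alpha \in [0,1]$ trading distance against adjacency
weight.  Note that an internal genome's adjacency weights count once per
incident branch, exactly as the per-branch sum prescribes.

# Genomes as graphs

A genome is a graph on marker extremities (each marker $g$ has a tail
$g^t$ and head $g^h$) plus telomeres marking the ends of linear
chromosomes: marker edges pair each tail with its head, and adjacency
edges form a perfect matching on extremities and telomeres, so components
are simple paths (linear chromosomes) or cycles (circular chromosomes).
A degenerate genome relaxes only the matching requirement on adjacencies.

```{r}
gs <- readUnimog(">A\n1 1 2 4 -3 |\n>B\n1 1 2 5 3 |")
gs$A
chromosomes(gs$A)[[1]]$ids
```

# The distance and its comparison graph

Homology is an equivalence on markers (families).  For a **resolved**
homology (each marker matched to at most one marker of the other genome),
the DCJ-indel distance has a closed form over the components of the
capping-free comparison graph (`buildCFMRD`): adjacency edges of both
genomes, *extremity edges* joining matched extremities, and *self edges*
closing the marker edges of unmatched (singular) markers.  Ignoring self
edges, every component is a cycle or a path; paths are labeled reading
from genome $A$ to $B$, uppercase for telomeric ends, lowercase for ends
at singular extremities.  With $n$ matched markers, $c$ cycles, $s$
circular singletons (cycles alternating adjacency and self edges) and
path counts $p_{XY}$:

$$d = n - c + \left\lceil \frac{p_{ab} + \max(p_{Aa},p_{aB}) +
\max(p_{Ab},p_{Bb}) - p_{AB}}{2}\right\rceil + s.$$

Path classes with equal end types within one genome ($p_{aa}$, $p_{AA}$,
$p_{bb}$, $p_{BB}$) carry coefficient zero.  This is not printed in the
formula and was validated here empirically: the randomized test suite
checks the closed form (and the ILP built on it) against an independent
bidirectional breadth-first search over genome space that literally counts
operations.

```{r}
ex <- workedExample()
cen <- componentCensus(ex$A, ex$B, ex$matching)
cen
dcjIndelDistance(cen)
```

For unresolved homologies the distance minimizes the closed form over all
**maximum matchings** (per family, as many marker pairs as possible).
`distanceMaxMatching` does this exhaustively and is the small-instance
oracle; the ILP is the production path.  The operation-count oracle
(`bfsDistanceOracle`) constrains indels so that per-family copy numbers
move monotonically from source to target, which makes the markers
conserved by any found scenario a maximum matching — without this
restriction the search finds cheaper scenarios that delete and re-insert
whole segments, which the maximum matching model deliberately excludes.

# Linearizability

Not every degenerate genome admits a linearization.  Weighting each
candidate adjacency by its number of non-telomeric endpoints, a
maximum-weight matching has total weight $|\mathcal{E}(\mathbb{D})|$ iff a
linearization exists, and the matching *is* one (`tryLinearize`).  User
weights only break ties among maximum-coverage matchings; this is
implemented by scaling the coverage weight by a constant exceeding the
total absolute candidate weight.

Two augmentation modes guarantee linearizability of noisy candidate sets.
`augmentLocalGuarantees` decomposes the candidate-adjacency graph into
connected components and adds telomeres to every extremity of a component
unless the component is of even size and a simple path, simple cycle, or
fully connected — shapes guaranteeing a perfect matching within the
component, and per-component perfect matchings assemble into a
linearization.  `augmentSafer` ("safer linearization mode") attaches a
candidate telomere to *every* extremity, even in locally safe components,
so that no adjacency is ever selected merely because linearizability
leaves no alternative; the added telomeric adjacencies default to weight
zero.

# The integer linear program

`buildSppModel` emits a solver-neutral model in two layers.

**Global level.**  One binary presence variable per extremity and
telomere, equal for the two extremities of a marker; one shared binary
selection variable per candidate adjacency; family copy-number bounds
$(L_F, H_F)$ per ancestor (defaulting to "every candidate marker occurs",
which fixes presence to 1); and the matching constraint: each present
vertex lies in exactly one selected adjacency.

**Local level, per tree branch.**  The comparison diagram of the incident
genome pair.  Adjacency edges inherit the global selection variables;
extremity edges come in tail/head sibling pairs sharing one variable; each
marker has a self edge on every side where the bounds allow it to end up
unmatched, and a per-family binary allows self edges in only one of the
two genomes — which is precisely what enforces the maximum matching model
under dynamic marker content.  Component counting follows the
rank-labeling scheme: each vertex gets a diagram-local rank and a bounded
integer label that must be constant along selected edges and vanishes on
components containing self edges; a component can claim one "head" where
the label reaches the vertex's own rank.  Ranks are ordered telomeres of
$A$, telomeres of $B$, extremities of $A$, extremities of $B$: telomeres
rank below extremities so path components (which always end in telomeres)
can never claim a cycle report, and $A$ before $B$ so every non-singleton
cycle can claim its report on the $A$ side and a telomere-to-telomere
cross path can claim its report at its $A$ telomere.  A genome flag per
vertex (0-flavored at $A$-telomeres and selected $A$-self edges,
1-flavored on the $B$ side) propagates along selected edges; flips across
$A$-adjacencies charge $p_{ab}$ reports, flips at telomeric adjacencies
charge the telomere report of the matching class, and reporting a
lowercase class forces the component label to zero — which is exactly what
stops a telomere-to-telomere path within one genome from fraudulently
claiming the distance-reducing cross-path report.  The counters are then
assembled with linearized maxima and ceiling, $f_E = n - c + q + s$, all
relaxations tightened by the minimization pressure on $f_E$.

**Circular singletons.**  A cycle of alternating candidate-adjacency and
self edges within one genome costs one indel, and in dense candidate sets
the number of such candidate cycles is exponential ($2^{|E_{self}|}-1$ is
a lower bound when every adjacency among singular markers is a candidate).
Below a threshold of twice the number of self edges the candidates are
enumerated, one indicator each; above it a counting gadget of constant
size per vertex and edge takes over: an orientation bit that flips across
each selected edge, an integer potential required to increase along
selected adjacency edges in the orientation's direction and to be equal
across selected self edges, and a per-vertex report that relaxes the
increase — a cycle forces at least one report, paths never do.  The
potential equality across self edges is enforced only when the self edge
is selected (big-$K$ relaxed); an unconditional equality would tie the
potentials of separate selected paths through unselected self edges and
force spurious reports.  The big-$K$ is the number of self edges, an upper
bound on the length of any circular singleton.  Both encodings are proven
against each other on constructed instances in the test suite.  The
resulting model is linear in the total size of all comparison diagrams;
the size test fits variable and constraint counts against diagram size at
10–80 markers.

**Solving.**  Models are kept in triplet form and can be exported as LP
files (`exportLP`).  The bundled backend is HiGHS via
`scipy.optimize.milp`, driven through a batch JSON interface over a
`python` subprocess, so that many small models (e.g. an oracle suite, or
batched linearizability tests) cost a single interpreter start.  The
backend runs single-threaded and deterministically.  Warm starts from
`initialSolution` are validated and serve as the reported incumbent if the
solver yields none within the time limit; the backend does not accept
injected incumbents.

**Decoding.**  `decodeSolution` rebuilds one genome per node from the
presence/selection variables, validates it against the genome definition,
reads per-branch distances and matchings, and independently recomputes the
objective via the closed-form distance on the decoded genomes; on a
proven-optimal solve with $\alpha > 0$ any mismatch raises an internal
consistency error.

# Pre-processing

`initialSolution` produces a feasible upper bound: weight-aware
linearization per ancestor, then a greedy resolved matching per branch
that prefers marker pairings whose adjacency contexts agree (closing the
shortest alternating cycles first), completed arbitrarily to maximum
cardinality.  `leafPairLowerBounds` computes pairwise leaf distances and
emits cuts forcing the summed branch distances along each leaf-leaf path
to reach at least the pairwise distance — valid because any chain of
intermediate genomes needs at least as many operations.  The cuts never
change the optimum, only the solver's bound, and both features default to
off.

# The simulator

`simulateEvolution` emulates the benchmark protocol used to exercise the
method: a balanced four-leaf tree, a root genome of 100 single-copy
markers, 30 operations per branch with duplication rate 0.4, deletion rate
0.2, insertion rate 0.1 (remainder DCJ), and Zipf-distributed segment
lengths (exponent 6.0 for duplications, 4.0 for indels).  The Zipf support
is truncated at 20 — the published protocol fixes the exponents but not
the support, so the truncation is this package's choice.  DCJs are drawn
uniformly over all cut pairs plus single cuts, so telomere counts drift as
in the experiments; duplications are tandem-free; insertions introduce
fresh single-copy families (the natural reading of segmental gain).
`addNoise` adds adversarial false adjacencies at the internal nodes: all
candidates, true and false, carry weight 1, so weight carries no signal.

What the simulator does *not* emulate: gene-tree/species-tree
reconciliation, sequence-level inference of candidate adjacencies, or
realistic weight distributions from adjacency-proposing tools.  Passing
tests on simulated data therefore demonstrate correctness of the
optimization, not end-to-end accuracy on real annotation pipelines.

The scaled-down problem sizes used in the test suite (10–20 markers, 2–6
operations per branch, up to 15 noise adjacencies) keep every proven
optimum within seconds while exercising all code paths; the model scales
to hundreds of markers per genome with a commercial or longer-running
solver.

# Scoring

`scoreReconstruction` compares recovered and true ancestral adjacency
sets on canonical, telomere-anonymized keys.  Precision on an empty
recovered set is defined as 1 and flagged.  Telomeric adjacencies added
purely by augmentation are excluded from the comparison unless present in
the ground truth (mode `"augmented"`, the default); modes `"exclude"` and
`"include"` are available.  Per-node unweighted means and pooled counts
are both reported.

# Degenerate inputs and edge cases

* Empty genomes are legal; a marker extremity with no candidate adjacency
  forces the marker absent (or infeasibility if bounds require it).
* Candidate adjacencies joining two telomeres are rejected at parse time.
* A genome compared with itself under the identity homology has distance
  zero; two genomes are equal iff their diagram consists of cycles and
  telomere-to-telomere cross paths with $n = c + p_{AB}/2$.
* With $\alpha = 0$ the distance machinery is unconstrained by the
  objective; only linearizations and weights are meaningful.
* Predecessor objectives with an explicit telomere penalty $\beta'$ map
  onto this model by rescaling: defaults $\alpha' = 1/2$, $\beta' = 1/4$
  correspond to $\alpha = 2/3$ with every telomeric candidate weight
  reduced by 1 (`betaEmulation = 1`).

# Known limitations

* The MILP backend requires a `python` with scipy ≥ 1.9 on the PATH
  (override with the `GENOMEPARSIMONY_PYTHON` environment variable).
* Warm starts cannot be injected into the bundled backend; they act as
  fallback incumbents only.
* `distanceMaxMatching` and `bfsDistanceOracle` are exponential-time
  oracles with explicit budgets; they refuse rather than silently
  truncate.
* Family bounds interact with the maximum matching model through interval
  reasoning (a side may hold unmatched copies only if its upper bound
  exceeds the other side's lower bound); degenerate bound combinations
  that make an instance infeasible surface as solver infeasibility, not
  as a targeted diagnostic.
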
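# GenomeParsimony

Ancestral genome reconstruction for **natural genomes** — gene orders with
unrestricted marker multiplicity on linear and circular chromosomes —
under the **DCJ-indel** rearrangement model.

Given a rooted phylogeny whose leaves carry extant gene orders and whose
internal nodes carry sets of (possibly conflicting, possibly weighted)
candidate adjacencies, the package selects one conflict-free ancestral
genome per internal node — a *linearization* of the candidate set — so
that the total tree distance is minimized:

    min  Σ_{(i,k) ∈ E}  α · d_DCJ-ID(L_i, L_k)  −  (1−α) · Σ w(selected adjacencies)

The DCJ-indel distance counts double-cut-and-join rearrangements
(inversions, translocations, fusions, fissions) plus segmental insertions
and deletions, under the maximum matching model of homology.  For a
resolved homology the distance is a closed form over the components of
the capping-free comparison graph of the two genomes — with `n` matched
markers, `c` cycles, `s` circular singletons and path counts `p` by end
type (uppercase: telomere, lowercase: singular extremity):

    d = n − c + ⌈(p_ab + max(p_Aa, p_aB) + max(p_Ab, p_Bb) − p_AB)/2⌉ + s

The whole optimization is emitted as an integer linear program whose size
is **linear** in the total size of all comparison graphs — including the
counting of circular singletons, which is handled without enumerating the
(worst-case exponential) candidate set.  It is solved with the HiGHS
solver bundled with scipy, through a batch interface over a `python`
subprocess.

The package is for researchers in comparative genomics who have marker
(gene / synteny block) orders for extant species, a species tree, and
candidate ancestral adjacencies from an upstream tool, and who want exact
parsimony reconstructions rather than heuristics.

## What is inside

* UniMoG-dialect gene-order I/O, candidate-adjacency and copy-number-bound
  TSV tables, Newick trees with labeled internal nodes.
* Pairwise DCJ-indel distances: closed form (`dcjIndelDistance` over a
  `componentCensus`), exhaustive maximum-matching oracle
  (`distanceMaxMatching`), operation-counting search oracle
  (`bfsDistanceOracle`), and the production ILP (`dcjIndelDistanceILP`).
* Linearizability testing by maximum-weight matching (`tryLinearize`) and
  two telomere-augmentation modes, including the *safer linearization
  mode* (`augmentSafer`).
* The small-parsimony ILP (`buildSppModel` / `solveSpp`), family
  copy-number bounds, warm starts (`initialSolution`) and leaf-pair
  lower-bound cuts (`leafPairLowerBounds`).
* A genome evolution simulator with adversarial adjacency noise
  (`simulateEvolution`, `addNoise`) and precision/recall/F1 scoring of
  reconstructions (`scoreReconstruction`).
* A command-line front end: `exec/genome-parsimony
  <distance|linearize|solve|simulate>`.

## Worked example

Two five-marker genomes with in-paralogs in family 1, each a single
linear chromosome:

```r
library(GenomeParsimony)
ex <- workedExample()          # A = (1 1 2 4 -3),  B = (1 1 2 5 3)
ex$A
#> Genome 'A': 5 markers on 1 chromosome(s) (1 linear, 0 circular)

componentCensus(ex$A, ex$B, ex$matching)
#> ComponentCensus: n=4 c=2 s=0 paths: AB=1 Ab=1 aB=1 ab=1

dcjIndelDistanceILP(ex$A, ex$B)
#> [1] 3
```

Under the resolved homology that matches the two copies of family 1 in
order, the comparison graph has 2 cycles and one path of each label AB,
ab, aB and Ab, so the distance is
`4 − 2 + ⌈(1 + 1 + 1 − 1)/2⌉ = 3`: one scenario uses one inversion plus
one deletion (of marker 4) and one insertion (of marker 5).  The ILP
proves the same optimum over all maximum matchings.

A full reconstruction run on simulated data with adversarial noise:

```r
cfg <- simulationConfig(rootMarkers = 20, opsPerBranch = 4, noise = 10, seed = 42)
tr  <- simulateEvolution(cfg)
#> GroundTruth: 7 genomes (19-28 markers), 24 operations, seed 42
nz  <- addNoise(tr, 10, seed = 42)
sol <- solveSpp(nz$phylogeny, weights = nz$weights, alpha = 0.5, augment = "safer")
#> SPPSolution: 7 linearized genomes, total tree distance 24, objective -78 (gap 0)
scoreReconstruction(sol, tr)[c("precision", "recall", "f1")]
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1
```

All three ancestral gene orders are recovered exactly despite 10 false
candidate adjacencies per internal node, and the tree distance (24)
equals the number of simulated operations.

## File formats

* **Genomes**: UniMoG dialect — `>name` headers, chromosome lines of
  signed family names ending `|` (linear) or `)` (circular).
* **Candidate adjacencies**: TSV `genome, marker1, side1, marker2, side2,
  weight` with sides `t`/`h`/`o` (`o` = telomere); `#` comments; missing
  weight = 0.
* **Bounds**: TSV `genome, family, low, high`.
* **Trees**: Newick, internal node labels mandatory.
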
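Package: GenomeParsimony
Title: Ancestral Genome Reconstruction Under the DCJ-Indel Model
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Solves the weighted small parsimony linearization problem for
    natural genomes on a rooted phylogeny under the DCJ-indel rearrangement
    model. Extant genomes are signed marker sequences over linear and circular
    chromosomes; ancestral nodes carry degenerate genomes (sets of weighted
    candidate adjacencies) that are linearized while minimizing the total
    tree distance via a polynomial-size integer linear program over
    capping-free multi-relational diagrams. Includes pairwise DCJ-indel
    distance computation under the maximum matching model, linearizability
    testing by maximum-weight matching, telomere augmentation modes, solution
    warm starts and leaf-distance lower bounds, a genome evolution simulator
    with adversarial adjacency noise, and precision/recall scoring of
    reconstructed ancestors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'genome.R'
    'cfmrd.R'
    'distance-oracles.R'
    'io.R'
    'simulate.R'
    'milp-backend.R'
    'linearize.R'
    'ilp-build.R'
    'ilp-solve.R'
    'evaluate.R'
    'preprocess.R'
    'utils-extremities.R'
    'worked-example.R'
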
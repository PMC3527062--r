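Package: dcjindel
Title: Edit Distances and Rearrangement Scenarios for Genomes with
    Duplicate Genes under DCJ, Insertion and Deletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the edit distance between two gene-order genomes with
    duplicate genes and unequal gene content under a unit-cost model of
    double-cut-and-join (DCJ) operations, single-gene insertions and
    single-gene deletions. The distance is obtained by decomposing the
    bipartite adjacency graph of the two genomes into alternating cycles
    after ghost-adjacency augmentation and null-extremity capping; an
    approximation algorithm packs helpful 4-cycles (exact branch-and-bound
    or greedy plus local-search set packing) and a brute-force oracle
    enumerates optimal decompositions on small instances. Every distance
    comes with an explicit, replayable operation scenario, and a simulator
    generates random genomes and operation histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
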
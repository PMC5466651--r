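Package: knetdist
Title: The kth-Distance Between Rooted Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("knetdist", "developers", email = "knetdist@example.org",
           role = c("aut", "cre"))
Description: Compares rooted phylogenetic networks (leaf-labelled single-rooted
    directed acyclic graphs) with the kth-distance, a polynomial-time metric on
    the space of kth-order reduced networks. Implements the chain of kth-order
    node equivalence relations (child-side at odd orders, parent-side at even
    orders, anchored at taxon labels and the root) by partition refinement, a
    naive recursive oracle for cross-validation, the kth-order reduction of a
    network, exact rational distance computation with a per-order breakdown, a
    brute-force isomorphism check for small networks, extended-Newick and
    edge-list input/output, a seeded random network generator, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
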
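Package: fragsim
Title: Weighted Fingerprint Similarity Search in Topological Chemical
    Fragment Spaces
Version: 0.1.0
Authors@R: person("fragsim", "maintainers", email = "fragsim@example.org",
    role = c("aut", "cre"))
Description: Models combinatorial chemical fragment spaces (topology graphs
    whose nodes hold interchangeable building-block fragments with named
    linker placeholder atoms) and searches them for the N products most
    similar to a query molecule without enumerating the space. Similarity is
    computed on sparse count fingerprints (connected-subgraph and circular
    descriptors) with the Tanimoto/Ruzicka coefficient; user-marked query
    substructures (SMARTS or atom lists) can be up-weighted so that search
    results preserve the marked area while varying elsewhere. Includes a
    brute-force enumeration oracle, a synthetic fragment-space generator
    built by fragmenting drug-like molecules, a desk-scale validation
    benchmark (substructure preservation scores, Bemis-Murcko scaffold
    counts, pairwise similarity distributions) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
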
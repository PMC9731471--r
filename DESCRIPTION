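Package: receptorclust
Title: Deterministic, Stochastic and Agent-Based Models of Receptor
    Clustering by Multivalent Ligands and Cytosolic Crosslinkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the clustering of monomeric cell-surface receptors such as
    the platelet glycoproteins GPVI, CLEC-2 and PEAR1.  Provides law-of-mass-action
    equilibrium and kinetic models for monovalent, divalent and tetravalent
    ligands (with ligand-excess and ligand-depletion modes and a cooperativity
    coefficient), an exact Gillespie simulator of the same reaction networks in
    integer copy numbers, and a toroidal-lattice agent-based model in which
    receptor homo-dimerisation, phosphorylation, divalent ligand bridging and a
    divalent cytosolic crosslinker (a tandem-SH2 protein such as Syk) jointly
    drive cluster formation.  Includes cluster-census metrics over the receptor
    bond graph, figure-scenario configuration fixtures, and TSV/JSON result
    writers with full run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
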
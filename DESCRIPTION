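Package: nitroscape
Title: Phylo-Structural Analysis of Nitrogenase Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the structural evolution of the nitrogenase
    enzyme family across a phylogeny. Generates maximum-likelihood and
    alternative ancestral sequences from site-wise reconstruction
    posteriors; superposes predicted or experimental multimer structures
    and scores them with RMSD, RMSD100 and TM-score; computes structural
    attributes (solvent-accessible surface area, radius of gyration,
    intersubunit contacts, a contact-based binding-affinity score,
    residue-contact networks, Gaussian-network-model modes); maps
    attributes and insertion events onto rooted trees (root distances,
    Spearman depth correlations, hierarchical clustering against clades,
    Fitch parsimony branch assignment, insertion length trajectories);
    and ships a fully seeded synthetic-data generator so the entire
    pipeline can be exercised and validated at desk scale without GPU
    structure prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
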
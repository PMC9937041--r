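Package: ponevo
Title: Gene-Family Evolution Analysis for the Paraoxonase (PON) Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for domain-based gene-family analysis in the
    style applied to the metazoan paraoxonase (PON) family: identification of
    family members from profile-HMM domain hit tables with tandem-array naming,
    conservative loss calls and retroduplication flags; exact phylogenetic
    likelihood computation under empirical amino-acid models (Poisson, JTT, LG,
    with discrete-Gamma rates and invariant sites) and Goldman-Yang codon
    models; constrained-topology likelihood-ratio tests and AIC model
    selection; codon site models (M0, M1a, M2a, M7, M8) and branch-site model A
    with likelihood-ratio tests and naive/Bayes empirical Bayes identification
    of positively selected sites; Shrake-Rupley solvent accessibility and a
    permutation test for spatial clustering of selected residues on a protein
    structure. A synthetic-data module simulates alignments under the
    implemented substitution processes, locus/hit tables with planted family
    structure, and pseudo-structures with planted residue clusters, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'ponevo-package.R'
    'AllClasses.R'
    'alignment.R'
    'trees.R'
    'models.R'
    'ratematrix.R'
    'likelihood.R'
    'optimize.R'
    'sitemodels.R'
    'selection.R'
    'beb.R'
    'family-scan.R'
    'simulate-loci.R'
    'simulate.R'
    'simulate-structure.R'
    'structure.R'
    'structure-map.R'
    'topology.R'
    'pipeline.R'
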
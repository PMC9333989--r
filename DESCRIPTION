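Package: EvoMotif
Title: Evolutionary Analysis of Protein Motifs with Functional Assay Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of short functional motifs in
    protein families and linking them to functional measurements. Implements
    reference-numbered alignment masking, information-theoretic column
    conservation on the ConSurf scale convention, mutual-information residue
    covariation with average-product correction and a permutation null,
    site-wise dN/dS selection testing in the fixed-effects-likelihood style
    under an MG94xHKY codon model with optional foreground branch sets,
    marginal ancestral sequence reconstruction under JTT with discrete-gamma
    rate heterogeneity, and quantification procedures for sucrose-gradient
    membrane-fraction profiles, IL-2 dose-response assays, and
    phospho-intensity histogram responder analysis. A simulation module
    generates trees, protein and codon alignments with planted selection
    classes and coevolving column pairs, and synthetic assay tables with known
    ground truth for end-to-end validation.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
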
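Package: piakit
Title: Peptide Inhibitor Assay Companion Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design blocking-peptide panels that tile a protein chain
    (secondary-structure windows, staggered junction peptides, short
    N/middle/C fragments, deletion splits and composition-preserving
    randomizations), compute ProtParam-style physicochemical descriptors
    (average molecular weight, isoelectric point, GRAVY, aliphatic index,
    instability index, aromatic count, hydrophilic percentage, net charge
    at pH 7), simulate saturating enzyme-digestion fluorescence time
    courses with competitive rate suppression, and analyse inhibition via
    control-normalized relative fluorescence, Dunnett many-to-one
    comparisons, ranking and descriptor correlations.  Ships the
    reconstructed EcoRI chain and the published 85-peptide blocking-peptide
    panel with its golden descriptor tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    jsonlite
Config/testthat/edition: 3
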
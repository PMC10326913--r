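Package: mrmqa
Title: Multi-Attribute Monitoring of Antibody Quality Attributes by Targeted MRM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and validating a multiple-reaction-monitoring
    (MRM) transition panel that monitors four quality attributes of a
    cysteine-inserted (C239i) IgG1 antibody intermediate: the thiol state of
    the inserted cysteines, Fc N-glycosylation, partial reduction of interchain
    disulfide bonds, and polypeptide fragmentation. Includes a mass engine for
    modified, glycosylated and disulfide-cross-linked peptide species
    (elemental compositions, monoisotopic masses, aggregated isotopologue
    patterns, precursor and fragment m/z), relative quantitation of the four
    attributes from peak-area tables with ionization-bias correction factors,
    calibration utilities (expected-vs-observed regression, blend-based
    response-factor estimation, orthogonal released-glycan bridging,
    design-of-experiments response surfaces), and a synthetic MRM data
    generator so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse
Config/testthat/edition: 3
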
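Package: glycotrident
Title: Site-Specific N-Linked Glycopeptide Identification from Beam-Type CID
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies intact N-linked glycopeptides from beam-type CID/HCD
    MS2 spectra. Filters glycopeptide spectra by diagnostic oxonium (B-) ions,
    locates the deglycosylated peptide ion (Y0) through triplet Y-ion pattern
    matching, extends the Y-ion ladder by dynamic programming, strips glycan
    fragment ions to emit searchable in silico peptide spectra, infers glycan
    compositions from the precursor mass difference under N-glycan biosynthesis
    constraints, and performs a targeted search against a customized isobaric
    target-decoy peptide database with an intensity-ratio peptide score and
    target-decoy diagnostics. Includes a deterministic synthetic-spectrum
    generator for end-to-end validation and report integration utilities for
    site-specific protein-glycan summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
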
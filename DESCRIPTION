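Package: kinasehotspots
Title: Mapping Pathogenic Mutation Hotspots onto a Reference Kinase Domain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects per-gene missense variants through a structure-based
    multiple sequence alignment of protein kinase domains onto a single
    reference kinase structure, counts mutations per reference position by
    disease class (cancer versus non-cancer), calls top-5 percent mutation
    hotspots with deterministic tie handling, tests per-position over- and
    under-representation of cancer mutations with a 2x2 chi-square test, and
    writes per-residue mutation counts into the B-factor column of the
    reference PDB file for visualisation. Includes a synthetic-data generator
    that emulates the aligned-FASTA, variant-table and structure inputs with
    planted hotspots so the whole pipeline can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
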
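Package: nglyco
Title: N-Glycoproteome Analysis from Deglycosylated Peptide Identifications
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of shotgun N-glycoproteomics experiments that
    identify formerly glycosylated peptides after PNGase F deglycosylation
    (asparagine-to-aspartate conversion at occupied sequons). Provides NXS/T
    sequon scanning, in-silico tryptic digestion, deamidation-aware mapping of
    peptide-spectrum matches onto protein sequences, glycosite calling with
    multi-sequon ambiguity handling, stoichiometry-normalized spectral-count
    quantification with copy-number calibration, sequon-occupancy and
    transmembrane-complementarity statistics, set-overlap and hypergeometric
    enrichment utilities, and a fully seeded synthetic proteome/PSM generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
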
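Package: ambihelix
Title: Statistical Analysis of Ambivalent (Chameleon) Alpha-Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and characterises ambivalent (chameleon) alpha-helices:
    sequence fragments that are fully helical in one protein chain but adopt
    partly or entirely non-helical conformations where the identical sequence
    occurs in other chains. Provides readers for DSSP output and a flat
    chain-table format, structure-quality filtering, helix extraction from
    8-state secondary-structure strings, exact cross-database sequence mapping
    (a reference N-by-M matrix algorithm plus an equivalent fast matcher),
    per-occurrence conformational-shift quantification with decade binning and
    conserved/partial/variable classification, normalized conformational
    parameters (amino-acid propensities) for arbitrary residue groups,
    flanking-sequence statistics split by terminus, Gly-X-Gly-normalized
    relative solvent accessibility, a seeded synthetic chain-database
    generator with planted ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse,
    yaml
Config/testthat/edition: 3
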
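Package: vertcoi
Title: Vertebrate-Specific Degenerate COI Primer Design and Mosquito
    Blood-Meal Host Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing degenerate cytochrome c oxidase subunit I
    (COI) primers that amplify a universal range of vertebrate hosts while
    excluding mosquito templates, and for identifying the vertebrate hosts
    of mosquito blood meals. Includes IUPAC ambiguity-code sequence algebra,
    discovery and scoring of candidate priming sites from a joint
    target/non-target multiple alignment, in-silico PCR with a 3'-clamp
    mismatch model, hierarchical amplification with percent-identity species
    assignment against a local reference database, a seeded generator of
    COI-like alignments and digestion-degraded blood-meal templates, and the
    concentration-based versatility/specificity statistics (nM conversion,
    crossed ANOVA, Tukey HSD letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'vertcoi-package.R'
    'iupac.R'
    'io.R'
    'ispcr.R'
    'site_scan.R'
    'ident.R'
    'synth.R'
    'quantstats.R'
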
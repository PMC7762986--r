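Package: spindelr
Title: Species Identification from Indel Length Profiles in Organellar Alignments
Version: 0.1.0
Authors@R: person("spindelr", "maintainers", email = "maintainers@spindelr.org",
    role = c("aut", "cre"))
Description: Identifies species from the ungapped lengths of hypervariable,
    indel-rich segments between conserved anchor blocks in multiple sequence
    alignments of non-coding chloroplast and mitochondrial regions. Detects
    conserved anchors, converts alignments into numeric length profiles,
    computes species-specific profile frequencies, mismatch distributions and
    minimum discriminating region subsets, enumerates multi-marker region
    combinations, and ships a ground-truthed alignment simulator plus a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
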
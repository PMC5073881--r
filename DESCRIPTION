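Package: hrgpscan
Title: Proteome-Wide Discovery and Classification of Hydroxyproline-Rich
    Glycoproteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans protein FASTA files for the biased amino-acid
    compositions and sequence motifs that mark the plant cell-wall
    hydroxyproline-rich glycoprotein (HRGP) superfamily, and classifies
    hits into arabinogalactan-proteins (AGPs), extensins (EXTs), and
    proline-rich proteins (PRPs) with their subclasses (AG peptides,
    fasciclin-like AGPs, lysine-rich AGPs, short and chimeric extensins,
    PR peptides, and hybrids). Every numeric criterion is held in a single
    configurable thresholds object; optional external evidence tables
    (signal peptide, GPI anchor, protein domains, homology) refine
    subclass calls. Includes a seeded synthetic-proteome generator with
    planted family members for end-to-end validation, TSV inventory and
    summary reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
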
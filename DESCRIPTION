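Package: kmerpep
Title: Deterministic K-Mer Matching of Short Peptides in Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finds short peptides (typically 8-17 residues) in large protein
    sets by deterministic k-mer indexing. Supports exact matching, matching
    with a fixed number of residue substitutions (Hamming distance) with
    completeness guaranteed by pigeonhole seeding, and best-match search
    (the minimum-substitution hit) via a cascade of decreasing k-mer sizes.
    Includes brute-force reference implementations, a synthetic
    proteome/peptide fixture generator, a pluggable benchmarking harness
    that times preprocessing/search phases and scores recall, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    tibble,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
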
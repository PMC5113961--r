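Package: corecazyome
Title: Core Carbohydrate-Active Gene Identification in Replicated Soil Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the core set of carbohydrate-active (CAZy-annotated)
    contigs consistently present across replicate soil metagenomes. Converts
    per-base depth tables into coverage summaries and presence calls, resolves
    best-hit CAZy annotations with seeded random tie-breaking, normalizes
    contig abundance to copies per recA single-copy gene, profiles the core by
    enzyme class, family and phylum with replicate means and confidence
    intervals, tests for annotation-database bias with an empirical-null
    resampling test, estimates the k-mer-level core fraction from read
    subsets, and quantifies how much of the core is shared with other
    metagenomes. Includes a synthetic-community generator with a planted,
    exactly recoverable core so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
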
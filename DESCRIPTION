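Package: proteopath
Title: Pathway-Based Expansion of Small-Sample Shotgun Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Elucidates the expressed proteome of very small cell samples
    from shotgun-proteomics identification lists. Protein reports are
    cleaned of common contaminants and harmonized to approved gene
    symbols via an alias table; detected genes are tested for
    over-representation against a canonical-pathway gene-set collection
    with an exact hypergeometric tail statistic; enriched sets are
    expanded into a predicted proteome; and predictions are verified
    against replicate structure and transcript-expression concordance
    (probe collapsing, sliding-window overlap scores, expression-threshold
    groups). A synthetic-data generator emits complete ground-truthed
    input bundles so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
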
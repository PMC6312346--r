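Package: mztevol
Title: Evolution of Maternal and Zygotic Transcript Complements Across a Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of early-embryo transcriptomes before and
    after the maternal-to-zygotic transition. Classifies isoforms and genes
    into six stage categories (maternal-only, predominantly maternal,
    maternal-zygotic, predominantly zygotic, zygotic-only, not present) from
    two-timepoint FPKM tables, detects stage-specific alternative isoform
    usage, correlates and clusters transcriptomes across species on
    one-to-one orthologs, encodes transcript presence/absence as binary
    characters and reconstructs marginal ancestral states on a fixed rooted
    phylogeny under a two-state Markov model with maximum-likelihood rates,
    calls gains and losses of representation at a posterior threshold, and
    identifies core sets of genes with conserved stage-restricted status
    including a distant outgroup. A ground-truthed synthetic-data generator
    emulates the statistical structure of the real data so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
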
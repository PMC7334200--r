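Package: exindnm
Title: Exon Versus Intron Germline De Novo Mutation Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare germline de novo mutation (DNM) densities
    between internal exons and their flanking introns. Implements k-mer
    sequence-context mutational models estimated directly or through a
    composite-likelihood decomposition, internal-exon-centered stacked
    observed/expected mutation profiles with a multinomial permutation test
    of exonic excess, context-model comparison by AIC over all window sites,
    a chromatin-feature binned-gene enrichment analysis with robust
    correlation, and absolute per-site per-generation mutation rate
    estimation. A synthetic-data module generates genomes, gene annotations,
    DNM tables and chromatin coverage tracks with the statistical structure
    the analysis assumes, so the whole pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
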
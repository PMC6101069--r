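Package: ucoselect
Title: Reference Model Species Selection for Non-Model Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects reference model species for annotating de novo
    transcriptome assemblies of non-model organisms, by two complementary
    routes: lowest-common-ancestor depth on the NCBI taxonomy tree, and
    sequence similarity of ultra-conserved orthologous (UCO) proteins.
    Validates UCO-derived inter-species distance matrices with Mantel
    correlations, transfers best-hit ortholog annotations from the selected
    species to query contigs, and performs hypergeometric GO and pathway
    enrichment on differentially expressed gene lists. Includes a synthetic
    fixture generator (planted taxonomies, divergence-scaled proteomes,
    back-translated contigs, planted enriched terms) so every stage of the
    pipeline can be tested against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
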
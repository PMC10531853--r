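Package: fogsig
Title: Cross-Species Cell-Specific Signature and Flip-Over Gene Discovery
Version: 0.1.0
Authors@R:
    person("fogsig", "developers", email = "fogsig@example.org", role = c("aut", "cre"))
Description: Discovers cell-type transcriptome signature genes and flip-over
    genes (ortholog groups whose bundle-sheath/mesophyll expression preference
    reverses between C3 and C4 grasses) from per-species RNA-seq count
    matrices, and compares protein sequence similarity against structure
    similarity (TM-score over Kabsch superpositions) to flag homolog pairs
    whose sequences agree but whose folds do not. Includes a negative-binomial
    Wald differential-expression stage with median-of-ratios normalization and
    Benjamini-Hochberg correction, hypergeometric gene-set enrichment,
    physicochemical protein profiling (four-group amino-acid composition,
    isoelectric point), Needleman-Wunsch global alignment with affine gaps,
    and a synthetic-data module that generates count matrices, homolog
    families and CA-trace structures with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
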
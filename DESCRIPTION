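Package: immunofrac
Title: Absolute Immune Cell Fraction Deconvolution from Bulk Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the absolute fractions of ten immune cell types
    (B cells, M1 and M2 macrophages, monocytes, neutrophils, NK cells,
    non-regulatory CD4+ T cells, CD8+ T cells, regulatory T cells, and
    dendritic cells) plus an uncharacterized-cell remainder from bulk
    transcriptomes by constrained least-squares deconvolution against a
    cell-type signature matrix, with mRNA-content correction and a
    dropout heuristic for regulatory T cells. Includes the signature
    construction pipeline (three-bin expression quantization and
    cell-specificity, tumor-expression, gene-set, expression-range,
    fraction-correlation and restricted-expression filters, plus curated
    and tumor gene blacklists), an in-silico mixture simulator with tumor
    purity and sequencing-depth effects, leave-K-out benchmarking, and
    deconvolution-based immunoscore and TB-score prognostic classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
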
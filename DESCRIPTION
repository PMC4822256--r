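Package: emcovar
Title: Shared Genetic Control of Gene Expression and DNA Methylation in Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying shared genetic control of gene expression
    and DNA methylation traits measured on the same blood samples. Provides
    exhaustive block-wise Pearson cross-correlation with Fisher-Z asymptotic
    p-values and Bonferroni control, a bipartite correlation-graph diagnostic
    for cell-composition confounding, reference-based deconvolution of blood
    cell proportions from methylation with calibration and residual
    adjustment, single-SNP QTL mapping with shared-QTL overlap summaries, and
    genomic-relationship-matrix based univariate and bivariate REML for
    heritability and genetic correlation. A synthetic-data module simulates
    twin-family pedigrees, gene-dropped genotypes, blood cell proportions and
    paired expression/methylation matrices with known ground truth so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
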
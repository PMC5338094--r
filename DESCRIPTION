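Package: segdupr
Title: Copy-Number and Concerted-Evolution Analysis of Segmentally Duplicated Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying segmentally duplicated gene families such as
    the primate SPATA31 core-duplicon family. Implements Poisson quantification
    of droplet digital PCR (ddPCR) counts into copies per diploid genome with
    population summaries and histograms; read-depth-based estimation of total
    copy number over paralog-homologous reference loci; Kimura 2-parameter
    distances with pairwise deletion, neighbor-joining trees, bootstrap
    supports and a within/between-species distance ratio that quantifies
    concerted evolution; and CRISPR amplicon indel calling that classifies
    reads as unedited, in-frame or frameshift around a cut site. Every stage
    is exercisable on synthetic data generated by the package itself:
    two-channel droplet counts under Poisson loading, Poisson read depth over
    a collapsed multi-copy locus, a two-species gene family evolving with
    optional gene conversion, and edited amplicon reads with a stated indel
    spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
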
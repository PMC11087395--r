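Package: kaspanel
Title: Design and Quality Control of Trait-Linked KASP Marker Panels for
    Deep-Sown Direct-Seeded Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating allele-specific (KASP) SNP
    marker panels for marker-assisted breeding of deep-sown direct-seeded
    rice. Covers donor-specific SNP discovery inside QTL windows, KASP
    primer design with multi-locus specificity rejection, endpoint
    fluorescence genotype calling, per-marker quality control (utility,
    false-positive and false-negative rates, Kruskal-Wallis allelic
    effects, single-marker regression, CRD ANOVA), core-panel selection,
    and parent-level diversity and variant-annotation summaries. Ships a
    synthetic-data generator that emulates biparental F3:F4 and backcross
    BC3F2:3 breeding populations with pedigree truth, phenotypes and
    controlled genotyping error, plus a transcription of the published
    54-marker quality-control table used as an in-package fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
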
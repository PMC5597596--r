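Package: denovoherd
Title: Discovery of Dominant De Novo Mutations and Mapping of Causal,
    Modifier and Recessive Loci in Livestock Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for discovering dominant de novo
    deleterious mutations from whole-genome variant calls filtered against a
    control genome panel, mapping causal and modifier loci from phased SNP
    haplotypes in half-sib cattle pedigrees by sliding-window haplotype
    association with permutation empirical p-values, localising recessive
    defects by homozygosity mapping and shared identity-by-descent segments,
    and forecasting the emergence of recessive disorders from pedigree
    founder contributions and gene-dropping simulation. Includes seeded
    synthetic-data generators that emulate each study design with planted
    ground truth, so the full pipeline is testable without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
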
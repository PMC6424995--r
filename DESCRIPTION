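Package: hopperqtl
Title: Bulked-Segregant QTL-Seq, Haplotype-Pattern Mining and Damage AUC
    Analysis for Brown Planthopper Resistance in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for mapping brown planthopper (BPH)
    resistance loci in rice from pooled reduced-representation sequencing.
    Implements trapezoid-rule damage AUC phenotyping on the SES 1-9 scale,
    extreme-pool selection, SNP-index and absolute delta-SNP-index
    sliding-window QTL-seq scans with Monte-Carlo null confidence thresholds,
    coding-variant effect annotation against gene models, per-gene
    haplotype-pattern (HP) mining with the damage-reducing ratio (DRR),
    marker and HP association (one-way ANOVA, regression PVE, Tukey compact
    letter displays, resistance classification), pairwise linkage
    disequilibrium (D, D', r-squared) with Gabriel confidence-interval block
    calling, and graphical genotyping of donor introgression segments. A
    synthetic-data generator emulating a backcross-inbred-line cross, a
    fast-neutron mutant population and pooled allele-depth sequencing makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    generics,
    Biostrings,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
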
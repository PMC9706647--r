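Package: sizescan
Title: Genome Scans for Body-Size Differentiation in Structured Chicken Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dual genome-scan pipeline for localizing genomic regions that
    underlie quantitative body-size differences between groups of related
    breeds ("types"). Implements marker quality control (call-rate,
    monomorphism and minor-allele-frequency filters with small
    genotype-class masking), hierarchical clustering of individuals from
    genotypes, within-breed sex correction of phenotypes, a per-marker
    association scan with a breed covariate and Benjamini-Hochberg false
    discovery rate control, linkage-disequilibrium based merging of
    significant markers into regions, and a principal-component
    contribution significance scan (the signed pcaDObs statistic with
    normal-fit p-values and Bonferroni selection) with distance-based
    region merging. A hierarchical-drift (Balding-Nichols style) simulator
    generates genotype and phenotype panels with planted causal and
    type-differentiated loci for calibration and power studies.
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
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
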
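Package: nilqtl
Title: QTL Mapping of Stuck Fermentation Traits in Backcrossed Yeast Lineages
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) mapping in nearly
    isogenic Saccharomyces cerevisiae lineages derived by recurrent
    backcrossing, aimed at stuck wine fermentation phenotypes. Provides
    fermentation CO2 kinetics trait extraction (lag phase, T35/T50/T70,
    CO2max, late-phase rate), broad-sense heritability from replicated
    controls, selective-genotyping marker validation from tiling-array
    signal against whole-genome-sequencing SNP tables, nonparametric
    Wilcoxon rank-sum linkage scans with permutation-based genome-wide
    significance thresholds, ANOVA variance decomposition at mapped loci,
    sequential cross design for minor-QTL detection, coding-variant
    consequence annotation (frameshift and nonsense calls in HGVS-like
    notation), and a synthetic-data generator emulating the full backcross
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
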
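Package: ildscr
Title: Interaction-LD Score Regression for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("ildscr", "maintainers", email = "ildscr@example.org",
    role = c("aut", "cre"))
Description: Estimates heritability from GWAS summary statistics while
    accounting for pairwise cis-acting SNP-by-SNP interactions that are
    tagged by additive effect size estimates. Computes additive LD scores
    and cis-interaction LD scores from a PLINK 1 reference panel, fits a
    weighted regression of chi-square statistics on both score types with
    block-jackknife standard errors, and ships a full synthetic-genotype
    and phenotype simulator for calibration, power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
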
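Package: sirehap
Title: Sire-Informed Two-Locus Haplotype Phasing and Trait Association in
    Half-Sib Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pedigree-based phasing of two-locus haplotypes in half-sib
    livestock families from unphased per-region genotypes, haplotype and
    diplotype frequency estimation by chromosome counting, and a three-tier
    association modelling scheme for growth and carcass traits: single
    haplotype presence/absence linear mixed models with a random sire
    effect, multi-haplotype adjusted models, and diplotype models with
    Bonferroni-corrected pairwise least-significant-difference comparisons
    and a compact letter display.  Includes a seeded synthetic half-sib
    cohort generator so the whole pipeline is testable end-to-end, and a
    small command-line interface for running the stages on delimited-text
    animal tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
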
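---
title: "Half-sib haplotype phasing and trait association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-sib haplotype phasing and trait association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirehap)
```

## The problem

Candidate-gene association studies in livestock often type a gene in two
separately amplified regions (here: a promoter--exon 1 fragment and an
intron 2--exon 3 fragment of the ovine adiponectin gene), yielding two
*unphased* genotypes per animal rather than haplotypes.  Because commercial
sheep flocks are organised as half-sib families -- large progeny groups
sharing one sire and many unrelated dams -- the pedigree itself carries
enough information to phase most animals without molecular haplotyping.
`sirehap` implements that phasing, estimates haplotype and diplotype
frequencies by chromosome counting, and fits the three-tier association
scheme commonly used for such data: single-haplotype presence/absence
models, multi-haplotype adjusted models, and diplotype models with
Bonferroni-corrected pairwise comparisons.

## Phasing model

A haplotype is a promoter--exon 1 variant paired with an intron 2--exon 3
variant (`A1-A3`); the two regions are treated as fully linked, so no
recombination between them is modelled.  A diplotype is the unordered pair
of haplotypes an animal carries.

**Direct rule.** An animal homozygous at either region has exactly one
diplotype consistent with its two genotypes; `enumerate_candidate_diplotypes()`
returns it and the animal is phased directly.  An animal heterozygous at
both regions has exactly two candidates (the *cis* and *trans* pairings).

**Sire reconstruction.** Each progeny inherits exactly one of its sire's
two haplotypes, so across a family roughly half the progeny carry each.
`reconstruct_sire_diplotype()` enumerates candidate sire diplotypes (from
the sire's own genotypes when typed, otherwise over all haplotypes observed
in the family), keeps the candidates consistent with every progeny (sharing
at least one haplotype with at least one of each progeny's candidates), and
scores survivors by *support*: the number of directly phased progeny
carrying one of the candidate's haplotypes.  The unique maximal-support
consistent candidate is chosen.  This is a deliberate design choice over a
likelihood/EM treatment of dam haplotype frequencies: it matches how such
pedigrees are phased in practice, is exactly checkable against a
brute-force enumeration oracle (the test suite does exactly that on ~500
random families), and surfaces ambiguity instead of hiding it in posterior
probabilities.  Ties in support are never broken arbitrarily.

**Resolution.** A double heterozygote keeps the candidates sharing a
haplotype with the chosen sire diplotype: one survivor phases it; zero
survivors mark a Mendelian inconsistency; two survivors (or an ambiguous
sire) leave it unresolved.  Unresolved and inconsistent animals are carried
with a null diplotype and dropped per trait downstream -- never imputed.
Under the default eight-haplotype pool a non-negligible fraction of progeny
is *intrinsically* unresolvable: when a sire is heterozygous at both
regions, a dam haplotype can complete the progeny's genotypes so that both
pairings contain a sire haplotype (e.g. sire `A1-A3/B1-A3`, transmitted
`A1-A3`, dam `B1-C3`).  Across seeded default cohorts the resolved fraction
is typically 0.87--0.96, and every resolved diplotype equals the
generator's hidden truth when genotyping is error-free.

**Frequencies.** `estimate_frequencies()` counts two chromosomes per
resolved animal (homozygotes count twice).  Because half of all progeny
chromosomes descend from only `2 x n_sires` founder chromosomes, the
cohort's realized haplotype frequencies scatter around the population pool
far more widely than a binomial draw of `2n` chromosomes: for 17 sires the
sampling SD of a common haplotype's cohort frequency is roughly
`sqrt(p(1-p)(1/34 + 1/n)/4)` (about 4 percentage points at `p = 0.46`),
four times the binomial SD at `n = 1185` animals.  Frequency-recovery
checks therefore distinguish three things: the estimator is *exact* on the
resolved subset; its deviation from the full cohort's realized frequencies
is bounded by the unresolved fraction (a total-variation argument); and
only the dam-transmitted chromosomes -- genuinely i.i.d. draws -- should be
expected to match the configured pool within binomial confidence bands.

## Association models

All models are linear mixed models fitted by REML with sire as a random
intercept (`lme4`/`lmerTest`); if the sire variance estimate is singular
the model collapses to a fixed-effects fit and the result is flagged.
P-values for single coefficients and for the diplotype factor use
Satterthwaite denominator degrees of freedom.  Estimated marginal means
(`emmeans`) average over fixed-factor level combinations with equal
weights, covariates held at their observed means.

**Trait structure.** Birth weight is analysed with gender and birth rank
fixed; tailing and weaning weight with gender, rearing rank and age at
weaning; pre-weaning growth rate with gender and rearing rank; carcass
traits (fat depth V-GR, regional and total lean-meat yields, proportion
yields) with rearing rank and age at slaughter, on males only -- only males
are slaughtered, selected on live weight exceeding 36 kg.  Because the same
litter-size information can enter as birth rank, rearing rank, or birth
weight, `select_structure_term()` fits each candidate on top of the
mandatory terms and picks the largest partial F, with the fixed tie
priority birth rank > birth weight > rearing rank; birth rank as a factor
and birth weight as a covariate are mutually exclusive within one model.

**Tier 1 -- single haplotype.** Presence/absence coding: an animal scores
1 if its diplotype contains the focal haplotype once or twice.  The
presence coefficient (present − absent) with its SE and p-value is
reported alongside the two marginal means.

**Tier 2 -- adjusted.** Any other haplotype whose single-model p-value for
the trait fell below 0.20 is co-fitted as an additional presence factor,
so the focal effect is estimated net of correlated haplotypes (with two
common haplotypes near frequency 0.5 their carrier indicators are strongly
negatively correlated).  With an empty co-fit set the adjusted model *is*
the single model, bit for bit.

**Tier 3 -- diplotype.** Diplotypes with frequency above 5% *on the
trait's analyzed subset* (e.g. slaughtered, phased males for carcass
traits) enter as a fixed factor with gender and birth rank (single-level
factors are dropped automatically -- gender is degenerate on the males-only
subset).  All `k(k-1)/2` pairwise least-significant-difference contrasts
are computed, their p-values multiplied by `k(k-1)/2` and capped at 1 (a
Bonferroni correction over the full family of pairs), and a compact letter
display is assigned by insert-and-absorb: two diplotypes share no letter
exactly when their adjusted p-value is below alpha.  The display is
deterministic (letters ordered by each group's smallest member) and
round-trips the adjusted p matrix, a property the tests assert on random
matrices.

**Thresholds.** Effects are significant at `p < 0.05` and noted as trends
for `0.05 <= p < 0.20`; the boundary `p = 0.05` is classified as a trend,
honouring the strict inequality.  Derived-effect helpers convert model
output into field units: a growth-rate difference accumulates to grams
from birth to weaning (`7.7 g/day over 100 days = 770 g`), and a total
lean-meat yield difference converts to grams of lean meat per carcass
(`0.71 percentage points of an 18 kg carcass ≈ 128 g`).

## The synthetic cohort generator

No individual-level data ship with the package, so the generator *is* the
study population for all end-to-end tests.  Its defaults encode the target
cohort: 17 sire lines, 1185 genotyped progeny distributed evenly, the
eight-haplotype frequency vector (0.3623, 0.0053, 0.1016, 0.4591, 0.0147,
0.0556, 0.0007, 0.0007), a 36 kg live-weight slaughter rule for males, and
presence-coded haplotype effects planted on the common haplotypes
(−8 g/day growth for `A1-A3` carriers, −0.45/−0.18 percentage points on
leg/loin yield; +1.4 mm fat depth for `A1-C3`).  Sires draw two haplotypes
from the pool; each progeny receives one sire haplotype uniformly and one
dam haplotype i.i.d. from the pool (dams are an unmodelled population --
no dam pedigree exists in the data this emulates).

Traits follow `intercept + Σ β_h·presence(h) + gender + rank + sire
deviation + residual`.  Birth weight and growth rate are primary;
weaning weight is *derived* as `birth + growth × age/1000` so the
growth-rate definition holds exactly on generated data (tailing weight is
interpolated at 21 days with noise).  Leg, loin and shoulder yields are
primary; total and proportion yields are derived through
`derive_composition()`, so the composition identities hold to rounding.
Variance components are not published for the real cohort; the defaults
(growth: sire SD 8, residual SD 55 g/day; yields: sire SD ≈ 0.2, residual
SD ≈ 1 percentage point; fat depth: sire SD 0.5, residual SD 1.7 mm) were
chosen once so that marginal-mean standard errors have the order of
magnitude reported for cohorts of this size, and are documented here as
calibration choices, not measured values.  Live weight extrapolates from
weaning weight at a fixed 0.23 kg/day so the 36 kg rule induces a
realistic males-only carcass subset (roughly a third of the cohort).

What the generator does *not* emulate: genotyping error is off by default
(an optional per-region mislabel rate exercises the inconsistency path);
dams carry no pedigree or litter correlation beyond the rank factors;
trait correlations arise only through shared factors, not through a
genetic covariance structure; and no linkage-disequilibrium decay or
recombination exists between the two regions.  Passing tests therefore
demonstrate the correctness of phasing, bookkeeping and model recovery
under the stated generative model -- they do not certify behaviour under
pedigree errors, population stratification, or non-normal residuals.

## Numerical and design notes

* All randomness flows from one mandatory integer seed; the generator
  restores the caller's RNG state, and identical configurations produce
  byte-identical cohort files (17-significant-digit rendering makes the
  write/read round trip exact).
* Haplotype identifiers use an ASCII hyphen (`A1-A3`) in every
  machine-readable output; en/em dashes are accepted on input.
* Rendered frequency tables round percentages by largest remainder so the
  column sums to exactly 100.00.
* Reconstruction ambiguity (no consistent sire candidate, or tied
  support) is surfaced as a flag; affected double heterozygotes stay
  unresolved.  A progeny inconsistent with *every* candidate sire
  diplotype is set aside before the consistency filter so one mistyped
  animal cannot veto its siblings' phasing.
* Default problem sizes in the test suite: ~500 random families against
  the brute-force oracle, one default-size cohort (1185 progeny) for
  recovery checks, and 1000 null replicates at 400 progeny for type-I
  calibration of the presence model -- sizes chosen as the smallest that
  make the stochastic assertions informative.
* Model skips are explicit: an empty presence group, a zero-variance
  trait, or fewer than two frequency-passing diplotypes return flagged
  results rather than errors.

## Known limitations

* The sire-reconstruction score uses directly phased progeny only; in
  principle a likelihood over dam haplotype frequencies could resolve some
  families the support rule leaves ambiguous.
* Unresolved animals are excluded per trait, which slightly over-represents
  homozygous and single-heterozygous animals among those analysed;
  the frequency estimator inherits a corresponding small bias relative to
  the full cohort (bounded by the unresolved fraction).
* The two-region haplotype is treated as one locus; the package does not
  model recombination, SNP-level phase within a region, or more than two
  regions.
* Estimated marginal means use equal weights across factor-level
  combinations; proportionally weighted means would differ in unbalanced
  cohorts.
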
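---
title: "Random-forest association on deregressed breeding values: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest association on deregressed breeding values: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rfgwas` implements a genome-wide association workflow for lowly heritable
carcass traits in pedigreed livestock, of the kind used for ultrasound
backfat thickness in Canchim beef cattle: pedigree BLUP with a known
variance ratio, deregression of breeding values into pseudo-phenotypes,
array-style genotype quality control, random-forest variable-importance
SNP selection, a stepwise regression that decomposes the explained
variance SNP by SNP with a permutation bias check, and LD-window
annotation against gene and QTL intervals. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the methodology left the details open.

## The animal model and breeding values

Phenotypes are modelled as

$$ y = Xb + Zu + e, \qquad u \sim N(0, A\sigma^2_a),\quad e \sim N(0, I\sigma^2_e), $$

where $b$ holds contemporary-group effects (sex x year x herd x genetic
group) and an age covariate, and $A$ is the numerator relationship matrix
built from the pedigree by the tabular recursion. `solve_animal_model()`
solves Henderson's mixed-model equations with $A^{-1}$ assembled directly
by Henderson's rules (with inbreeding), which is numerically stabler and
sparser than inverting $A$. Variance components are inputs, not estimates:
the workflow this package mirrors estimated heritability externally by
REML and carried $h^2 = 0.16$ forward, so `h2` (or
`sigma2_a`/`sigma2_e`) is a parameter. Prediction error variances come
from the inverse coefficient matrix, and accuracy is
$r = \sqrt{1 - PEV/\sigma^2_a}$.

Identifiability of the fixed effects uses the reference-level constraint
(first level of each factor dropped); columns still aliased after that are
reported by name rather than silently dropped.

## Deregression

EBVs are shrunken and contain parent-average information, both of which
bias SNP association; `deregress_ebv()` removes them. The default mode
reconstructs, from the animal's reliability $r^2$ and its parent-average
reliability $r^2_{PA} = (r^2_{sire} + r^2_{dam})/4$, the 2x2 mixed-model
system in (parent average, individual effect) whose information contents
are the unknowns. Writing $q_i = 1 - r^2$ and $q_{PA} = 1 - 2 r^2_{PA}$,
the determinant $D$ of the system satisfies a quadratic with the positive
root

$$ D = \lambda^2 \frac{1 + \sqrt{1 + 8 q_i q_{PA}}}{q_i q_{PA}},
   \qquad \lambda = \frac{1 - h^2}{h^2}, $$

from which both information contents and then the deregressed proof
follow. When both parents are unknown the parent-average equation drops
out and the solution is exactly the simple form $dEBV = EBV/r^2$ (also
available as `mode = "simple"`). Weights for downstream weighted analyses
are $w = (1 - h^2) / ((c + (1 - r^2_d)/r^2_d) h^2)$ with $c$ the fraction
of genetic variance not captured by markers; $c$ and the reliability
floor (default 0.1, below which animals are excluded rather than divided
by a near-zero reliability) are configuration, because the source
workflow names the deregression method only by citation and reports
neither constant.

A note on validation: a deregressed proof is an unbiased, noisy record of
the true breeding value, so the calibration test regresses dEBV on true
(simulated) breeding values and expects slope 1. The reverse regression
(TBV on dEBV) is attenuated by the proof's reliability and would sit far
below 1 at $h^2 = 0.16$ by construction, not by error.

## Genotype quality control and imputation

`qc_filter()` applies, in a fixed and reported order: (1) samples with
call rate < 0.90; (2) SNPs with call rate < 0.90 or MAF < 0.01, with MAF
recomputed after sample removal so failed samples cannot distort allele
frequencies; (3) samples whose heterozygosity deviates from the cohort
mean by more than 3 SD. The heterozygosity filter is taken per sample --
the conventional array-QC reading of a "3 SD heterozygosity" rule; a
per-SNP variant is available via `het_on = "snp"` since the source
description does not disambiguate. Every removal carries exactly one
primary reason in the QC report, and the filter is idempotent.

Missing genotypes are imputed by the naive column-median rule
(`impute_median()`): each missing call becomes the median of the SNP's
observed dosages. The median of an even count is the midpoint, so imputed
dosages may be 0.5 or 1.5; downstream code accepts fractional dosages and
the PED writer (which cannot represent them) refuses them explicitly.

## Random-forest selection

`rf_importance()` fits a regression forest of dEBV on dosages with
5,000 trees and `mtry` equal to 10% of the SNPs being evaluated
(`max(1, floor(0.1 p))`), reporting permutation importance (mean decrease
in out-of-bag squared-error accuracy); impurity importance sits behind a
flag. The forest engine is `ranger`, run single-threaded so a seed fully
determines the result; a cross-check test confirms rank agreement with
the classic `randomForest` implementation on a planted signal.

The two-step selection (`two_step_select()`) keeps the top 1% of SNPs by
importance *within each chromosome* (stage 1), then refits the forest on
the stage-1 set only and keeps the top 1% *pooled* (stage 2). Rounding is
`max(1, floor(fraction * n))`: floor is the only convention under which
708,641 input SNPs force exactly 70 stage-2 candidates regardless of how
the SNPs split across 30 chromosomes, and the `max(1, .)` guard prevents
chromosome dropout. Stage 2 refits rather than reusing stage-1 scores
because the selection is described as a re-analysis disregarding
chromosome assignment.

Two candidate strategies are built on top. *Highest 1%* is the stage-2
set of the full-sample run. *Common SNPs* keeps SNPs present in the
full-sample stage-1 set and in at least `min_subsample_hits` of the
subsample runs; the membership rule is configurable because the published
candidate counts (162 for Common vs 70 for Highest-1%) rule out a strict
intersection but do not pin the rule down. Subsamples
(`build_subsamples()`, 10 of 198 by default) are grown greedily: a random
start, then repeatedly the animal with the lowest mean relationship to
the selected set, ties broken by the highest mean relationship to the
remaining animals (most representative of the rest), then by id. The
greedy target is the selected-set mean rather than only the previously
added animal; the source description supports either reading, and the
set-mean version is the one that actually reduces within-subsample
kinship (a property the tests check against random subsets).

## Stepwise regression and the permutation bias test

`forward_stepwise()` is the classic entry/stay procedure on 0/1/2
dosages with an intercept and no standardization: enter the candidate
with the smallest partial-F p-value while it is below `sl_entry`
(default 0.15, the long-standing default of the stepwise implementations
this mirrors; the source does not state its levels), then remove any
predictor whose p-value has risen to `sl_stay`. Sequential partial R^2
values are recomputed over the surviving predictors in entry order, so
they are nonnegative and sum to the model R^2 to machine precision --
this is the "% dEBV" decomposition reported per SNP. Zero-variance and
numerically collinear candidates (residual variance below 1e-10 of their
total) are skipped with warnings rather than destabilizing the solve.

The permutation test shuffles the response 1,000 times and refits the
*same* selected SNPs. The statistic defaults to the **adjusted** R^2 of
the fixed model: under the null the raw R^2 has mean $p/(n-1)$ -- about
0.053 at $p = 21$, $n = 396$, which could not print as "0.00 +/- 0.02" --
while adjusted R^2 has null mean ~0 and SD ~0.017, which rounds to
exactly that. A `statistic = "stepwise"` mode re-runs the whole selection
per shuffle for the alternative reading. The raw-statistic null is
cross-checked against the closed form $R^2 \sim
\mathrm{Beta}(p/2, (n-p-1)/2)$ in the tests.

## LD windows and annotation

`pairwise_r2()` computes composite LD from unphased dosages: the squared
Pearson correlation between dosage vectors of same-chromosome SNP pairs
within a distance cap. This replaces the phasing + haplotype-block
pipeline of the source workflow (fastPHASE + Haploview); under
Hardy-Weinberg the genotypic correlation converges to the haplotype
r^2, and avoiding phasing keeps the module dependency-free and
deterministic. It is a documented deviation, not an approximation the
results are sensitive to at the window scale used. `ld_decay()` reports
both the per-bin mean and the cumulative mean up to each bin edge, since
an "average r^2 at a distance" can be read either way.

Windows are `position +/- 250 kb`, 1-based inclusive, clamped at the
chromosome start. Features load from BED (0-based half-open, converted at
the reader boundary) or GFF3 (native 1-based); chromosome labels are
compared after stripping a "chr" prefix case-insensitively. A feature is
reported for a window iff the intervals share at least 1 bp; the
implementation uses `IRanges` overlap machinery and is property-tested
against a brute-force all-pairs loop.

## The synthetic herd generator

Because the genotypes behind the motivating study are not deposited,
`sim_config()` + `simulate_pedigree()` / `simulate_genotypes()` /
`simulate_phenotypes()` generate a herd emulating its design: a final
cohort sired by 50 bulls with 1-30 offspring each out of a dam pool,
above which sit configurable ancestor generations (the real pedigree's
generational structure around its 6,801 animals is unpublished, so depth
is a parameter); sexes Bernoulli(0.5); contemporary groups formed by
randomly crossing 2 sexes x 3 years x 7 herds x 2 genetic groups; age
~N(550, 30) days with a slope of 0.002 trait units/day; heritability
0.16 with phenotypic variance 1 (backfat SDs are of order 1 mm, and only
ratios matter downstream).

Genotypes arise by gene dropping: founders draw two haplotypes from a
finite pool, and descendants receive Poisson-recombined parental gametes
(1 cM/Mb, uniform crossover placement -- no genetic map is available to
do better). The finite pool is what creates LD; pool haplotypes are
Markov chains along the chromosome whose correlation length tunes the
decay. The shipped defaults -- 29 chromosomes x 170 SNPs over 10 Mb each
(an HD-array density scaled down ~140x), pool of 40, correlation length
200 kb -- were calibrated once so the genotyped cohort's mean r^2 in the
225-275 kb bin is ~0.12, matching the LD level the study reports at
250 kb, and then frozen. Founder MAF is floored (default 0.02) by
seeding minor alleles into founder haplotype copies of rare SNPs; the
floor is a founder-generation guarantee, and drift may still push
descendants below it (which is what the MAF QC filter is for).
Missingness is MCAR (0.5% default) -- the real missingness mechanism is
uncharacterized, and MCAR is the weakest assumption that exercises the
call-rate filters and imputation.

Planted trait architectures (`trait_architecture()`) pick QTL from the
genotyped panel (so selection can in principle recover them exactly;
masking them for tag-only experiments is an option), scale effects so the
QTL variance is a set fraction (default 50%) of the additive variance,
assign the remainder to a pedigree polygenic term simulated by the
gene-flow recursion consistent with $A$, and keep true breeding values
alongside the phenotypes for recovery tests.

What the generator does *not* emulate: coalescent site-frequency spectra,
selection or migration history, genotyping error, sex chromosomes, or
maternal/permanent-environment effects. Passing tests therefore
demonstrate that the pipeline recovers what it should under a clean
additive model at realistic LD and heritability -- not that it is robust
to artifacts these processes create in real data.

## Problem sizes and numerical choices

Tests and examples run at desk scale, chosen to finish in minutes on one
CPU while staying at the study's structural proportions: herds of one to
two thousand pedigree animals, ~400 genotyped, ~5,000 SNPs, forests of
150-500 trees (5,000 remains the analysis default), permutation counts of
50-1,000. At 5,000 SNPs a literal 1% two-step keeps a single stage-2 SNP
(the floor rule), so recovery experiments use `fraction = 0.1`, which
reproduces the study's candidate-set scale (~500 stage-1, ~50 stage-2
SNPs against its 7,086 and 70). The planted-QTL recovery checks give the
ten QTL comparable magnitudes (random sign): with N(0,1) effect draws a
tail of near-zero QTL is unfindable by any method, which tests the
architecture draw, not the selector.

Other numerical choices: the MME are solved by a dense factorization and
the full inverse is kept because PEV needs its diagonal (fine to a few
thousand animals; larger problems would want sparse partial inversion);
ties in importance and p-values break by score then lexicographic SNP id
so runs are reproducible; the master seed derives per-stage seeds as
`(seed * 1009 + 97k) mod (2^31 - 1)` so any stage can be re-run in
isolation; collinearity in stepwise uses a relative 1e-10 residual
threshold; permutation R^2 is computed from one QR factorization of the
design with each shuffle a single crossproduct.

## Known limitations

- REML variance estimation is out of scope by design; a wrong `h2`
  biases accuracies and deregression exactly as it would in the source
  workflow.
- The deregression constants ($c$, reliability floor) and the Common-SNP
  membership rule are exposed as configuration because the underlying
  report does not determine them; results can be sensitive to both.
- Composite genotypic r^2 slightly underestimates haplotype r^2 away
  from Hardy-Weinberg equilibrium.
- The A-matrix and MME code is dense and targets herds of up to a few
  thousand animals, not national evaluations.
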
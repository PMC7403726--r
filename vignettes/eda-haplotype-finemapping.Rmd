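---
title: "Fine-mapping a short haplotype: models and methods in edamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a short haplotype: models and methods in edamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edamap)
```

## The scientific setting

Threespine stickleback repeatedly lose their bony lateral plates when they
colonise fresh water, and most of that change maps to a ~16-kb haplotype at
the *Eda* locus.  Marine populations carry the freshwater ("L") haplotype at
low frequency, sometimes in truncated ("short-L") forms, and polymorphic
freshwater populations contain chromosomes that recombined inside the
haplotype generations ago.  Those historical recombinants break up linkage
disequilibrium between markers only kilobases apart, so a dense marker panel
plus a large phenotyped sample can localise which part of the haplotype
drives which trait — plate number, lateral-line neuromast patterning,
neuromast counts, gill raker length, and morphometric landmarks.

`edamap` implements the full analysis stack for this design: data curation
and rule-based imputation, haplotype carrier classification, per-marker
LOD/PVE association scans under covariate models, stratified permutation
significance, detectable-effect power analysis, and two-locus contrasts —
together with a synthetic population generator so every stage is testable
without access to the original collections.

## Genotype model and carrier classification

Markers are biallelic with alleles **C** (associated with complete plating,
typical of marine fish) and **L** (the freshwater haplotype allele).
Unphased diploid calls are `CC`, `CL`, `LL` or missing, and chromosomes come
in three non-recombinant forms: all-C, all-L, and *short-L* — an L block
anchored at the 5' end of the region with C alleles beyond.

Classification works on the L-allele **dosage** (CC = 0, CL = 1, LL = 2).
Any unordered pair of non-recombinant chromosomes produces a dosage profile
that is monotone non-increasing from 5' to 3', and conversely every monotone
non-increasing profile decomposes into two such chromosomes (take one
chromosome to be L wherever dosage ≥ 1 and the other L wherever dosage = 2;
both are 5'-anchored L blocks).  An individual is therefore called a
**historical recombinant** exactly when its observed dosages *increase*
somewhere along the region; each increase is reported as a breakpoint
interval.  Missing calls act as wildcards: they are consistent with, never
evidence of, recombination — the conservative reading of a visual-genotype
matrix.

Two deliberate consequences of this definition:

* A profile such as `LL, CL, …, CL, CC` is *not* a recombinant: it is two
  short-L chromosomes of different extents (`hom_short_L`).  Only patterns
  that cannot be phased onto 5'-anchored blocks (e.g. `CC, CL, …, LL`) are
  recombinant.  Short-L haplotypes are standing variation in this system, so
  treating 5'-anchored het blocks as a carrier class rather than as
  recombination matches how the field reads these matrices.
* The NAKA SNP — a single intergenic site whose L allele also segregates on
  completely plated backgrounds — is exempt from the *full-L* class checks:
  a fish heterozygous at every region marker except NAKA is still a full-L
  carrier.  The exemption applies only there; NAKA participates in the
  dosage monotonicity check like any other marker.

The classifier is validated against a brute-force oracle that enumerates
all unordered pairs over {all-C, all-L, every 5'-anchored chimera} for an
8-marker panel (all 3^8 genotype vectors).

## Imputation and trimming

Missing genotypes are filled only under a strict flanking-marker rule: a
maximal missing run of length ≤ 3 is filled with `a` when both nearest
observed flanks equal `a` *and* no other individual observed at a run
marker, whose genotypes at the same two flanking markers are both `a`,
carries a different genotype there.  The second clause is a congruence check
against the dataset itself: such an individual would directly evidence a
breakpoint between the flanks, voiding the no-double-recombination
assumption the fill rests on.  The check is deliberately conditional on
matching flanking genotypes (the stricter of the readings the rule admits);
the per-call trace in the imputation report records this.  Runs touching the
panel edge have only one flank and are never filled.  The rule is
deterministic and row-order invariant, and on non-recombinant truth with
masked runs it is exact — the test suite asserts 100% recovery of every
rule-eligible call.

Because rule-based filling can still be wrong on recombinant chromosomes,
the conservative analysis path trims instead: markers missing in more than
half the individuals are deleted outright, then individuals with any
remaining missing call are dropped (`trim_genotypes()`), and per-trait
analyses are listwise per marker in any case.

## Association model

For each trait a declarative `model_spec()` names the covariates of the null
model — e.g. family, standard length, sex, and their interactions for a
cross design; sex, size, collection month, staining covariates and selected
interactions for wild-caught fish.  The alternate model adds the focal
marker genotype as an **unordered 3-level factor** (up to 2 df), because the
traits show dominance and a factor captures both additive and dominance
components.  Both models are ordinary least squares, and

$$\mathrm{LOD} = \frac{n}{2}\,\log_{10}\frac{RSS_0}{RSS_1},
\qquad
\mathrm{PVE} = 100\,\bigl(1 - 10^{-2\,\mathrm{LOD}/n}\bigr)
= 100\,\Bigl(1 - \frac{RSS_1}{RSS_0}\Bigr),$$

with $n$ the number of samples entering both fits (the total-$n$ multiplier,
exactly as the formula is conventionally printed, not residual df).  Both
fits use the same listwise-complete subset per marker, and $n$ is reported
per marker.  Curation removes rows by declarative category predicates
(e.g. poor staining quality), then trait values more than 4 SD from the
post-filter mean in a single, non-iterated pass.

**Adjusted trait values** for plotting and class contrasts are each fish's
residual plus the model prediction at its genotype with covariates held
equal — factors at reference levels, continuous covariates at their sample
mean.  The reference choice shifts every value by the same constant, so
contrasts are invariant to it; the defaults (first observed level, sample
mean) are overridable in the model spec.

## Permutation significance

LOD significance is assessed by permuting whole genotype *rows* (all
markers jointly, so within-individual haplotype structure is preserved)
among individuals **within strata** — families with comparable haplotype
sizes in crosses, collection month in wild samples — while trait and
covariates stay fixed.  Permuting genotypes rather than traits preserves the
covariate–trait relationship under the null of no genotype effect.  The
p-value estimator is $(1 + r)/(1 + N)$ with $r$ the count of permuted
statistics at or above the observed one, which cannot return zero.  The LOD
threshold is the nearest-rank $(1-\alpha_{adj})$ quantile of the permutation
distribution, with $\alpha_{adj} = 0.05/\#\text{traits}$ (Bonferroni).  Two
modes are exposed, since either could back a published threshold: the
default `max` mode uses the per-permutation maximum LOD across the panel
(family-wise control over markers), `per_marker` tests a single focal
marker.  The default permutation count is 5000; the calibration tests in
this package use 1000 permutations per replicate at $n = 400$ to keep 500
replicates tractable, and confirm the empirical type-I error sits inside
the binomial 95% interval around 0.05.

The permutation engine recomputes the null fit by QR once and adds the
permuted genotype block by Frisch–Waugh residualisation; the test suite
asserts it agrees with the `lm()`-based scan to 10^-10.

## Power analysis

The error variance is $\sigma^2 = RSS_1/(n - p - 1)$ with $p$ the number of
fitted parameters excluding the intercept.  The minimum detectable variance
share at a target power (default 90%) treats the likelihood-ratio statistic
$2\ln(10)\,\mathrm{LOD}$ as non-central $\chi^2$ with the genotype df
(default 2) and non-centrality $2\ln(10)\,\mathrm{ELOD}$, where
$\mathrm{ELOD} = -(n/2)\log_{10}(1-q)$; the smallest $q$ whose power reaches
the target is found by bisection (power is monotone in $q$), returning the
upper bracket so the achieved power is never below target.  On the
variance-share scale $\sigma^2$ cancels; it is used only to report the
corresponding absolute genotype-class offset.  The approximation is
cross-validated in the test suite against a 2000-replicate Monte-Carlo power
estimator at $n \in \{100, 500\}$ and thresholds 2.6/2.9: analytic power at
the returned share stays within ±0.03 of simulation, and inverting the
Monte-Carlo power curve lands within one PVE point of the analytic answer.

## Two-locus contrasts

`two_locus_table()` cross-tabulates adjusted trait values over the ≤ 9
genotype combinations at two markers and evaluates declaratively specified
cell-set contrasts with pooled-variance Student t tests
($df = n_A + n_B - 2$; the pooled rather than Welch form matches the df
structure such analyses report).  The canonical contrasts are data, not
code: CC-vs-CL at the major locus (expected null under dominance),
(CC∪CL)-vs-LL (the dominance signature), and LL-vs-rest at the 3' locus
within the LL major-locus background (the epistasis signature).

## The synthetic population generator

`generate_population()` draws two chromosomes per individual from a
haplotype pool, applies historical recombination, generates covariates, and
builds the trait as intercept + covariate effects + locus effects +
Gaussian noise.  The defaults emulate the structure of a polymorphic
freshwater population sampled across months:

| parameter | default | meaning |
|---|---|---|
| panel | 17 markers over 16 kb | SNP/indel assays, 5' `Stn382` … 3' `SNP13`, NAKA mid-region |
| pool | C 0.55, full-L 0.30, short-L 0.15 | short-L extends to ~11 kb, within the 10–12 kb range such haplotypes span |
| `recombinant_fraction` | 0.22 | fraction of fish carrying a recombined chromosome |
| architecture | dominant major locus at `Stn382`, PVE 0.90; epistatic 3' locus at `SNP13`, PVE 0.02 | the dominant-major / conditional-minor architecture of the plate and lateral-line traits |
| covariates | sex ±0.3, length slope 0.05/mm (SD 6 mm), family/month effects SD 0.3 | modest, realistic confounding |
| `missing_rate` | 0.02 | per-call dropout, runs capped at 3 |
| `noise_sd` | 1 | residual SD in trait units |

Pool frequencies put the 5' L-allele frequency at 0.45 — the intermediate
frequency an interbreeding polymorphic population needs for informative
genotype classes at every marker; the region-wide L frequencies and the
short-L extent are user-configurable, since the empirical short-L length
distribution is known only coarsely.

Numerical choices worth stating:

* **Breakpoints** are uniform over inter-marker intervals, one per
  recombined chromosome (no double recombination within the region — the
  same assumption the imputation rule relies on).
* **Orientation.**  Recombined chromosomes are marine-5'/freshwater-3'
  chimeras.  The complementary orientation produces exactly the allele
  pattern of a standing short-L haplotype, which no unphased-data classifier
  could distinguish from the short-L class; generating only the
  distinguishable orientation keeps "fraction of recombinant carriers" a
  well-defined, recoverable quantity.  Real recombinants of the other
  orientation would be absorbed into the short-L classes, there as here.
* **Effect solving.**  A locus effect is an offset $a$ on an indicator $z$
  (LL cell for dominant/recessive modes, dosage for additive, the joint
  LL×LL cell for the epistatic mode), with
  $a = \sqrt{q\,T/\mathrm{var}(z)}$ and
  $T = (\sigma^2 + \mathrm{var}(\text{covariate effects}))/(1 - \sum q)$,
  using the realized sample variances.  For a single-locus architecture the
  realized marginal variance share converges to `target_pve` (checked at
  $n = 10{,}000$ within ±0.01).  With several loci on one haplotype the
  indicators are necessarily correlated (the epistatic cell is nested in
  the major-locus LL class), so marginal shares also absorb cross-locus
  covariance — exactly as marginal PVE at a 3' marker absorbs LD with the
  major locus in the real system.  `target_pve` is therefore each *term's*
  own share of total variance.
* **Counts** can be produced as rounded, zero-truncated Gaussians
  (`trait_type = "count"`), matching the linear-model analysis rather than
  any count-process biology; the continuous default is used wherever exact
  variance-share arithmetic matters.
* `target_pve` up to ~0.94 with the default noise keeps the variance budget
  feasible; shares summing to ≥ 1 are a hard error.

What the generator does **not** emulate: multi-generation pedigree
structure (families are an exchangeable covariate, not a genetic unit),
genotype–covariate correlation, genotyping error (missingness is random
dropout, not allele-specific failure), and any selection or coalescent
history behind the pool frequencies.  Passing tests therefore demonstrate
correctness of the estimators under the stated statistical structure, not
robustness to those real-data complications.

## Problem sizes used in the test suite

The calibration experiments are sized to be informative yet routine to run:
type-I error uses 500 null replicates of $n = 400$ with 1000 permutations
each; PVE recovery uses 100 replicates of $n = 700$ per effect size in
{0.25, 0.5, 0.75, 0.9}; the classifier oracle is exhaustive over all 6561
genotype vectors of an 8-marker panel; Monte-Carlo power uses 2000
replicates per grid point.  These sizes were chosen so the binomial /
sampling error of each check is several times smaller than the tolerance it
asserts.

## Known limitations

* The congruence check scans all individuals with matching flank genotypes;
  whether the original curation conditioned on matching flanks or on any
  sample at the marker is ambiguous — the stricter conditional form is
  implemented and traced in the report.
* Strata for the permutation test are user-supplied; the package does not
  infer which families share haplotype sizes.
* The power approximation is a non-central chi-square likelihood-ratio
  approximation, accurate to a few percent of power in the validated range;
  very small $n$ (tens) or thresholds far above 3 were not validated.
* No statistical phasing, no reference-panel imputation, no mixed models or
  kinship correction: the design is a single dense region in samples where
  OLS with explicit covariates is the intended analysis.
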
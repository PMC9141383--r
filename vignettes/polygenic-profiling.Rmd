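---
title: "Polygenic profiling and epistasis search for candidate-SNP case-control panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic profiling and epistasis search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprofile)
```

## The scientific setting

Sport-related concussion risk and recovery are plausibly polygenic: several
candidate polymorphisms have been associated with traumatic-brain-injury
incidence or outcome, and in a collision sport a genetically mediated
resistance to concussion could be selected for at the elite level.
`polyprofile` implements the analysis machinery for testing this idea on a
case-control design: a panel of eight candidate polymorphisms (ANKK1
rs1800497, APOE rs429358 + rs7412 + rs405509, BDNF-AS rs6265, COMT rs4680,
MAPT rs10445337, NOS3 rs2070744) genotyped in elite rugby athletes (n = 635,
with rugby-union forward/back and rugby-league subgroups) and in
non-athletes (n = 722). The same machinery applies to any small
candidate-SNP panel with categorical genotype attributes.

Because individual-level genotypes for such cohorts are not generally
redistributable, the package is built to be fully exercisable from its
synthetic-cohort generator, which draws cohorts from the published per-locus
genotype frequency table (`rugbyFrequencies()`); every analysis stage is
therefore testable end to end without any external download.

## The Total Genotype Score

The TGS is an additive score over seven components under the assumption of
codominant allele effects. For each bi-allelic component the 'preferable'
homozygote scores 2, the heterozygote 1 and the other homozygote 0. APOE is
tri-allelic: the epsilon2/epsilon3/epsilon4 haplotypes are defined jointly
by rs429358 and rs7412, and the component scores 2 for epsilon4 non-carriers
and 0 for carriers, with no intermediate score. With seven components the
score is scaled onto 0-100 by

$$\mathrm{TGS} = \frac{100}{14}\sum_{i=1}^{7} s_i, \qquad s_i \in \{0,1,2\},$$

so 100 is the 'perfect' profile, 0 the 'worst', and the attainable values
are the fifteen multiples of 100/14 (hence the characteristic printed
scores such as 21.4, 50.0, 92.9). `scoreCohort()` keeps full precision and
leaves 1-decimal rounding to display.

Two scoring schemes are built in. The `"literature"` scheme allocates the
'preferable' genotypes from prior TBI literature (ANKK1 GG = 2, APOE e4- = 2,
rs405509 GG = 2, BDNF-AS CC = 2, COMT AA = 2, MAPT CC = 2, NOS3 TT = 2).
The `"data_led"` scheme instead takes the direction observed in elite rugby
athletes, re-scoring rs405509 (TT = 2, GT = 1, GG = 0) and COMT (GG = 2,
GA = 1, AA = 0).

A third preset, `"literature_nos3_flipped"`, exists because the published
description of the data-led scheme lists NOS3 TT = 2 among "three" changed
scores even though the literature table already scores NOS3 TT = 2 — an
internal inconsistency in the source material. Under linkage equilibrium
the expected literature-scheme cohort means computed from the frequency
table reconcile with the published literature-based means (≈ 56.4-56.5)
only if that scheme had scored NOS3 CC = 2, so the flipped preset is
provided for users who want to explore that reading. No preset is asserted
to be the historically used literature scheme; all quantitative
benchmarking in this package uses the unambiguous data-led scheme and the
scale anchors, which are scheme-independent.

### Missing components

The default policy is complete-case: an individual missing any component
(including an unresolvable APOE diplotype) gets no TGS and is excluded from
TGS analyses. This matches a design in which per-analysis ns fall slightly
below the full cohort sizes. `missing = "impute"` optionally substitutes
the group-expected component score computed from the cohort's own genotype
frequencies; it is never the default because it shrinks variance.

## APOE epsilon derivation

Over the haplotype (rs429358, rs7412), epsilon2 = (T,T), epsilon3 = (T,C)
and epsilon4 = (C,C); (C,T) is the rare epsilon1 haplotype, which the
scoring does not model. Unphased genotype pairs resolve uniquely except the
double heterozygote C/T + C/T, whose two resolutions are {e2,e4} and
{e1,e3}. `deriveApoe()` follows the standard convention of excluding
epsilon1 and assigning e2/e4; `ambiguous = "exclude"` drops such records
instead. Combinations whose every resolution contains epsilon1 (for
example rs429358 C/C with rs7412 T/T) are flagged unresolvable and excluded
from epsilon-based scoring. Records with a missing or unresolvable APOE
pair are excluded from analyses that need the epsilon attribute; the QC
report counts them.

## Hardy-Weinberg QC

`hweTest()` estimates the allele frequency from the genotype counts,
forms expected counts $np^2, 2npq, nq^2$ and reports the uncorrected
Pearson chi-square on 1 df. No continuity correction is applied, matching
the convention of the mainstream statistics packages this toolkit mirrors.
Each group is tested separately (`hweTable()`); a monomorphic locus is
reported as not applicable rather than as p = 1, since the test statistic
is undefined there. The derived APOE epsilon attribute is not a bi-allelic
genotype and is not HWE-tested.

## The statistical toolkit

* **Pearson chi-square** (`chi2Contingency()`): uncorrected, with Cohen's
  effect size $w = \sqrt{\chi^2 / n}$ attached. Uncorrected matches the
  reconciliation of the published odds ratios with the printed proportions.
* **Power planning** (`chi2PowerN()`): the power of a chi-square test at
  total sample size $N$ and effect size $w$ is
  $P[\chi^2_{df}(\lambda = N w^2) > \chi^2_{df,1-\alpha}]$, strictly
  increasing in $N$; the solver root-finds the exact crossing and returns
  the minimal integer $N$. At $w = 0.1$, df = 1, $\alpha = 0.05$, power
  0.8 this gives 785 participants; at $w = 0.13$, 465 (exact crossing
  464.4).
* **Odds ratios** (`oddsRatio()`): OR = ad/bc with the Woolf log-method CI;
  the Haldane-Anscombe +0.5 correction engages only when a cell is zero.
  `oddsRatioFromProps()` converts two proportions directly.
* **ROC/AUC** (`rocAuc()`): the Mann-Whitney pair-counting AUC via
  midranks (ties count 1/2), with the Hanley-McNeil standard error by
  default and DeLong by flag; the p-value is the normal approximation of
  AUC − 0.5. With a 15-point discrete score the ROC is coarse, which is
  fine for the AUC itself.
* **t-test** (`tTestInd()`): Student's pooled-variance two-sided test by
  default (the default of the package lineage the workflow mirrors),
  Welch by flag.
* **Quartile comparison** (`quartileMembership()`): cut-points are
  linear-interpolation quartiles of the *pooled* distribution of both
  groups (type-7 quantiles); the bottom quartile is `score <= Q1`, the top
  `score >= Q3`, the middle half excluded. Pooling was chosen because the
  comparison asks whether the groups are differently represented in the
  extremes of a common score distribution; with heavy ties on a 15-point
  scale the realised tail fractions can deviate from 25%, identically for
  both groups.

## Multifactor dimensionality reduction

`mdrSearch()` is a from-scratch MDR implementation. For a candidate
attribute combination, individuals are partitioned into multilocus genotype
cells; a cell is labelled **high-risk** if its training case:control ratio
reaches the threshold $T$ (the overall case:control ratio of the training
split, recomputed per fold; ratio ties label high, a cell with cases and no
controls is high), otherwise low-risk. The labelled table is a
one-dimensional classifier — predict 'case' in high cells — whose
**balanced accuracy** (mean of sensitivity and specificity) is the search
criterion. Balanced accuracy is the modern MDR convention and the right
choice for the unbalanced 635:722 design; with balanced data it reduces to
ordinary accuracy, and majority-style labelling maximises it over all
possible labelings (property-tested against exhaustive enumeration).

The search is exhaustive over all combinations of each size in `kRange`
inside stratified 10-fold cross-validation (seeded shuffle): per fold the
best combination of each size on the training 9/10 is evaluated on the
held-out 1/10. The **cross-validation consistency** (CVC) of a size is the
number of folds selecting its modal combination; the final model maximises
CVC with ties broken by higher mean testing balanced accuracy, then by
name for determinism. Cells unseen in training predict low by default
(`emptyCell = "abstain"` removes them from the testing denominator
instead). With `folds = 1` the procedure reduces to maximising
whole-sample balanced accuracy, which the tests match against a brute-force
oracle.

By default the cohort contributes the same seven attributes as the TGS
components, with rs429358/rs7412 merged into the binary epsilon4-carrier
attribute; `apoe = "raw"` keeps them as two three-level attributes for
users who read the "eight polymorphisms" design as eight raw attributes.

The companion `carrierCombinationFrequency()` quantifies a selected
interaction as an allele-combination carrier rate: an individual is a
carrier iff it holds at least one copy of the listed allele at every listed
locus (e.g. COMT G + MAPT C), over individuals with complete calls at those
loci. Carrier-level counting reproduces the published combination
percentages under linkage equilibrium; a chromosome-level (2N denominator)
counting mode is provided for frequency comparisons phrased at allele
level, using the per-individual minimum allele dosage across loci as an
unphased proxy for haplotype counts (phase is not modelled, so this is an
approximation and no p-value is attached to it by default).

## The synthetic-cohort generator

`simulateCohort()` draws each locus independently — the panel's loci lie on
different chromosomes, so linkage equilibrium is the appropriate null
structure — using the frequency table's proportions as exact category
probabilities (they are published without per-SNP denominators, so they are
taken at face value). Two modes exist: `"genotype"` reproduces the printed
category frequencies as-is (including their slight departures from HWE),
`"hwe"` draws Hardy-Weinberg proportions at the implied allele frequencies.

The APOE pair is generated through the epsilon haplotypes so that the
derived attribute hits the published epsilon4-carrier rate: the epsilon4
allele frequency is calibrated by $f_4 = 1 - \sqrt{1 - P(e4+)}$, the
epsilon2:epsilon3 ratio is held at the European reference 0.08:0.77 and
renormalised, two alleles are drawn independently per individual, and the
diplotype is back-converted to rs429358/rs7412 genotypes. Only epsilon4
carriage feeds any downstream statistic in this workflow, so the reference
ratio affects nothing but the realistic marginals of the two raw SNPs.

Missingness is completely at random per call at a configurable rate (no
mechanism is published; MCAR is the neutral default). Planted effects are
expressed as a two-locus penetrance table (`penetrancePlant()`):
individuals become cases with their cell's probability. The XOR-style
table (`xorPenetrance()`, case probability 0.9 when exactly one locus is
heterozygous, 0.1 otherwise) has constant single-locus marginals at
heterozygote frequency 1/2, making it a pure interaction: single-locus
tests see nothing, and recovering it is the canonical positive control for
the MDR search.

What the generator deliberately does not emulate: linkage disequilibrium,
population stratification or admixture, genotyping error, per-position
athlete subgroup frequencies (unpublished — subgroups draw from the pooled
athlete table), and any real TGS-phenotype association. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under the stated null/planted structures, not biological claims about real
cohorts.

## Numerical and design choices

* Kurtosis is the bias-corrected sample excess kurtosis
  $G_2 = \frac{(n-1)}{(n-2)(n-3)}[(n+1)g_2 + 6]$ with the closed-form
  standard errors $SE(g_1) = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$,
  $SE(G_2) = 2\,SE(g_1)\sqrt{(n^2-1)/((n-3)(n+5))}$ — the definitions used
  by the mainstream statistics packages whose output the summaries mirror.
  Kurtosis is reported as NA for n < 4 or constant samples.
* Quantiles are R's default type-7 linear interpolation throughout.
* All stochastic operations (simulation, fold assignment, penetrance
  labelling) are driven by explicit integer seeds; a fixed seed reproduces
  cohorts, fold assignments, selection paths and reports byte-identically.
* `enumerateTgs()` computes the exact TGS distribution over the full
  genotype product space (≤ 3^6 × 2 = 1458 cells) with cell probabilities
  from the frequency table; it is the analytic oracle the simulated means
  are tested against. Under the data-led scheme it gives 59.7 (athlete
  frequencies) and 58.7 (non-athlete frequencies) on the 0-100 scale.
* Test problem sizes: convergence checks use cohorts of 10^5 (frequency
  recovery) and 2 × 10^4 (mean convergence, 4 SEM band); calibration
  checks use 1000 null replicates for the type-I error of the chi-square,
  t and HWE tests and 20 seeded replicates of the full 635 + 722 design
  for cohort-level summaries. These sizes keep Monte-Carlo error well
  below the tested tolerances.

## Limitations

The package analyses a fixed small panel with equal component weighting;
it does not fit weighted or dosage-based scores, logistic models, or any
LD-aware structure. The MDR implementation searches at most the panel's
handful of attributes (exhaustive search is instant at this scale) and
estimates no permutation p-values — published significance claims for
selected interactions rest on frequency chi-squares, which are in scope.
The allele-level counting mode is an unphased approximation. Synthetic
cohorts are a modelling device: they validate machinery, not biology.
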
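---
title: "Dissecting a GWAS locus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a GWAS locus: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagfun)
```

`tagfun` implements the statistical spine of a post-GWAS locus dissection:
starting from per-study case-control summary statistics at an associated
region, it combines them by fixed-effects meta-analysis, screens variants
through standard genotype QC, narrows the credible candidates by exploiting
weaker linkage disequilibrium (LD) in admixed populations, asks whether an
apparently inconsistent tag SNP is in fact *expected* under the region's LD
structure, and finally scores candidate functional mechanisms — a
genotype-dependent transcription-factor/target coexpression test and
allele-level motif scoring.  Every stage can run on synthetic inputs
produced by the package's own generators, because the cohort genotype and
expression data such analyses normally consume sit behind controlled
access.

This vignette records the models, the tunable parameters and their
defaults, and the choices made where the design was genuinely open.  It
states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## Meta-analysis of per-study odds ratios

Per-study effects enter as log odds ratios $\beta_i$ with standard errors
$s_i$.  When only the printed "OR (95% CI)" is available, the SE is
recovered as $s = (\ln \mathrm{hi} - \ln \mathrm{lo}) / (2z)$ with
$z = 1.959964$ — the convention of standard meta-analysis software rather
than the rounded 1.96, although at two printed decimals the difference is
far below the reproduction tolerance.  A printed Wald CI is symmetric on
the log scale; `seFromCi()` warns when
$|\ln(\mathrm{or}^2/(\mathrm{lo}\cdot\mathrm{hi}))| > 0.02$, the largest
discrepancy explainable by two-decimal rounding, because the recovered SE
is then only approximate.

`fixedEffectsMeta()` pools with inverse-variance weights $w_i = 1/s_i^2$:

$$\hat\beta = \frac{\sum w_i \beta_i}{\sum w_i}, \qquad
  \widehat{se} = \Big(\sum w_i\Big)^{-1/2},$$

with a two-sided normal P, Cochran's
$Q = \sum w_i(\beta_i - \hat\beta)^2$ on $k-1$ df, and
$I^2 = \max\!\big(0, (Q - (k-1))/Q\big)\times 100$, floored at zero so a
homogeneous pair of studies reports $I^2 = 0$ rather than a negative
value.  `heterogeneityFilter()` drops records with $I^2$ above 50% by
default, the conventional screen.  Random-effects pooling and
sample-size-weighted combination are deliberately out of scope.

Because printed ORs carry two decimals, re-combining the per-study cells
reproduces a printed combined OR only to about $\pm 0.01$; the fixture
tests use exactly that tolerance.  One packaged row (rs17694555) has a
replication CI narrower than its combined CI — internally impossible under
inverse-variance weighting, so almost certainly a transcription artefact in
the source table; its combined OR still reproduces.

Genomic control uses $\lambda_{GC} = \mathrm{median}(\chi^2)/0.45494$,
where the denominator is the null median of the 1-df chi-square.

## QC and association testing

`applyQc()` applies, in fixed order: imputation-info pass-through (only
when an `info` column is present; threshold 0.3), sample call rate (missing
fraction $\le$ 0.02), sample inbreeding $|F| \le 0.05$ with
$F = 1 - \mathrm{het}_{obs}/\mathrm{het}_{exp}$ over the variants in hand,
SNP missingness ($\le$ 0.05), MAF ($\ge$ 0.01), Hardy-Weinberg equilibrium
($P \ge 10^{-4}$, 1-df chi-square on hard-called genotypes of all analysed
samples, computed pre-analysis as QC pipelines do), and case/control
differential missingness ($P \ge 0.05$).  Exclusions are attributed to the
first rule that triggers.  Two caveats worth knowing: the chi-square HWE
test (not the exact test) is used, matching common pre-imputation QC; and
the per-sample inbreeding coefficient is only meaningful when computed over
many variants — on toy matrices of a handful of SNPs the default $|F|$
threshold would reject most samples on noise, so small-panel callers should
relax it.

`logisticAssoc()` fits the additive allele-dosage logistic model by IRLS
(tolerance $10^{-8}$, 25 iterations) and reports the Wald beta/SE/OR/CI and
two-sided P on the dose term; conditioning SNPs enter as covariates, which
is how conditional independence of two signals at one locus is tested.  A
Rao score test at the null fit is available behind `method = "score"`; the
Wald default is what produces the OR/CI records summary tables print, and
the two agree asymptotically.  Non-convergence and quasi-complete
separation are reported as P = NA rather than an error, mirroring how
association software flags unfittable models.  One-sided P values follow
the halving convention: half the two-sided P when the estimate matches the
prespecified direction, else one minus that half.  (Whether the original
replication analyses halved two-sided P values or used signed score tests
is not documented; the halving convention is implemented and stated, not
asserted as theirs.)

`allelicPower()` gives the normal-approximation power of the allelic 2x2
comparison, with `maf` interpreted as the *control* allele frequency and
the case frequency derived through the odds ratio; the variance is
evaluated at the expected allele counts under the alternative.  At OR = 1
the one-sided power equals the nominal level exactly.

## Trans-ethnic fine-mapping and the resampling null

`ldR2()` computes $D = p_{AB} - p_A p_B$,
$r^2 = D^2/(p_A q_A p_B q_B)$ and $D' = D/D_{\max}$ from phased haplotype
counts; `selectTagged()` returns the index SNP plus all variants with
$r^2$ strictly above 0.6 (the conventional bound defining a tagged locus).

The centrepiece is `constrainedResampleSim()`.  The scientific question:
if a candidate causal SNP is significant in an admixed sample but its
European tag SNP is not, is that *inconsistent*, or just what the admixed
LD structure predicts?  The null is built by resampling: each replicate
reassembles the case-control sample so that every individual's two
haplotypes are drawn from a reference panel conditional on the causal-SNP
alleles implied by that individual's assigned causal genotype.  The causal
genotype counts therefore match the input *exactly in every replicate* —
this is asserted, not merely expected — while the tag SNP's alleles ride
along on the sampled haplotypes.  Each replicate's tag association is
tested by the chi-square test of homogeneity on the allele-count 2x2 table
(a genotype-table 2x3 variant is available; which table the original
analysis used is not documented, so the allele table is the default), and
the report gives the fraction of replicates whose tag P is strictly
greater than the observed one; ties count as not-less-significant.

Sampling is with replacement within each causal-allele stratum.  Strict
without-replacement sampling is arithmetically impossible whenever the
design needs more haplotypes than the panel holds (a 203/1,363 design
needs 3,132 haplotypes; an admixed reference panel may hold a few
hundred), while conditional with-replacement sampling preserves the
constraint that defines the null — the exact causal genotype counts.  A
`withoutReplacement` flag (hypergeometric draws) exists for designs small
enough to fit.  A replicate in which a tag allele-count margin is zero
carries no evidence against homogeneity and is assigned P = 1.

`prioritizeCrossAncestry()` implements the validation filter: a variant
survives if its one-sided P is below $\alpha$ (default 0.05) in every
population, with risk-allele concordance required by default.  Published
locus tables often omit allele columns, so when no `risk_allele` column is
present the check falls back to odds-ratio direction concordance.

## Genotype-dependent coexpression

The mechanism test asks whether the correlation between a TF's and a
target gene's expression differs by genotype class at a regulatory SNP.
Because homozygous-risk carriers are rare, dosages collapse to carrier
status: class 1 iff dose $\ge$ 0.5 (`genotypeClass()`), the imputed-dosage
convention at the hard-call boundary.

`coexprLrt()` standardizes both expression vectors (mean 0, variance 1 —
enforced internally) and compares nested OLS models:

* reduced: target ~ tf + class
* full: target ~ tf + class + tf:class

Standardization makes the interaction coefficient interpretable as the
difference in correlation between classes, and indeed
$\hat\delta \approx r_1 - r_0$ to $O(1/n)$ (a tested invariant).  The
statistic is the Gaussian likelihood-ratio form
$n\ln(RSS_{reduced}/RSS_{full})$ on 1 df; an exact F variant sits behind
`fTest = TRUE`.  The one-sided convention needed a decision, since
"one-sided" is usually stated without defining the side: *attenuation*
means the interaction pulls the risk-class slope toward zero, i.e. the
interaction sign is opposite to the class-0 slope; in that case the
one-sided P is half the two-sided P.  Per-class correlations are reported
as Pearson (matching the regression parameterization); Spearman is
available through `correlationTest()`, which uses average ranks for ties
and the same $t = r\sqrt{(n-2)/(1-r^2)}$ approximation, plus an optional
percentile bootstrap.  Published Spearman correlations sometimes travel
with P values that the $t$ approximation cannot reproduce (a printed
r = 0.22 at n = 358 implies P near $3\times10^{-5}$, not
$4.3\times10^{-9}$); no attempt is made to match such values.

Per-population interaction estimates pool by inverse variance
(`correlationDifferenceMeta()`, delegating to the meta module on the raw
correlation-difference scale).  `additiveExpressionAssoc()` covers the
cis-eQTL and exon-usage stages: OLS of (optionally log2) expression on
dose plus covariates with a t test on the dose term.
`expressionPresenceFilter()` applies the strict presence screen
(value > 0.01 in > 75% of samples by default) before TF loops.

## Motif and splice-element scoring

A PWM is stored as per-position base probabilities with a background and
the pseudocount used during count conversion.  JASPAR count matrices
convert with an additive pseudocount of 0.25 per cell (configurable); a
TRANSFAC-dialect reader is included.  LOD scores are
$\sum_j \log_2\!\big(p_j(b_j)/bg(b_j)\big)$ with a uniform background by
default; the log base is configurable because the conventions of annotation
services differ, and every comparison the package makes (allele deltas,
rankings) is base-invariant.  `alleleDisruption()` substitutes each allele
into a window, takes each allele's best LOD over offsets and strands, and
reports $\Delta = \mathrm{best}_{alt} - \mathrm{best}_{ref}$; a negative
$\Delta$ is the signature of a binding-site-disrupting allele.  The
function is antisymmetric in ref/alt by construction and by test.
`spliceHexamerScan()` resolves a one-slot `[X/Y]` template per allele and
reports every exact, possibly overlapping motif occurrence — the pattern
of interest being two overlapping splice-enhancer hexamers each completed
by a different allele.

## The synthetic-data generators

The generators define the study conditions under which everything above is
tested:

* `simHaplotypePanel()` solves the two-locus haplotype frequencies for
  given marginals and target $r^2$
  ($D = \pm\sqrt{r^2 p_A q_A p_B q_B}$, positive coupling by default since
  risk alleles at a tagged locus co-occur) and draws multinomially.
  Infeasible targets fail with the attainable maximum in the message.
* `simCaseControl()` is retrospective rejection sampling from
  $\mathrm{logit}\,P(\mathrm{case}) = \alpha + \ln(\mathrm{OR})\cdot
  \mathrm{dose}$, with $\alpha$ set for a baseline (dose-0) prevalence of
  0.10 — a retrospective design never states its prevalence, so a round
  default is used and is configurable.
* `simExpression()` draws, within each genotype class, bivariate normal
  pairs with the requested correlation and unit variances.
* `simNullChisq()` draws i.i.d. 1-df chi-squares for genomic-control
  calibration.

All generators are bit-reproducible given a seed and restore the caller's
RNG state.  What they emulate — and what they do not: panels carry exactly
the two focal variants (no background haplotype structure, no coalescent
realism), expression pairs are Gaussian with equal class variances (no
heavy tails, no shared technical covariates), and case-control sampling
assumes a homogeneous population (no stratification).  Tests passing under
these conditions therefore demonstrate correctness of the statistics, not
robustness to the messiness of real cohort data.

## Numerical choices and problem sizes

Degenerate inputs are classed errors (`tagfun_*_error` conditions), except
where a degenerate value is itself informative: monomorphic HWE input
returns P = 1 with a flag; a perfect correlation reports P below 1e-15
with a perfect-fit flag; an unfittable logistic model reports P = NA.  The
LRT is floored at zero against roundoff; $I^2$ is floored at zero; P
values are floored at 1e-300.

The calibration checks in the test-suite and acceptance script use problem
sizes chosen to make the asymptotics they rely on tight while staying
desk-sized: 2,000 null likelihood-ratio simulations at 500 samples per
class for the type-I rate; 1,000 recovery simulations at the 300/58 class
design for interval coverage of a $-0.09$ correlation difference; 10,000
null chi-squares for $\lambda_{GC}$; 2,000 phenotype permutations of a
1,000-sample set for P-uniformity, run on fractional (imputed-style)
dosages because hard-called doses make the permutation distribution
discrete and a Kolmogorov–Smirnov test against the *continuous* uniform
would reject on discreteness alone; and 50,000 replicates for the
resampling-sampler oracle comparison on a 20-haplotype panel.

A known limitation of the resampling null follows from its own constraint:
because the causal genotype counts are held fixed, replicate-to-replicate
variation in the tag statistic has standard deviation roughly
$\sqrt{1-r^2}$ rather than 1, so the fraction of replicates less
significant than an observed value depends sharply on the panel's
tag/causal frequency asymmetry and the strength of the causal signal.
Reported fractions are therefore only comparable between identical designs.

## Worked example

```{r example}
# combine two studies given as printed OR (95% CI) cells
t1 <- loadTable1()
r <- t1[t1$snp_id == "rs77728904", ]
metaFromCi(or = c(r$disc_or, r$rep_or),
           ciLo = c(r$disc_lo, r$rep_lo),
           ciHi = c(r$disc_hi, r$rep_hi))

# cross-ancestry prioritization of the packaged locus table
t2 <- loadTable2()
prioritizeCrossAncestry(list(
  HA = data.frame(snp_id = t2$snp_id, p_one_sided = t2$ha_p, or = t2$ha_or),
  AA = data.frame(snp_id = t2$snp_id, p_one_sided = t2$aa_p, or = t2$aa_or)))

# is a non-significant tag consistent with the LD structure?
panel <- simHaplotypePanel(0.12, 0.15, r2Target = 0.58, nHap = 244, seed = 9)
constrainedResampleSim(panel, "snpA", "snpB",
                       caseGenotypeCounts = c(138, 59, 6),
                       controlGenotypeCounts = c(1056, 288, 19),
                       observedTagP = 0.403, b = 1000, seed = 10)

# genotype-dependent coexpression at the published class design
cls <- rep(c(0, 1), c(300, 58))
xy <- simExpression(cls, rClass0 = 0.24, rClass1 = 0.15, seed = 11)
coexprLrt(xy$target, xy$tf, cls)
```
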
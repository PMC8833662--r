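---
title: "Two-trait heat-stress genetic evaluation and weighted single-step GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-trait heat-stress genetic evaluation and weighted single-step GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoGBLUP)
```

## The problem and the model

Pigs cannot sweat; sustained heat depresses feed intake and growth, and hot
carcass weight (HCW) recorded at slaughter reflects that. Whether the genetics
of HCW *under* heat stress differs from the genetics of HCW under
thermo-neutral conditions is a genotype-by-environment question with direct
consequences for selection: a genetic correlation well below one between the
two environments means the best boar in a cool season is not the best boar in
a hot one.

`thermoGBLUP` implements the two-trait analysis of this question end to end.
The heat load of a record is the temperature-humidity index

$$\mathrm{THI} = (1.8\,t + 32) - (0.55 - 0.0055\,rh)\,(1.8\,t - 26),$$

computed from each day's maximum temperature $t$ (deg C) and minimum relative
humidity $rh$ (0-100), averaged over the 30 calendar days preceding the
slaughter date. A mean THI strictly above 78 assigns the record to the
heat-stress trait (HS); otherwise it is the non-heat-stress trait (NHS). A
THI of 78 spans roughly 25.5 deg C at saturated humidity to 40 deg C in dry
air, which is where finishing pigs start to suffer.

Each animal is slaughtered once, so it has a record on exactly one of the two
traits. The record model per trait is

$$y_{ijkl} = CG_i + sex_j + litter_k + b\,\mathrm{age} + animal_l + e_{ijkl},$$

with contemporary group (year-week-farm of slaughter), sex and an age
covariate as fixed effects, and litter (dam x parity), animal and residual as
random effects. In the two-trait form the additive-genetic effects carry the
full 2x2 covariance structure $A \otimes G_0$ across traits, while litter and
residual cross-trait covariances are structurally zero — the traits are never
observed on the same animal, so those covariances are not identifiable and
are not part of the model.

Narrow-sense heritability per trait is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_l + \sigma^2_e)$ and the genetic
correlation is $r_g = \sigma_{a,\mathrm{HS,NHS}} /
\sqrt{\sigma^2_{a,\mathrm{HS}}\,\sigma^2_{a,\mathrm{NHS}}}$.

## Relationship structures

* `makeA()` builds the numerator relationship matrix by the tabular
  recursion; `makeAInverse()` applies Henderson's rules with inbreeding from
  the tabular diagonal (exact at the package's desk scale).
* `makeG()` builds the genomic matrix $G = MDM'/(2\sum p_nq_n)$ from dosages
  centered at twice the allele frequency, with a positive SNP-weight diagonal
  $D$. Frequencies default to those observed in the genotyped set; base-
  population frequencies are not available for the data this package
  emulates. Because centering at observed frequencies leaves the all-ones
  vector in the null space of $G$, the default blends
  $G^* = 0.95\,G + 0.05\,A_{22}$; `alpha = 1` returns the raw definition for
  algebraic tests. No further tuning of $G$ to $A_{22}$ means or scales is
  applied.
* `makeHInverse()` assembles the single-step inverse
  $H^{-1} = A^{-1} + \begin{pmatrix}0&0\\0&G^{-1}-A_{22}^{-1}\end{pmatrix}$
  on the genotyped block, pedigree order preserved.

## AIREML

`aireml()` maximizes the restricted likelihood of the (two-)trait model on
the phenotypic-covariance parameterization $V(\theta)=\sum_k \theta_k V_k$,
which is exact and convenient at desk scale (a few thousand records): the
average-information matrix is $\mathrm{AI}_{kl} = \tfrac12\, y'PV_kPV_lPy$
and the score is $-\tfrac12(\mathrm{tr}(PV_k) - y'PV_kPy)$, both cheap once
$P$ is formed densely. This uses the relationship matrix itself rather than
its inverse; at this scale either is available. Design choices:

* **Guarded AI updates.** A proposed AI step is halved until the parameters
  are admissible (variances above `1e-8` of the phenotypic scale, genetic
  correlation inside (-1, 1)) and the restricted log-likelihood does not
  decrease. Accepted iterations are therefore monotone. We chose backtracking
  over an explicit EM fallback because, in this linear parameterization, a
  damped AI step is the standard safeguard with the same guarantee and less
  machinery; the monotone-likelihood property is what the tests assert.
* **Starting values.** Per-trait phenotypic variance split 0.3/0.1/0.6 into
  animal/litter/residual, genetic correlation started at 0.5.
* **Convergence.** Relative parameter change below `1e-8` or gradient below
  `1e-6`, with a 200-iteration cap; typical fits converge in about ten
  iterations.
* **Boundary behaviour.** When a true variance is near zero the estimate
  pins at the lower bound; the reported correlation is clamped to [-1, 1].
  These boundary fits are genuine REML optima on such data sets, not solver
  failures, and they shape the sampling distribution of $\hat r_g$ at small
  scale (see below).

## Weighted single-step GWAS

SNP effects are backsolved from the GEBVs of the genotyped animals,
$\hat u = DM'(MDM')^{-1}\hat a$. With blending ($\alpha<1$) the blended
$G^*(2\sum pq)$ replaces the bracket — a deviation forced by the
invertibility of the observed-frequency $G$, documented here. Weights are
then iterated: iteration 1 is always $D=I$; **quadratic** weighting sets
$d_s = \hat u_s^2$ (no allele-frequency factor), **nonlinear "A"** sets
$d_s = [\sigma^2_a/(2\sum pq)]\,CT^{\min(|\hat u_s|/\mathrm{sd}(\hat u)-2,\,5)}$.
The nonlinear constant defaults to $CT = 1.125$ (the conventional
departure-from-normality value; 1.25 also appears in print for this method,
so the constant is an argument and both values are exercised in tests).
After every update the weights are floored at `1e-8` and rescaled so
$\mathrm{tr}(D)$ equals the number of SNPs, conserving the total genetic
variance.

The scan statistic sums the per-SNP variances
$\hat\sigma^2_{u,s} = \hat u_s^2\, 2p_s(1-p_s)$ over 20-SNP moving windows
(advancing one SNP, never spanning chromosomes) and expresses each window as
a percent of the total summed over all SNPs, so the per-SNP fractions add to
100%. Expressing windows as percent-of-total rather than as a window average
gives identical peak ranking at fixed window size and makes the 0.8%
reporting threshold internally consistent. The thermotolerance scan is the
absolute difference $|pct_{HS} - pct_{NHS}|$ between the single-trait
profiles on a shared window frame; `peakReport()` merges overlapping
supra-threshold windows into peaks. `chromosomeSegments()` implements
$q = 2N_eL/\log(2N_eL)$ with the natural logarithm; for $N_e = 55$ and
$L = 19$ Morgans this gives 273.4. (The figure of 577 segments quoted in the
literature for these same inputs does not follow from this formula under
either natural or base-10 logarithms; the function implements the formula as
printed and we note the discrepancy rather than reproduce the number.)

## Validation design

`splitByDate()` produces reduced (records up to a cutoff; "after" is strict)
and complete sets; `selectValidationSires()` keeps sires with at least 200
progeny with records in the complete data and none in the reduced data; and
`validationAccuracy()` reports the Pearson correlation between reduced-data
EBVs and the complete-data two-trait unweighted single-step GEBVs (the
benchmark) for all four trait pairings — same-trait pairings are
homo-correlations, crossed ones hetero-correlations. Accuracy is the plain
correlation of this partial/whole comparison, not divided by $\sqrt{h^2}$,
and sire GEBVs are taken directly from the solution vector without
deregression.

## The synthetic-data generator

Real carcass-weight, pedigree and genotype data of this kind are commercially
sensitive and unavailable, so every pipeline stage is exercised on synthetic
data whose **defaults encode the published population structure, scaled to
desk size**: a ~3,000-animal three-generation pedigree on two farms (62%/38%
of records), about 14.4% of records heat-stressed with the hotter farm at
20.8% and the cooler at 4.0%, slaughter age 185 +/- 8 d, baseline NHS mean
94.2 kg with a -4.3 kg shift under heat stress, and simulation truths of
84.697/60.173 kg^2 genetic, 31.736/30.791 litter and 216.69/210.69 residual
variance with genetic covariance $0.63\sqrt{84.697 \times 60.173}$ (the
correlation is published; the covariance is not, so it is derived).

Choices the source material leaves open, fixed once here:

* The three-breed terminal cross is collapsed to a sire pool and a dam pool;
  breed means are absorbed by contemporary groups, which is consistent with a
  record model that carries no breed term.
* Litters farrow in batches (default 20 per generation-year) spread over the
  year, each sire serving about two litters within a batch and several
  batches; dams cycle through parities 1-3. Batch farrowing is how commercial
  flow works and is what fills contemporary groups and creates cross-litter
  half-sib structure.
* Weather is a sinusoidal seasonal maximum temperature (peak mid-July) with
  daily noise and near-constant minimum humidity; per-farm annual means are
  calibrated analytically so the 30-day mean THI exceeds 78 for the farm's
  target fraction of the year. An age regression of 0.5 kg/d, a 1.5 kg sex
  effect and contemporary-group effects with 4 kg SD set the fixed-effect
  scale; none of these influence variance-component recovery, which depends
  on the random structure.
* In QTL mode (`nQtl > 0`) marker effects decay geometrically with
  cross-trait correlation implied by the genetic covariance and are rescaled
  to carry `qtlVarFrac` of the genetic variance; this is a test fixture for
  peak detection, not a claim about the trait's architecture, which the
  source material describes only as polygenic.
* Slaughter dates are birth + N(185, 8^2) days, with litter birth weeks
  spread uniformly so records cover all seasons; the distribution of
  slaughter dates across weeks is otherwise unspecified upstream and is
  exposed as configuration.

What the generator does **not** emulate: linkage (loci are unlinked, so LD
patterns and realistic QTL mapping resolution are absent), selection across
generations, maternal genetic effects, breed composition, and real weather
autocorrelation. Passing tests therefore demonstrate the correctness of the
algorithms under the stated statistical model, not robustness to the
violations real data would add.

## The parameter-recovery experiment

The acceptance analysis refits the two-trait model by AIREML on data
simulated at the published variance-component truths and averages
$\hat r_g$ and $\hat h^2_{HS}$ over 16 seeds (about 4,200 records per seed
on a three-generation pedigree of roughly 4,800 animals; ten to fifteen
minutes of compute on one CPU).

Scale matters here, in two ways. First, at the published imbalance (14.4%
heat-stressed, concentrated on one farm) a desk-scale replicate carries only
a few hundred HS records, and the asymptotic standard error of
$\hat\sigma^2_{a,HS}$ evaluated at the truth is ~80% of the truth itself:
the heat-stress components are essentially unidentified at 1/100 of the
original data volume, and no estimator could recover them. The recovery
experiment therefore validates the **estimator** on an informative design
with the same model and the same truths: the two traits are balanced within
each farm (the split is still driven by weather through the same THI rule)
and dams are rebred to the same sire across parities, creating cross-litter
full-sib pairs — the cleanest source of cross-trait genetic covariance
information because litter effects do not contaminate cross-litter pairs.
These choices take the per-seed sampling SD of $\hat r_g$ from ~0.5 (full
imbalance) to ~0.2 (balanced, repeat mating).

Second, constrained REML correlation estimates are biased toward the +/-1
boundary at modest information: replicates that pin $\hat\sigma^2_{a,HS}$
near zero rail $\hat r_g$ at 1, and these are true REML optima of those
data sets, averaged rather than discarded. With heat-stress records
concentrated on one farm this boundary pile-up inflates the mean of
$\hat r_g$ by roughly +0.04-0.08 at desk scale; spreading the heat-stress
share evenly over both farms and enlarging the replicate to ~4,200 records
makes rails rare (characterized over independent seed batches: mean
$\hat r_g \approx 0.64$, SD $\approx 0.15$, mean
$\hat h^2_{HS} \approx 0.24$). The experiment design was chosen so that the
mean over seeds estimates the truth rather than the boundary artifact. The
default generator keeps the published imbalance; `recoveryConfig()`-style
overrides are used only where the quantity under test is the estimator, not
the data structure.

## Numerical conventions and edge cases

* The 30-day heat-load window is the 30 calendar days immediately preceding,
  and excluding, the slaughter date; any missing day is an error listing the
  dates. One THI per day, from that day's maximum temperature and minimum
  humidity.
* A mean THI exactly at the threshold is NHS (the definition is strictly
  "above").
* Genotype QC order is fixed for reproducibility: animal call rate, then SNP
  call rate, then MAF/monomorphic on the survivors (thresholds 0.9, 0.9,
  0.05); remaining missing dosages are imputed to twice the allele
  frequency. The 4-SD record cut is two-sided and per trait by default
  (`perTrait = FALSE` pools), since the upstream definition is one-sided in
  wording but silent on the distribution side and per-trait means.
* Fixed-effect identifiability: the first level of each fixed factor is
  dropped; the age covariate is centered; aliased columns are removed by QR
  in the REML design.
* The mixed-model solver is a direct sparse factorization; its contract is
  the relative residual below `1e-8`, not the factorization method.
* `A22` is obtained by subsetting the tabular `A`; the contract is the
  submatrix, so a recursion-based method could replace the construction at
  larger scale. APY-style approximations are out of scope.

## Limitations

Everything here is desk-scale: dense `A` and dense REML are deliberate
simplifications that are exact but would not survive a 553k-animal pedigree;
the sparse MME path scales further but the REML path would need a
sparse-inverse (Takahashi) implementation. The generator's independence
assumptions (no linkage, no selection) mean GWAS power and LD-decay behaviour
are not representative of real chips. Reported standard errors come from the
inverse AI matrix and carry the usual asymptotic caveats, and there is no
published benchmark for them.
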
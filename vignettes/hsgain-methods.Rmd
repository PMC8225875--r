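---
title: "Methods: modelling genetic gain in half-sib family breeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling genetic gain in half-sib family breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsgain)
```

## The problem

Outcrossing forage species such as perennial ryegrass are bred by recurrent
selection on half-sib (HS) families: maternal parents are polycrossed, their
HS progenies evaluated as plots in multi-location, multi-season, multi-year
trials, and the best material intermated to start the next cycle. Classical
among-family phenotypic selection exploits only the among-family quarter of
the additive variance; the remaining three quarters segregate *within*
families, where plot-based phenotyping cannot see them. Genomic selection
(GS) makes within-family selection possible (genotype seedlings, rank their
genomic estimated breeding values, GEBVs), and phenomics (e.g. a
LiDAR-based yield proxy) makes among-family phenotyping drastically
cheaper at a modest accuracy penalty. `hsgain` quantifies what these
technologies buy: per-cycle genetic gain, cost per percentage point of
gain, and the multi-cycle dynamics of variance, allele fixation and
prediction accuracy.

## Deterministic model

### Variance components and heritability

The engine's starting points are REML variance components of the HS trial
mixed model

$$y = \mu + L + S + Y + f + fL + fS + fY + b + r + c + \varepsilon,$$

with fixed location/season/year main effects, random family ($\sigma^2_f$),
family-by-location/season/year interactions, optional replicate/row/column
blocking, and a plot residual. With inbreeding coefficient $F = 0$, the
among-HS-family component estimates $\tfrac14\sigma^2_A$ of the additive
variance. The phenotypic SD among family means under an
$n_l \times n_s \times n_y \times n_r$ design is

$$\sigma_{PF} = \sqrt{\sigma^2_f + \sigma^2_{fl}/n_l + \sigma^2_{fs}/n_s +
  \sigma^2_{fy}/n_y + \sigma^2_\varepsilon/(n_l n_s n_y n_r)},$$

and the family-mean narrow-sense heritability is
$h^2_n = \sigma^2_f / \sigma_{PF}^2$. Note the residual divisor includes
$n_l$ — the residual is averaged over every plot of a family, i.e. over
all $n_l n_s n_y n_r$ replicates; this is the form consistent with the
heritabilities the component magnitudes imply.

### Response equations

For one cycle of truncation selection with selected fraction $p$, the
selection intensity is the infinite-population truncated-normal mean
$i(p) = \phi(\Phi^{-1}(1-p))/p$; no finite-sample order-statistic
correction is applied (at the family numbers involved, $\geq 200$, the
correction is below the reporting precision). Parental control is
$c = 0.5$ for selection acting through female gametes only. The five
strategies are:

* **A_p** — among-family phenotypic selection:
  $\Delta G = i(p_f)\, c\, \sigma^2_f / \sigma_{PF}$.
* **A_Ph** — as A_p on phenomics-derived yield; the total prediction is
  multiplied by the phenomics accuracy (default 0.90).
* **A_pWgs** — A_p plus within-family GS, a correlated response through
  the GEBV:
  $i(p_w)\, c_w\, h_X\, r_A\, \tfrac{\sqrt3}{2}\, \sigma_A$, with
  $\sigma_A = 2\sqrt{\sigma^2_f}$ and $\sqrt{3}/2$ the within-family share
  of the additive SD. $h_X$, the square root of the selection-trait
  heritability, is 1 for GEBVs; $r_A$ is the prediction accuracy.
* **A_PhWgs** — as A_pWgs with the *whole* sum scaled by the phenomics
  accuracy (the phenomics-trained prediction model carries the accuracy
  penalty into the within-family term as well).
* **A_gsWgs** — both stages genomic, no field trial, one-year cycle:
  $i(p_f) c_f h_X r_A \tfrac12 \sigma_A + i(p_w) c_w h_X r_A
  \tfrac{\sqrt3}{2} \sigma_A$.

Percent gain is expressed against the *current* cycle's base mean; when
cycles are chained (`chain_cycles()`), each cycle's base mean is the
previous mean plus the previous absolute gain, per-cycle percentages are
summed, and annual gain divides by the cycle length (3 years for
field-trial cycles, 1 for all-genomic ones). Parent counts round half-up,
and a pressure that rounds to zero selected units is an error rather than
a silent floor.

### Scale convention

The component tabulated as the among-family variance is used *directly* as
the numerator of the among-family response and as $(\sigma_A/2)^2$ for the
within-family terms. This convention — rather than multiplying by 4 first
and dividing again — is the one under which the engine's predictions
reproduce the published worked examples from the printed components to
reporting precision, and it is applied consistently everywhere.

## Cost model

Cycle cost = fixed operational cost + one sample per plot
($n_f n_r n_l n_s n_y$ samples at \$7.50 cut / \$0.87 phenomics) +
\$41 per GEBV for genotyped candidates. The fixed operational cost depends
on program line items that are not part of this package's inputs, so it is
a required configuration value; the package asserts cost *patterns* (e.g.
phenomics is cheaper per percent gain at every pressure across a
\$80k–110k fixed-cost band) rather than absolute dollar figures.

## REML implementation

`fit_trial_reml()` delegates to `lme4::lmer` (REML, bobyqa with tight
tolerances `rhoend = 1e-10`), which bounds variance components at zero and
handles unbalanced data. Nesting is encoded by compound keys: replicate
within (location, season, year), and rows/columns within replicate — a
column-within-row effect would have one level per plot and is confounded
with the residual, so columns enter at the replicate level. On balanced
complete data REML coincides with the closed-form ANOVA
expected-mean-squares estimators for interior solutions;
`anova_components()` implements that oracle and the test suite verifies
agreement to about $10^{-6}$ relative (with the optional `polish`
refinement — a Nelder-Mead pass on the REML deviance plus a tight local
restart; the default fit stops near $10^{-5}$, orders of magnitude below
the statistical uncertainty). Permuting record order moves estimates by
about the optimizer tolerance, which is why the permutation-invariance
test asserts $10^{-6}$ rather than machine epsilon. Convergence is
flagged on the fit;
`as_variance_components()` refuses unconverged fits.

## Stochastic simulator

### Genome and founders

The default genome emulates a forage-grass setup: 1807 biallelic markers on
7 linkage groups, 474 of them additive QTLs. Linkage-group lengths are not
part of the tabulated setup; the package uses 100 cM per group (a
ryegrass-scale ~700 cM map) as its own default. QTL effects are drawn
standard normal — in a real program they would come from GWAS on the actual
founders, which is out of scope here — and can be rescaled so the cycle-0
additive variance $\sum 2p(1-p)a^2$ hits a target. Synthetic founders are
drawn in linkage equilibrium and Hardy–Weinberg proportions with allele
frequencies Uniform(0.1, 0.9).

Meiosis uses the Haldane model (no interference): crossover counts per
chromosome are Poisson(map length/100) with uniform positions, chromosomes
assort independently. For marker loci this is equivalent to a Markov chain
with per-interval recombination $(1 - e^{-2d/100})/2$; the implementation
(compiled, `src/meiosis.cpp`) draws the Poisson process and copies
contiguous segments, which is exact and fast. Polycross mating gives every
progeny a maternal gamete from its mother and a paternal gamete from a
uniform draw of the pollen pool excluding the mother (no selfing, no
mutation, no dominance/epistasis).

### Trait and trial

Plant phenotype = base mean + TBV + family-by-environment deviation +
residual. The single-plant residual is calibrated so the single-plant
heritability matches the value implied by the family-mean heritability
input: for HS families on $K$ plants total,
$h^2_{fam} = \tfrac14 V_A / (\tfrac14 V_A + (\tfrac34 V_A + V_E)/K)$,
solved for $V_E/V_A$ (`h2_single_from_family()`). The family-mean
heritability default is 0.31, the 200-family REML estimate. The
family-by-environment variance defaults to 0 and is exposed as
configuration — the original simulation systems' GE settings are not
specified, so GE is deliberately a user dial rather than a guessed
constant. Families are evaluated in 2 environments x 2 years x 3
replicate plots of 30 plants; a plot value is the mean over 30 plants
drawn from the family's candidates.

### Breeding loop

The training population (98 polycrossed founders, 2 or 10 draws per family
giving 196 or 980 plants) is evaluated in a 3-environment x 3-year trial
of its own HS families, and an rrBLUP model is trained once on member
dosages against family means. rrBLUP solves
$(Z'Z + \lambda I)u = Z'(y - \bar y)$ with $\lambda$ estimated by REML via
the eigendecomposition of $ZZ'$. GEBVs carry a genotyping-error model:
noise added so the squared correlation with the clean score is 0.95
(implemented as additive noise rather than genotype-call errors because the
calibration is then exact and testable).

Each cycle the current parents are polycrossed into one HS family per
parent with 180 genotyped candidates each (so selecting 5 or 50 within a
family is a 2.77% or 27.8% within-family pressure); families are ranked on
shrunken phenotypic means (`A_p`, `A_pWgs`) or family-mean GEBVs
(`A_gsWgs`); within selected families parents are drawn at random (`A_p`)
or by GEBV rank (`Wgs`); and the selected ~196 individuals found the next
cycle. Family-mean shrinkage uses one-way method-of-moments reliability —
the published analysis says only that gains were BLUP-mean based, so the
package uses the standard shrunken mean as its design choice. The
prediction model is *not* retrained across cycles by default (retraining
is a flag): accuracy then decays as recombination erodes relatedness to
the training set, which is the phenomenon of interest.

Trackers per cycle: genetic mean (base + mean TBV — an all-genomic cycle
has no field trial, so the genetic mean is the quantity defined in every
cycle for every strategy), percent gain per year with the previous-cycle
mean as denominator (the baseline-denominator alternative is computable
from the records), cumulative gain vs cycle 0, percent of cycle-0 genetic
variance, percent of QTLs fixed for the favourable allele, and prediction
accuracy (Pearson correlation of TBV with GEBV, estimated on a capped
subsample of 2000 candidates — the correlation, not the population, is
what is being estimated). Iterations use seeds derived from one master
seed, so different strategies under the same master seed share founders
and cycle-0 populations and are paired.

## What the synthetic data do and do not show

The mock-trial generator draws every random term of the trial model as
independent normals at the generating variances — exactly the model the
REML fitter assumes. Passing recovery tests therefore validates the
estimation machinery, not the model's adequacy for real field data (no
spatial trend, no outliers, no heteroscedasticity). Likewise the simulator's
founders and QTL effects are synthetic: multi-cycle outputs reproduce the
*structure* of published simulation results (strategy ordering, variance
decay, fixation under pressure, accuracy decay) but not their exact
magnitudes, which depend on unavailable real genotypes and GWAS effects.

## Numerical choices and scales used in the test suite

Deterministic worked examples are checked to ±0.02 percentage points
(heritabilities ±0.005). REML recovery uses 50 synthetic trials per
population size (200 and 1000 families) with mean estimates within 10% of
generating values; the balanced ANOVA oracle is checked to 1e-6 relative.
Stochastic property runs use 50 iterations of 5 cycles at population size
196 with 180 candidates per family — large enough for stable means of the
tracked quantities while keeping a full suite run on one CPU in tens of
minutes. Haldane recombination fractions are checked at 1, 10 and 50 cM
over 10,000 gametes (±0.01) and cycle-0 additive variance against its
linkage-equilibrium closed form (±5%).

## Known limitations

No dominance or epistasis, no mutation, no selfing, no overlapping
generations, no multi-trait indices; no spatial (AR1×AR1) residual models
in REML; the cost model has no discounting or labour breakdown; the
deterministic engine treats prediction accuracy as an input rather than
deriving it from training design.
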
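---
title: "Methods: summary-statistics Mendelian randomization with mediation chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics Mendelian randomization with mediation chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchain)
```

## The inference problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here: socioeconomic risk factors such as household income,
education, smoking, alcohol use, BMI, physical activity) on an outcome
(lung cancer risk) from GWAS summary statistics alone. Each genetic variant
j contributes a pair of estimated per-allele associations: with the exposure
($\hat\beta_{Xj}$, from one GWAS) and with the outcome ($\hat\beta_{Yj}$,
log odds ratios from an independent case-control GWAS). If the variant is a
valid instrument — associated with the exposure, affecting the outcome only
through it, and unconfounded — the Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect
$\theta$ on the outcome's log-odds scale.

`mrchain` implements the full chain this kind of study runs: instrument
selection and strength metrics, five univariable estimators, heterogeneity
and pleiotropy diagnostics with a reported-estimate decision rule,
multivariable MR to separate independent from mediated risk factors, and
mediation (network) MR with the proportion-mediated decomposition. A
synthetic-data generator with known causal structure makes every stage
testable without external downloads.

## Data model and harmonization

A phenotype panel is one row per SNP: identifier, effect and other allele,
effect-allele frequency (EAF), beta, SE, p-value, sample size
(`summary_stats()`, `read_summary_stats()`). Before any estimator runs,
panels are aligned to a common effect allele per SNP (`harmonize()`):
swapped alleles flip the sign of beta and replace EAF by 1 − EAF;
strand-complement pairs are resolved by complementing; palindromic SNPs
(A/T, C/G) cannot be oriented from alleles alone, so they are aligned by
allele frequency when frequencies are informative and dropped when the EAF
falls inside the ambiguity band in any panel. The band defaults to
[0.42, 0.58], the conservative convention in two-sample MR practice; it is
configurable. Records with missing EAF are retained for estimation (EAF
enters only the variance-explained formula) but dropped if palindromic.
Every action is recorded per SNP in an alignment log.

## Instrument selection and strength

Instruments are genome-wide significant records (p < 5e-8, strict) with
minor-allele frequency at least 0.01, thinned to approximate linkage
independence by greedy clumping on a user-supplied r² matrix: repeatedly
take the smallest-p unclaimed SNP as an index and discard unclaimed SNPs
with r² > 0.001 against it (p ties broken lexicographically by SNP id, so
the result is deterministic). Positions and windows are not needed because
the r² matrix already defines which pairs are in LD.

Instrument strength uses the variance explained per SNP,
$R^2_j = 2\beta_j^2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)/\mathrm{SD}^2$
(SD defaults to 1, i.e. a standardized phenotype), summed over the set, and
the F statistic
$F = \frac{N-k-1}{k}\cdot\frac{R^2}{1-R^2}$
for k SNPs in a sample of N. The conventional F > 10 gate is applied to
the aggregate F; per-SNP F values (k = 1) are also reported because the
convention is sometimes applied per variant.

## Univariable estimators

All estimators operate on the harmonized per-SNP pairs with weights
$w_j = 1/\mathrm{se}(\hat\beta_{Yj})^2$.

* **IVW** — weighted regression of outcome on exposure associations through
  the origin; algebraically the inverse-variance weighted mean of Wald
  ratios. The default is the multiplicative random-effects model, which
  inflates the fixed SE by $\max(1, \sqrt{Q/(k-1)})$; it is identical to
  fixed effects under homogeneity and conservative otherwise, which is why
  it is the reported flavour.
* **MR-Egger** — the same regression with a free intercept, exposure
  associations oriented non-negative first. The slope is the causal
  estimate tolerating directional pleiotropy (under the InSIDE assumption);
  the intercept estimates the average pleiotropic effect and its test is
  the pleiotropy gate. SEs use the weighted residual variance floored at 1
  and t inference on k − 2 df.
* **Weighted median** — the 50% point of the inverse-variance-weighted
  ordered Wald ratios, interpolated linearly between adjacent order
  statistics; consistent while valid instruments carry more than half the
  weight. Its SE is a parametric bootstrap (default 1000 replicates,
  seeded and recorded in the output) redrawing both association vectors
  from their sampling distributions.
* **Contamination mixture** — each ratio is modelled as valid,
  $N(\theta, \mathrm{se}_j^2)$, or invalid, $N(0, \mathrm{se}_j^2+\psi^2)$;
  for each candidate $\theta$ on a grid every SNP takes the likelier
  component and the summed log-likelihood is profiled. $\psi$ defaults to
  1.5 times the SD of the ratio estimates (the cited method's practical
  guidance) and the grid to 1000 points spanning the ratio range widened by
  3 SDs. The 95% confidence set collects grid points within
  $\chi^2_{1,0.95}/2 \approx 1.92$ log-likelihood units of the maximum; a
  maximum on the grid boundary raises an error asking for a wider grid.

P-values are normal-approximation two-sided except Egger's t. Binary
outcomes are reported both on the log-odds scale and as exponentiated odds
ratios with 95% CIs.

## Diagnostics and the reported-estimate rule

Cochran's Q, $\sum_j w_j(\hat\beta_{Yj} - \hat\theta_{\mathrm{IVW,fixed}}
\hat\beta_{Xj})^2 \sim \chi^2_{k-1}$, gates heterogeneity; the Egger
intercept test gates directional pleiotropy; both at $\alpha = 0.05$ by
default (the gate level is a convention, configurable). MR-PRESSO compares
the observed leave-one-out weighted residual sum of squares against
parametric simulations under the no-pleiotropy model (global test),
flags per-SNP outliers at the Bonferroni-adjusted level $\alpha/k$ against
each SNP's simulated residual distribution, recomputes IVW without the
outliers, and runs a distortion test against random same-size removals.
Empirical p-values have floor $1/(n_{\mathrm{sim}}+1)$; the default 1000
simulations and a mandatory seed make results reproducible bit for bit.

The decision rule for the reported estimate: no heterogeneity and no
pleiotropy — IVW; heterogeneity without pleiotropy and the weighted median
agreeing in direction with IVW — weighted median; pleiotropy — the
MR-PRESSO outlier-corrected IVW; heterogeneity with discordant directions —
IVW carrying an explicit `"discordant"` flag rather than a suppressed row.

## Multivariable MR and the independence partition

`mr_mvmr()` regresses outcome associations jointly on several exposures'
associations (no intercept, weights $w_j$), over the union of each
exposure's selected instruments restricted to SNPs present in every panel
(complete case). Coefficients are direct effects conditional on the
co-exposures; SEs carry the same multiplicative overdispersion inflation as
univariable IVW, to which the fit reduces exactly at m = 1. A risk factor
that survives the univariable screen is classed *independent* when its
multivariable p-value stays below the gate — by default the same Bonferroni
level as the univariable screen — and *mediated* otherwise.

## Mediation chains and the proportion mediated

For an exposure X, mediators $M_1,\dots,M_K$, and outcome Y, three IVW-based
coefficient sets are estimated (`build_chain()`): $\beta_{1k}$, X on $M_k$
(univariable); $\beta_{2k}$, $M_k$ on Y adjusted for X (multivariable,
mediator coefficient); $\beta_3$, X on Y adjusted for the whole mediator
set (multivariable, exposure coefficient). The proportion mediated is

$$E = 100\% \times \frac{\sum_k \beta_{1k}\beta_{2k}}
{\beta_3 + \sum_k \beta_{1k}\beta_{2k}}.$$

The denominator groups as direct effect plus summed indirect effect — the
only reading under which single-mediator percentages are consistent with
their single adjusted effects; the printed form of this equation is
typographically ambiguous in places, so the grouping is stated here
explicitly. The SE uses the first-order delta method with a diagonal
covariance (mediators treated as uncorrelated), with analytic gradient
components $\beta_{2k}\beta_3/T^2$, $\beta_{1k}\beta_3/T^2$ and $-I/T^2$
(up to the factor 100), where $I$ is the indirect and $T$ the total effect.
A Monte-Carlo propagation mode cross-checks the gradient; on the test
fixtures the two agree within 5%. Proportions below 0% or above 100% and
intervals extending outside [0, 100]% are reported as-is, never truncated
— with a near-null total effect the ratio is genuinely unstable and
truncation would hide that. The joint-mediator E need not equal the sum of
single-mediator Es, and no such identity is enforced. Note that OR
noncollapsibility is outside the generator's scope: outcome effects are
simulated directly on the log-odds scale, so conditional-vs-marginal OR
discrepancies of real case-control data are not emulated.

## The study driver

`run_study()` chains the design end to end per outcome: univariable screen
of every exposure (reported estimate gated at the Bonferroni threshold,
default 0.05/6 = 8.33e-3 applied per outcome with a configurable family
size, since the correction's family definition is ambiguous in such
designs), multivariable MR over the survivors with the independence
partition, and mediation chains for every mediated survivor through each
other survivor singly and through all jointly. Empty stages are skipped
with a logged reason; every reported row is traceable to the decision rule
and method tables, and a fixed seed reproduces all tables bit for bit.

## The synthetic generator

`simulate_panels()` draws, per instrumented trait, a block of instruments
with effects $\gamma_j$ uniform on ±[0.02, 0.1] at EAFs uniform on
[0.05, 0.95]; propagates total effects along the configured directed
edges; and adds independent noise per panel with the sample-size-driven
standard error $1/\sqrt{2N\,\mathrm{EAF}(1-\mathrm{EAF})}$ — no sample
overlap between panels. Defaults emulate the motivating study: biobank-scale
exposure GWAS (N = 4e5), a binary outcome panel of 27,209 subjects
(11,348 cases, 15,861 controls), and instrument counts in the low hundreds.
A configurable fraction of one trait's instruments receives a direct
pleiotropic outcome effect, oriented relative to the exposure-increasing
allele (otherwise a "directional" mean would cancel across arbitrarily
signed instruments); balanced mode draws it symmetric about zero,
directional mode from $N(0.05, 0.025^2)$ by default. Non-reference panels
report a random 30% of SNPs with swapped allele labels so harmonization is
always exercised. Everything is reproducible from (config, seed), and the
truth record keeps every $\gamma_j$, pleiotropic effect and edge weight.

What the generator does *not* emulate: real LD (blocks come from
`simulate_ld_blocks()`, exact block-diagonal r²), winner's curse, sample
overlap, population stratification, and logistic-model noncollapsibility.
Passing tests therefore validate the estimators' statistical behaviour
under their own assumptions, not robustness to those artefacts.

## Operating characteristics, and two honest limitations

The test suite measures, under the default conditions (150 instruments,
planted effect 0.3 on the log-odds scale, outcome N = 27,209):

* IVW, Egger and weighted-median 95% CI coverage of the planted effect
  within [92%, 98%] over 1000 replicates; Cochran's Q type-I error 5% ± 2%
  over 2000 replicates; MR-PRESSO sensitivity above 95% for a planted
  unit ratio shift on a strong instrument; ≥ 90% recovery of a planted
  independent/mediated partition over 100 full pipeline runs; mediation
  proportions within [90, 110]% on a fully mediated diagram with
  delta-method SEs matching Monte-Carlo propagation within 5%.

Two regime effects at this outcome sample size are worth knowing, and the
suite reports them rather than hiding them:

* **Contamination mixture under weak ratios.** With Wald-ratio noise of
  0.1–0.4 (a 27k-subject binary outcome) and a true effect ~2 ratio-SDs
  from zero, instruments whose ratio lands near zero are absorbed by the
  invalid component (which the model centres at zero), clipping the lower
  tail: measured bias +0.028 (≈ 1.7 SE) and 54–62% coverage. The same code
  at ratio SE ≈ 0.03 shows no bias and 94% coverage. Conmix is therefore a
  supplementary estimator here, not a primary one.
* **Weighted median under one-sided contamination.** With 40% of
  instruments carrying directional pleiotropy, the estimate is the ~0.83
  weighted quantile of the valid ratios, i.e. biased upward by about one
  ratio-SD. At this outcome sample size that is ≈ 3.6–3.9 of its own SEs
  (IVW: ≈ 7 SEs, a 2.6× larger absolute bias); the 50%-breakdown guarantee
  is asymptotic in instrument precision, and the suite demonstrates it in
  a tight-SE fixture.

## Problem sizes and numerical choices

Replicate counts in the tests and acceptance script (1000 coverage
replicates, 2000 Q replicates, 200 PRESSO replicates at 1000 simulations
each, 100 pipeline runs) were chosen to resolve the stated tolerance bands
with binomial noise well inside them. Degenerate inputs are handled
explicitly: one instrument degrades IVW (and conmix) to the Wald ratio;
Egger and the weighted median refuse fewer than three instruments;
MR-PRESSO refuses fewer than four instruments or fewer than 100
simulations; a zero total effect makes the proportion mediated undefined
(error, not NaN); rank-deficient multivariable designs are refused naming
the collinear exposures.
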
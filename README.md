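# mrchain

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
the full inference chain used in studies that screen several correlated risk
factors against a disease outcome: instrument selection, univariable causal
estimators, heterogeneity/pleiotropy diagnostics, multivariable MR, and
mediation ("network") MR with the proportion-mediated decomposition.

## Who it is for and what it does

Epidemiologists with summary-level GWAS associations — one table per trait
of per-SNP effect sizes, alleles, frequencies, standard errors — who want to
ask: *which of these risk factors causally affect the outcome, which of them
act directly, and how much of a non-direct factor's effect flows through the
others?*

For a valid genetic instrument j, the Wald ratio
`beta_Y[j] / beta_X[j]` estimates the causal effect of exposure X on outcome
Y (log odds ratio for a binary outcome). The package implements:

* **gwas_io** — tab-separated summary-statistic I/O with configurable column
  maps, validation, and allele harmonization across panels (sign/frequency
  flips, strand complements, palindromic-SNP frequency rule with a
  configurable ambiguity band, per-SNP alignment log).
* **instruments** — genome-wide significance and MAF filters, deterministic
  greedy LD clumping on a supplied r² matrix, variance explained
  `R² = 2 beta² EAF(1−EAF)/SD²` and instrument strength
  `F = ((N−k−1)/k) · R²/(1−R²)`.
* **univariable** — Wald ratio, fixed/random-effects IVW, MR-Egger
  (slope + pleiotropy intercept), weighted median with parametric-bootstrap
  SE, contamination mixture with profile-likelihood CI.
* **robustness** — Cochran's Q, Egger-intercept gate, MR-PRESSO (global,
  per-SNP outlier, distortion tests), and the decision rule that picks the
  reported estimate (IVW when clean; weighted median under concordant
  heterogeneity; outlier-corrected IVW under pleiotropy).
* **mvmr** — multivariable IVW giving direct effects conditional on
  co-exposures, and the independent/mediated classification.
* **mediation** — the `beta1/beta2/beta3` chain and the proportion mediated
  `E = 100% · Σ beta1_k·beta2_k / (beta3 + Σ beta1_k·beta2_k)` with
  delta-method (and Monte-Carlo cross-check) standard errors.
* **synthetic_data** — a generator of summary-statistic panels from a known
  causal diagram (sample-size-driven SEs, configurable invalid-instrument
  fraction and pleiotropy regime, block LD matrices), so every stage is
  testable with planted truth.
* **run_study()** — the three-stage pipeline (Bonferroni-gated univariable
  screen → multivariable classification → mediation chains) producing tidy
  result tables.

Everything takes and returns tibbles; fitted objects have `tidy()` /
`glance()` methods and `autoplot()` / `plot_instruments()` figures.

## Worked example

Simulate the documented four-exposure scenario — `a` and `b` act on a binary
outcome directly (log-OR +0.5 / −0.5), `c` and `d` act only through them —
and run the full study:

```r
library(mrchain)

sim   <- simulate_study_scenario(seed = 7)
study <- run_study(sim$panels[c("a", "b", "c", "d")], sim$panels["y"],
                   seed = 7)

glance(study)
#> # A tibble: 1 × 6
#>   n_pairs n_significant n_independent n_mediated threshold  seed
#>     <int>         <int>         <int>      <int>     <dbl> <dbl>
#> 1       4             4             2          2    0.0125     7

tidy(study)[, c("exposure", "or", "or_ci_low", "or_ci_high",
                "chosen_method", "significant")]
#> # A tibble: 4 × 6
#>   exposure    or or_ci_low or_ci_high chosen_method    significant
#>   <chr>    <dbl>     <dbl>      <dbl> <chr>            <lgl>
#> 1 a        1.65      1.61       1.69  ivw              TRUE
#> 2 b        0.613     0.598      0.629 presso_corrected TRUE
#> 3 c        1.22      1.18       1.25  ivw              TRUE
#> 4 d        0.836     0.813      0.860 ivw              TRUE

study$mvmr[, c("exposure", "or", "or_ci_low", "or_ci_high", "class")]
#> # A tibble: 4 × 5
#>   exposure    or or_ci_low or_ci_high class
#>   <chr>    <dbl>     <dbl>      <dbl> <chr>
#> 1 a        1.64      1.60       1.69  independent
#> 2 b        0.607     0.592      0.623 independent
#> 3 c        0.998     0.969      1.03  mediated
#> 4 d        1.02      0.990      1.05  mediated
```

Reading this: all four factors pass the univariable screen (reported odds
ratios per 1-SD exposure change, gated at the Bonferroni threshold
0.05/4 = 0.0125; `b`'s Egger intercept happened to flag pleiotropy, so its
reported row is the MR-PRESSO outlier-corrected IVW — the decision rule at
work). Conditional on each other, only `a` and `b` retain direct effects
(multivariable ORs ≈ their planted values, `c` and `d` shrink to the null),
so `c` and `d` are classed mediated and sent to the mediation stage:

```r
study$mediation[study$mediation$exposure == "c",
                c("mediator", "proportion", "se", "ci_low", "ci_high")]
#> # A tibble: 4 × 5
#>   mediator proportion    se ci_low ci_high
#>   <chr>         <dbl> <dbl>  <dbl>   <dbl>
#> 1 a          102.     7.68  87.0   117.
#> 2 b           -0.868  0.895 -2.62    0.886
#> 3 d            0.0405 0.347 -0.640   0.721
#> 4 all        101.     7.81  85.5   116.
```

About 100% of `c`'s effect on the outcome is carried by mediator `a`
(the planted truth: `c` acts only via `c → a → y`), essentially none by `b`
or `d`. Proportions are reported untruncated with delta-method 95% CIs.

`autoplot(study)` draws the forest of reported odds ratios;
`plot_instruments(h)` shows a harmonized set with the IVW and Egger fits.

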
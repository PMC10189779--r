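#' Construct a mediation effect chain
#'
#' Bundles the three coefficient sets of a network-MR decomposition for one
#' exposure, K mediators and one outcome: `beta1[k]`, the effect of the
#' exposure on mediator k; `beta2[k]`, the effect of mediator k on the
#' outcome adjusted for the exposure; and `beta3`, the effect of the
#' exposure on the outcome adjusted for the whole mediator set. All are MR
#' estimates on the outcome's log-odds scale (for the `beta2`/`beta3`
#' regressions) or the mediator's scale (`beta1`).
#'
#' @param exposure_id,mediator_ids Labels.
#' @param beta1,se1 Length-K exposure-to-mediator effects and SEs.
#' @param beta2,se2 Length-K adjusted mediator-to-outcome effects and SEs.
#' @param beta3,se3 Scalar adjusted exposure-to-outcome effect and SE.
#' @return A list of class `mediation_chain`.
#' @export
mediation_chain <- function(exposure_id, mediator_ids, beta1, se1, beta2, se2,
                            beta3, se3) {
  K <- length(mediator_ids)
  stopifnot(length(beta1) == K, length(se1) == K,
            length(beta2) == K, length(se2) == K,
            length(beta3) == 1, length(se3) == 1)
  if (any(c(se1, se2, se3) <= 0)) abort("all SEs must be > 0")
  structure(
    list(exposure_id = exposure_id, mediator_ids = mediator_ids,
         beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
         beta3 = beta3, se3 = se3),
    class = "mediation_chain"
  )
}

#' @export
print.mediation_chain <- function(x, ...) {
  cat(sprintf("<mediation_chain> %s -> {%s} -> outcome; beta3 = %.4f (SE %.4f)\n",
              x$exposure_id, paste(x$mediator_ids, collapse = ", "),
              x$beta3, x$se3))
  invisible(x)
}

#' @export
tidy.mediation_chain <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure_id, mediator = x$mediator_ids,
    beta1 = x$beta1, se1 = x$se1, beta2 = x$beta2, se2 = x$se2,
    beta3 = x$beta3, se3 = x$se3
  )
}

#' Proportion of a causal effect carried by mediators
#'
#' The indirect effect through K mediators is `sum(beta1[k] * beta2[k])`;
#' the total effect is the adjusted direct effect plus the indirect effect,
#' `beta3 + sum(beta1[k] * beta2[k])`; and the proportion mediated is their
#' ratio expressed in percent,
#' `E = 100 * indirect / (beta3 + indirect)`.
#'
#' The default standard error uses first-order error propagation (the delta
#' method) with the coefficients treated as mutually independent, which is
#' appropriate when the mediators are uncorrelated: writing T for the total
#' effect, the gradient components are `beta2[k] * beta3 / T^2` (wrt
#' `beta1[k]`), `beta1[k] * beta3 / T^2` (wrt `beta2[k]`) and
#' `-indirect / T^2` (wrt `beta3`). A Monte-Carlo propagation mode redraws
#' every coefficient from its normal sampling distribution and reports the
#' empirical spread, as a cross-check of the analytic gradient. Proportions
#' and intervals outside \[0, 100\]% are reported as-is, never truncated.
#'
#' @param chain A [mediation_chain()].
#' @param method `"delta"` (analytic, default) or `"mc"` (Monte-Carlo
#'   propagation).
#' @param n_draws Draws for the Monte-Carlo mode.
#' @param seed Seed for the Monte-Carlo mode.
#' @return A list of class `mediation_result`: `proportion` (percent), `se`,
#'   `ci_low`, `ci_high`, `indirect`, `total`, `method`.
#' @export
proportion_mediated <- function(chain, method = c("delta", "mc"),
                                n_draws = 1e5, seed = 1) {
  method <- match.arg(method)
  indirect <- sum(chain$beta1 * chain$beta2)
  total <- chain$beta3 + indirect
  if (total == 0) abort("total effect is zero; proportion mediated is undefined")
  prop <- 100 * indirect / total
  if (method == "delta") {
    g1 <- 100 * chain$beta2 * chain$beta3 / total^2
    g2 <- 100 * chain$beta1 * chain$beta3 / total^2
    g3 <- -100 * indirect / total^2
    se <- sqrt(sum(g1^2 * chain$se1^2) + sum(g2^2 * chain$se2^2) + g3^2 * chain$se3^2)
  } else {
    se <- withr::with_seed(seed, {
      K <- length(chain$beta1)
      b1 <- matrix(rnorm(K * n_draws, chain$beta1, chain$se1), nrow = K)
      b2 <- matrix(rnorm(K * n_draws, chain$beta2, chain$se2), nrow = K)
      b3 <- rnorm(n_draws, chain$beta3, chain$se3)
      ind <- colSums(b1 * b2)
      stats::sd(100 * ind / (b3 + ind))
    })
  }
  z <- stats::qnorm(0.975)
  structure(
    list(proportion = prop, se = se, ci_low = prop - z * se, ci_high = prop + z * se,
         indirect = indirect, total = total, method = method),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> E = %.1f%% (SE %.1f, 95%% CI %.1f to %.1f), indirect = %.4f, total = %.4f\n",
              x$proportion, x$se, x$ci_low, x$ci_high, x$indirect, x$total))
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(proportion = x$proportion, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 indirect = x$indirect, total = x$total, method = x$method)
}

# union of each panel's selected, clumped instruments, restricted to SNPs
# present in every panel (complete case)
pool_instruments <- function(panels, cfg, ld_r2 = NULL) {
  chosen <- lapply(panels, function(p) {
    sel <- select_genomewide(p, cfg)
    if (!is.null(ld_r2)) sel <- clump(sel, ld_r2, cfg)
    sel$snp
  })
  pooled <- Reduce(union, chosen)
  present <- Reduce(intersect, lapply(panels, `[[`, "snp"))
  intersect(pooled, present)
}

#' Estimate a mediation chain from phenotype panels
#'
#' Builds the `beta1`/`beta2`/`beta3` chain by running the IVW machinery
#' three ways: `beta1[k]` from univariable MR of the exposure on mediator k
#' (exposure instruments only); `beta2[k]` from multivariable MR of
#' (mediator k, exposure) on the outcome, taking mediator k's coefficient;
#' `beta3` from multivariable MR of (exposure, all mediators) on the
#' outcome, taking the exposure's coefficient. Multivariable stages pool the
#' union of each trait's genome-wide-significant (optionally clumped)
#' instruments, keeping SNPs present in every panel.
#'
#' @param exposure A phenotype panel for the exposure.
#' @param mediators Named list of mediator panels.
#' @param outcome The outcome panel.
#' @param cfg An [instrument_config()].
#' @param ld_r2 Optional LD matrix used to clump each trait's instruments.
#' @param palindrome_band Passed to [harmonize()].
#' @return A [mediation_chain()].
#' @export
build_chain <- function(exposure, mediators, outcome, cfg = instrument_config(),
                        ld_r2 = NULL, palindrome_band = c(0.42, 0.58)) {
  if (is.null(names(mediators)) || any(names(mediators) == "")) {
    abort("mediators must be a named list of panels")
  }
  med_ids <- names(mediators)

  # beta1: exposure -> mediator k, exposure instruments
  exp_iv <- select_genomewide(exposure, cfg)
  if (!is.null(ld_r2)) exp_iv <- clump(exp_iv, ld_r2, cfg)
  b1 <- purrr::map(mediators, function(m) {
    h <- harmonize(exp_iv[exp_iv$snp %in% m$snp, ], m, palindrome_band)
    mr_ivw(h)
  })

  # beta2: (mediator k, exposure) -> outcome, mediator coefficient
  b2 <- purrr::imap(mediators, function(m, id) {
    snps <- pool_instruments(list(m, exposure), cfg, ld_r2)
    h <- harmonize(m[match(snps, m$snp), ],
                   list(exp = exposure, y = outcome), palindrome_band)
    mv <- mr_mvmr(h, exposures = c("x", "exp"))
    mv$estimates[mv$estimates$exposure == "x", ]
  })

  # beta3: (exposure, all mediators) -> outcome, exposure coefficient
  snps <- pool_instruments(c(list(exposure), unname(mediators)), cfg, ld_r2)
  others <- c(mediators, list(y = outcome))
  h3 <- harmonize(exposure[match(snps, exposure$snp), ], others, palindrome_band)
  mv3 <- mr_mvmr(h3, exposures = c("x", med_ids))
  row3 <- mv3$estimates[mv3$estimates$exposure == "x", ]

  mediation_chain(
    exposure_id = attr(exposure, "phenotype_id") %||% "exposure",
    mediator_ids = med_ids,
    beta1 = purrr::map_dbl(b1, "beta"), se1 = purrr::map_dbl(b1, "se"),
    beta2 = purrr::map_dbl(b2, "beta"), se2 = purrr::map_dbl(b2, "se"),
    beta3 = row3$beta, se3 = row3$se
  )
}
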
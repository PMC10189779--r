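#' Cochran's Q heterogeneity test
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-SNP Wald ratios from the fixed-effects IVW estimate,
#' `sum(w_j * (ratio_j - beta_ivw)^2)` with `w_j = beta_x_j^2 / se_y_j^2`,
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' Large Q signals heterogeneity among instruments, a symptom of invalid
#' instruments or multiple causal pathways.
#'
#' @inheritParams mr_ivw
#' @return A list with `q_stat`, `df` and `q_pvalue`.
#' @export
cochran_q <- function(h, outcome = "y") {
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k < 2) abort("Cochran's Q needs at least 2 SNPs")
  fixed <- mr_ivw(h, model = "fixed", outcome = outcome)
  w <- 1 / d$sy^2
  q <- sum(w * (d$by - fixed$beta * d$bx)^2)
  list(q_stat = q, df = k - 1L, q_pvalue = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

# leave-one-out fixed-effects IVW slopes, vectorised over simulated outcome
# betas (columns of by_mat)
loo_ivw <- function(bx, by_mat, w) {
  sxx <- sum(w * bx^2)
  sxy <- colSums(w * bx * by_mat)
  num <- matrix(sxy, nrow = length(bx), ncol = ncol(by_mat), byrow = TRUE) -
    (w * bx) * by_mat
  den <- sxx - w * bx^2
  num / den
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based test for horizontal pleiotropy. The observed global
#' statistic is the weighted residual sum of squares where each SNP's
#' residual is taken against the IVW fit that excludes it. Its null
#' distribution is obtained by redrawing outcome associations from the
#' no-pleiotropy model (`beta_y_j ~ N(beta_x_j * b_(-j), se_y_j^2)`). SNPs
#' whose observed squared residual is extreme relative to its simulated
#' distribution at the Bonferroni-adjusted level `outlier_alpha / k` are
#' flagged as outliers, the IVW estimate is recomputed without them, and a
#' distortion test compares the observed change in the estimate with the
#' change induced by removing random SNP subsets of the same size.
#'
#' @inheritParams mr_ivw
#' @param n_sim Number of parametric simulations (at least 100; empirical
#'   p-values have floor `1 / (n_sim + 1)`).
#' @param outlier_alpha Familywise level for the per-SNP outlier test before
#'   Bonferroni adjustment.
#' @param seed Seed for the simulations; recorded on the output.
#' @return A list of class `mr_presso`: `global_rss_obs`, `global_p`,
#'   `outlier_snps` (tibble of `snp`, `p`), `corrected_estimate` (an
#'   [mr_estimate], present only when outliers were removed),
#'   `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1, outcome = "y") {
  if (n_sim < 100) abort("n_sim must be at least 100 for a stable empirical p-value")
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k < 4) abort("MR-PRESSO needs at least 4 SNPs")
  w <- 1 / d$sy^2

  b_loo <- drop(loo_ivw(d$bx, matrix(d$by, ncol = 1), w))
  resid_obs <- d$by - b_loo * d$bx
  rss_obs_per <- w * resid_obs^2
  rss_obs <- sum(rss_obs_per)

  sims <- withr::with_seed(seed, {
    by_sim <- matrix(rnorm(k * n_sim, mean = d$bx * b_loo, sd = d$sy), nrow = k)
    b_loo_sim <- loo_ivw(d$bx, by_sim, w)
    resid_sim <- by_sim - b_loo_sim * d$bx
    w * resid_sim^2
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + rowSums(sims >= rss_obs_per)) / (n_sim + 1)
  is_out <- p_snp < outlier_alpha / k
  outliers <- tibble::tibble(snp = d$snp[is_out], p = p_snp[is_out])

  corrected <- NULL
  distortion_p <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2) {
    hc <- h[!is_out, , drop = FALSE]
    corrected <- mr_ivw(hc, model = "random", outcome = outcome)
    corrected$method <- "presso_corrected"
    sxx <- sum(w * d$bx^2)
    sxy <- sum(w * d$bx * d$by)
    beta_all <- sxy / sxx
    d_obs <- beta_all - mr_ivw(hc, model = "fixed", outcome = outcome)$beta
    n_out <- sum(is_out)
    txy <- w * d$bx * d$by
    txx <- w * d$bx^2
    d_sim <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(k, n_out)
        beta_all - (sxy - sum(txy[drop_idx])) / (sxx - sum(txx[drop_idx]))
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(
    list(global_rss_obs = rss_obs, global_p = global_p, outlier_snps = outliers,
         corrected_estimate = corrected, distortion_p = distortion_p,
         n_sim = n_sim, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.4g, global p = %.4g, %d outlier(s), n_sim = %d\n",
              x$global_rss_obs, x$global_p, nrow(x$outlier_snps), x$n_sim))
  if (!is.null(x$corrected_estimate)) print(x$corrected_estimate)
  invisible(x)
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_rss_obs = x$global_rss_obs, global_p = x$global_p,
                 n_outliers = nrow(x$outlier_snps), distortion_p = x$distortion_p,
                 n_sim = x$n_sim, seed = x$seed)
}

#' @export
tidy.mr_presso <- function(x, ...) x$outlier_snps

#' Heterogeneity and pleiotropy diagnostics for one harmonized set
#'
#' Combines Cochran's Q with the MR-Egger intercept test and, when
#' pleiotropy is indicated (or on request), MR-PRESSO. The `heterogeneous`
#' and `pleiotropic` flags compare the respective p-values with `alpha`.
#'
#' @inheritParams mr_presso
#' @param alpha Gate level for both the heterogeneity and pleiotropy flags.
#' @param presso `"auto"` runs MR-PRESSO only when the Egger intercept flags
#'   pleiotropy (and at least 4 SNPs are available); `"always"` / `"never"`
#'   override.
#' @return A list of class `mr_sensitivity` with `q_stat`, `df`, `q_pvalue`,
#'   `egger_intercept_p`, `heterogeneous`, `pleiotropic`, `alpha` and
#'   `presso` (an `mr_presso` or `NULL`).
#' @export
sensitivity_report <- function(h, alpha = 0.05, presso = c("auto", "always", "never"),
                               n_sim = 1000, seed = 1, outcome = "y") {
  presso <- match.arg(presso)
  q <- cochran_q(h, outcome = outcome)
  eg <- mr_egger(h, outcome = outcome)
  pleio <- eg$intercept$pvalue < alpha
  run_presso <- switch(presso,
    always = TRUE,
    never = FALSE,
    auto = pleio
  )
  k <- nrow(h)
  pres <- if (run_presso && k >= 4) {
    mr_presso(h, n_sim = n_sim, seed = seed, outcome = outcome)
  } else {
    NULL
  }
  structure(
    list(q_stat = q$q_stat, df = q$df, q_pvalue = q$q_pvalue,
         egger_intercept_p = eg$intercept$pvalue,
         heterogeneous = q$q_pvalue < alpha,
         pleiotropic = pleio,
         alpha = alpha, presso = pres),
    class = "mr_sensitivity"
  )
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<mr_sensitivity> Q = %.3f (df %d, p = %.3g)%s; Egger intercept p = %.3g%s\n",
    x$q_stat, x$df, x$q_pvalue,
    if (x$heterogeneous) " [heterogeneous]" else "",
    x$egger_intercept_p,
    if (x$pleiotropic) " [pleiotropic]" else ""
  ))
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}

#' @export
glance.mr_sensitivity <- function(x, ...) {
  tibble::tibble(q_stat = x$q_stat, df = x$df, q_pvalue = x$q_pvalue,
                 egger_intercept_p = x$egger_intercept_p,
                 heterogeneous = x$heterogeneous, pleiotropic = x$pleiotropic,
                 presso_global_p = if (is.null(x$presso)) NA_real_ else x$presso$global_p)
}

#' Choose the reported estimate from the diagnostic flags
#'
#' Decision rule for which estimator's result a study reports for one
#' exposure-outcome pair: with neither heterogeneity nor pleiotropy, IVW is
#' the primary estimate; with heterogeneity but no pleiotropy and the
#' weighted median agreeing in direction with IVW, the weighted median is
#' reported (it tolerates up to half-invalid instruments); when pleiotropy
#' is detected, the MR-PRESSO outlier-corrected IVW is reported; with
#' heterogeneity and discordant directions, IVW is reported flagged
#' `"discordant"` rather than suppressed.
#'
#' @param ivw_est,wmedian_est [mr_estimate]s from the same harmonized set.
#' @param het An `mr_sensitivity` report for that set.
#' @param presso An `mr_presso` result; required when `het$pleiotropic` is
#'   `TRUE` (defaults to the one embedded in `het`).
#' @return A list of class `mr_decision`: `chosen_method`, `rationale`, and
#'   the chosen `estimate`.
#' @export
decide_reported <- function(ivw_est, wmedian_est, het, presso = het$presso) {
  if (het$pleiotropic) {
    if (is.null(presso)) abort("pleiotropy flagged but no MR-PRESSO result supplied")
    est <- presso$corrected_estimate
    if (is.null(est)) {
      est <- ivw_est
      rationale <- "pleiotropy_no_outliers_removed"
    } else {
      rationale <- "pleiotropy_outliers_removed"
    }
    return(structure(list(chosen_method = "presso_corrected", rationale = rationale,
                          estimate = est), class = "mr_decision"))
  }
  if (het$heterogeneous) {
    if (sign(wmedian_est$beta) == sign(ivw_est$beta)) {
      return(structure(list(chosen_method = "weighted_median",
                            rationale = "heterogeneity_concordant_direction",
                            estimate = wmedian_est), class = "mr_decision"))
    }
    return(structure(list(chosen_method = "ivw", rationale = "discordant",
                          estimate = ivw_est), class = "mr_decision"))
  }
  structure(list(chosen_method = "ivw", rationale = "clean", estimate = ivw_est),
            class = "mr_decision")
}

#' @export
print.mr_decision <- function(x, ...) {
  cat(sprintf("<mr_decision> report %s (%s)\n", x$chosen_method, x$rationale))
  print(x$estimate)
  invisible(x)
}

#' @export
tidy.mr_decision <- function(x, ...) {
  dplyr::mutate(tidy(x$estimate), chosen_method = x$chosen_method,
                rationale = x$rationale)
}
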
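#' Multivariable MR by weighted regression
#'
#' Regresses the per-SNP outcome associations jointly on several exposures'
#' associations, without intercept, with weights `1 / se_y^2`. Each
#' coefficient is an exposure's direct effect on the outcome conditional on
#' the co-exposures. Standard errors inflate the weighted regression SE by
#' the multiplicative overdispersion factor `max(1, sqrt(Q / (k - m)))`,
#' matching the univariable IVW random-effects model (to which this reduces
#' when `m = 1`).
#'
#' @param h A harmonized set from [harmonize()] whose `others` included all
#'   co-exposures and the outcome; the reference exposure's columns are
#'   labelled `x`.
#' @param exposures Labels of the exposure columns to include, e.g.
#'   `c("x", "bmi")`; `"x"` denotes the reference exposure.
#' @param outcome Label of the outcome columns (default `"y"`).
#' @return A list of class `mvmr_result` with a tibble `estimates` (one row
#'   per exposure: `exposure`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`,
#'   odds-ratio view), plus `n_snp` and `q_stat`.
#' @export
mr_mvmr <- function(h, exposures, outcome = "y") {
  d <- h_cols(h, outcome)
  k <- nrow(h)
  m <- length(exposures)
  if (k <= m) abort("need more SNPs than exposures")
  X <- vapply(exposures, function(e) {
    col <- if (e == "x") "beta_x" else paste0("beta_", e)
    if (is.null(h[[col]])) abort(paste0("no beta column for exposure '", e, "'"))
    h[[col]]
  }, numeric(k))
  if (qr(X)$rank < m) {
    abort(paste0("exposure beta matrix is rank deficient; check collinearity among: ",
                 paste(exposures, collapse = ", ")))
  }
  w <- 1 / d$sy^2
  xtwx <- crossprod(X, w * X)
  beta <- unname(drop(solve(xtwx, crossprod(X, w * d$by))))
  resid <- d$by - drop(X %*% beta)
  q <- sum(w * resid^2)
  infl <- max(1, sqrt(q / (k - m)))
  se <- unname(sqrt(diag(solve(xtwx)))) * infl
  z <- stats::qnorm(0.975)
  est <- tibble::tibble(
    exposure = exposures, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pvalue = p_from_z(beta, se),
    or = exp(beta), or_ci_low = exp(beta - z * se), or_ci_high = exp(beta + z * se)
  )
  structure(list(estimates = est, n_snp = k, q_stat = q), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures on %d SNPs (Q = %.2f)\n",
              nrow(x$estimates), x$n_snp, x$q_stat))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.mvmr_result <- function(x, ...) x$estimates

#' @export
glance.mvmr_result <- function(x, ...) {
  tibble::tibble(n_snp = x$n_snp, q_stat = x$q_stat,
                 n_exposures = nrow(x$estimates))
}

#' Partition significant exposures into independent vs mediated
#'
#' An exposure that remains significant conditional on its co-exposures
#' (multivariable p-value strictly below `alpha`) acts on the outcome
#' directly and is classed `independent`; the rest are classed `mediated`
#' and become candidates for mediation analysis.
#'
#' @param uv_significant Phenotype labels that passed the univariable
#'   screen; must be a subset of the multivariable exposures.
#' @param mv An `mvmr_result` over those exposures.
#' @param alpha Significance level for the direct effect (strict inequality).
#' @return A tibble with `exposure`, `pvalue`, `class`.
#' @export
classify_independence <- function(uv_significant, mv, alpha = 0.05) {
  est <- mv$estimates
  if (!all(uv_significant %in% est$exposure)) {
    abort("uv_significant must be a subset of the multivariable exposures")
  }
  est <- est[match(uv_significant, est$exposure), ]
  tibble::tibble(
    exposure = est$exposure,
    pvalue = est$pvalue,
    class = ifelse(est$pvalue < alpha, "independent", "mediated")
  )
}
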
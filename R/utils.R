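#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm pchisq pt qt dnorm rnorm runif rbinom median sd var weighted.mean setNames
#' @importFrom utils head
NULL

# two-sided normal p-value from an estimate and its SE
p_from_z <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

ci_from_se <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(DNA_COMPLEMENT[a1] == a2)
}

#' Construct a causal-effect estimate object
#'
#' Container used by every estimator in the package: the method tag, the
#' causal effect on the additive (log-odds, for binary outcomes) scale, its
#' standard error, a Wald 95% confidence interval, a two-sided p-value, the
#' number of instruments used, and an odds-ratio view (`exp` of the estimate
#' and interval) for binary outcomes.
#'
#' @param method Method tag, e.g. `"ivw_random"`.
#' @param beta Point estimate on the log-odds (or continuous-outcome) scale.
#' @param se Standard error of `beta`.
#' @param n_snp Number of instruments contributing to the estimate.
#' @param pvalue Two-sided p-value; computed from a normal approximation if
#'   omitted.
#' @param ci Length-2 interval; computed as `beta ± 1.96 se` if omitted.
#' @param ... Extra fields stored on the object (e.g. `intercept`, `note`).
#'
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL, ci = NULL, ...) {
  stopifnot(is.numeric(beta), is.numeric(se), se >= 0)
  if (is.null(ci)) ci <- ci_from_se(beta, se)
  if (is.null(pvalue)) pvalue <- p_from_z(beta, se)
  out <- list(
    method = method, beta = beta, se = se,
    ci_low = ci[[1]], ci_high = ci[[2]],
    pvalue = pvalue, n_snp = as.integer(n_snp),
    or = exp(beta), or_ci_low = exp(ci[[1]]), or_ci_high = exp(ci[[2]]),
    ...
  )
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, OR = %.3f [%.3f, %.3f], n_snp = %d\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
    x$or, x$or_ci_low, x$or_ci_high, x$n_snp
  ))
  invisible(x)
}

#' Tidy an MR estimate into a one-row tibble
#'
#' @param x An [mr_estimate] object.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, interval, p-value, odds-ratio
#'   view and instrument count.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
    n_snp = x$n_snp
  )
}

#' @export
glance.mr_estimate <- function(x, ...) tidy(x, ...)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
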
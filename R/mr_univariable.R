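h_cols <- function(h, outcome = "y") {
  by <- h[[paste0("beta_", outcome)]]
  sy <- h[[paste0("se_", outcome)]]
  if (is.null(by) || is.null(sy)) {
    abort(paste0("harmonized set has no columns for outcome '", outcome, "'"))
  }
  list(bx = h$beta_x, sx = h$se_x, by = by, sy = sy, snp = h$snp)
}

#' Wald ratio estimate for a single instrument
#'
#' The per-SNP causal estimate `beta_y / beta_x`. The first-order delta
#' method gives `se = se_y / |beta_x|`; the second-order version adds the
#' uncertainty in the instrument-exposure association,
#' `sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param beta_x,se_x Instrument-exposure association and its SE.
#' @param beta_y,se_y Instrument-outcome association and its SE.
#' @param second_order Use the second-order delta-method SE.
#' @return An [mr_estimate] with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0) abort("beta_x must be nonzero for a Wald ratio")
  beta <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  mr_estimate("wald", beta, se, n_snp = 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of the outcome associations on the exposure
#' associations through the origin, with weights `1 / se_y^2`; equivalently
#' the inverse-variance weighted meta-analysis of per-SNP Wald ratios. The
#' multiplicative random-effects model (the default) inflates the fixed
#' SE by `max(1, sqrt(Q / (k - 1)))`, where Q is Cochran's heterogeneity
#' statistic, and is conservative under heterogeneity; the fixed model uses
#' the nominal SE.
#'
#' @param h A harmonized set from [harmonize()].
#' @param model `"random"` (multiplicative random effects) or `"fixed"`.
#' @param outcome Label of the outcome columns in `h` (default `"y"`).
#' @return An [mr_estimate] with method `"ivw_random"` or `"ivw_fixed"` and
#'   an extra `q_stat` field. With a single SNP the Wald ratio is returned.
#' @export
mr_ivw <- function(h, model = c("random", "fixed"), outcome = "y") {
  model <- match.arg(model)
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k == 0) abort("no SNPs in harmonized set")
  if (all(d$bx == 0)) abort("all exposure betas are zero")
  if (k == 1) return(wald_ratio(d$bx, d$sx, d$by, d$sy))
  w <- 1 / d$sy^2
  beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- sqrt(1 / sum(w * d$bx^2))
  q <- sum(w * (d$by - beta * d$bx)^2)
  se <- if (model == "random") se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  mr_estimate(paste0("ivw_", if (model == "random") "random" else "fixed"),
              beta, se, n_snp = k, q_stat = q)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations with a free
#' intercept, weights `1 / se_y^2`. The slope estimates the causal effect
#' allowing directional pleiotropy; the intercept estimates the average
#' directional pleiotropic effect and its test is the standard pleiotropy
#' diagnostic. Exposure associations are oriented non-negative before
#' fitting (the InSIDE convention), flipping the outcome associations
#' accordingly. Standard errors use the weighted residual variance floored
#' at 1 (multiplicative random effects) with t-based inference on k - 2
#' degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return A list of class `mr_egger` with elements `slope` and `intercept`
#'   (both [mr_estimate]s, methods `"egger_slope"` / `"egger_intercept"`).
#' @export
mr_egger <- function(h, outcome = "y") {
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k < 3) abort("MR-Egger needs at least 3 SNPs")
  s <- ifelse(d$bx < 0, -1, 1)
  bx <- d$bx * s
  by <- d$by * s
  w <- 1 / d$sy^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * by)
  coefs <- unname(drop(solve(xtwx, xtwy)))
  resid <- by - drop(X %*% coefs)
  sigma2 <- sum(w * resid^2) / (k - 2)
  vc <- max(1, sigma2) * solve(xtwx)
  ses <- unname(sqrt(diag(vc)))
  tstat <- coefs / ses
  pv <- 2 * stats::pt(-abs(tstat), df = k - 2)
  tq <- stats::qt(0.975, df = k - 2)
  mk <- function(i, tag) {
    mr_estimate(tag, coefs[i], ses[i], n_snp = k, pvalue = pv[i],
                ci = c(coefs[i] - tq * ses[i], coefs[i] + tq * ses[i]))
  }
  structure(list(slope = mk(2, "egger_slope"), intercept = mk(1, "egger_intercept")),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope); print(x$intercept)
  invisible(x)
}

#' @export
tidy.mr_egger <- function(x, ...) {
  dplyr::bind_rows(tidy(x$slope), tidy(x$intercept))
}

weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(b[1])
  i <- max(which(cs < 0.5))
  if (i == length(b)) return(b[length(b)])
  b[i] + (b[i + 1] - b[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the value at which the
#' cumulative inverse-variance weight crosses 0.5, interpolating linearly
#' between adjacent order statistics. Consistent even when up to 50% of the
#' weight comes from invalid instruments. The SE comes from a parametric
#' bootstrap: exposure and outcome associations are redrawn from their
#' normal sampling distributions and the weighted median recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap; recorded on the output.
#' @return An [mr_estimate] with method `"weighted_median"` and extra fields
#'   `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1, outcome = "y") {
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k < 3) abort("weighted median needs at least 3 SNPs")
  ratio <- d$by / d$bx
  w <- d$bx^2 / d$sy^2
  beta <- weighted_median_point(ratio, w)
  boots <- withr::with_seed(seed, {
    bxm <- matrix(rnorm(k * n_boot, d$bx, d$sx), nrow = k)
    bym <- matrix(rnorm(k * n_boot, d$by, d$sy), nrow = k)
    vapply(seq_len(n_boot), function(j) {
      weighted_median_point(bym[, j] / bxm[, j], bxm[, j]^2 / d$sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, n_snp = k, n_boot = n_boot, seed = seed)
}

#' Contamination-mixture estimate
#'
#' Models each SNP's Wald ratio as drawn either from a valid component
#' centred at the causal effect with the ratio's own sampling variance, or
#' from an invalid component centred at zero with variance inflated by
#' `psi^2`. For each candidate effect on a grid, SNPs are classed to the
#' component with the higher likelihood; the profile log-likelihood is the
#' sum of the winning log-densities and is maximised over the grid. The 95%
#' confidence set collects grid points within `qchisq(0.95, 1) / 2` (about
#' 1.92) log-likelihood units of the maximum.
#'
#' @inheritParams mr_ivw
#' @param psi Scale of the invalid component; defaults to 1.5 times the
#'   standard deviation of the Wald ratios.
#' @param grid Candidate effects; defaults to 1000 points spanning the ratio
#'   range widened by 3 ratio standard deviations.
#' @param n_grid Grid size when `grid` is not supplied.
#' @return A list of class `mr_conmix`: `estimate` (an [mr_estimate]),
#'   `valid_snps`, `psi` and the `profile` tibble (`theta`, `loglik`).
#' @export
mr_conmix <- function(h, psi = NULL, grid = NULL, n_grid = 1000, outcome = "y") {
  d <- h_cols(h, outcome)
  k <- length(d$bx)
  if (k == 0) abort("no SNPs in harmonized set")
  ratio <- d$by / d$bx
  se_r <- d$sy / abs(d$bx)
  if (k == 1) {
    est <- wald_ratio(d$bx, d$sx, d$by, d$sy)
    est$method <- "conmix"
    return(structure(list(estimate = est, valid_snps = d$snp, psi = psi %||% NA_real_,
                          profile = tibble::tibble(theta = est$beta, loglik = 0)),
                     class = "mr_conmix"))
  }
  spread <- stats::sd(ratio)
  if (spread == 0) spread <- max(se_r)
  if (is.null(psi)) psi <- 1.5 * spread
  if (psi <= 0) abort("psi must be > 0")
  if (is.null(grid)) {
    grid <- seq(min(ratio) - 3 * spread, max(ratio) + 3 * spread, length.out = n_grid)
  }
  l_invalid <- dnorm(ratio, 0, sqrt(se_r^2 + psi^2), log = TRUE)
  # k x n_grid matrix of valid-component log densities
  lv <- dnorm(outer(ratio, grid, `-`) / se_r, log = TRUE) - log(se_r)
  win <- pmax(lv, l_invalid)
  profile <- colSums(win)
  imax <- which.max(profile)
  if (imax == 1 || imax == length(grid)) {
    abort("profile likelihood maximised at the grid boundary; widen the grid")
  }
  theta <- grid[imax]
  drop <- stats::qchisq(0.95, 1) / 2
  inside <- profile >= profile[imax] - drop
  ci <- range(grid[inside])
  se <- (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  valid <- lv[, imax] >= l_invalid
  est <- mr_estimate("conmix", theta, se, n_snp = k, ci = ci,
                     pvalue = p_from_z(theta, max(se, .Machine$double.eps)))
  structure(
    list(estimate = est, valid_snps = d$snp[valid], psi = psi,
         profile = tibble::tibble(theta = grid, loglik = profile)),
    class = "mr_conmix"
  )
}

#' @export
print.mr_conmix <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  valid instruments: %d of %d (psi = %.3g)\n",
              length(x$valid_snps), x$estimate$n_snp, x$psi))
  invisible(x)
}

#' @export
tidy.mr_conmix <- function(x, ...) tidy(x$estimate)

#' Run a battery of univariable MR estimators
#'
#' Applies the requested estimators to one harmonized exposure-outcome set
#' and stacks their tidy summaries.
#'
#' @inheritParams mr_ivw
#' @param methods Estimators to run, a subset of `"ivw"`, `"egger"`,
#'   `"wmedian"`, `"conmix"`.
#' @param seed Seed forwarded to the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return A tibble with one row per estimate (Egger contributes its slope
#'   and intercept rows).
#' @export
mr_univariable <- function(h, methods = c("ivw", "egger", "wmedian", "conmix"),
                           seed = 1, n_boot = 1000, outcome = "y") {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  if ("ivw" %in% methods) rows$ivw <- tidy(mr_ivw(h, outcome = outcome))
  if ("egger" %in% methods) rows$egger <- tidy(mr_egger(h, outcome = outcome))
  if ("wmedian" %in% methods) {
    rows$wmedian <- tidy(mr_weighted_median(h, n_boot = n_boot, seed = seed,
                                            outcome = outcome))
  }
  if ("conmix" %in% methods) rows$conmix <- tidy(mr_conmix(h, outcome = outcome))
  dplyr::bind_rows(rows)
}
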
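#' Forest plot of the reported estimates of a study
#'
#' One row per exposure-outcome pair, odds-ratio scale with 95% interval,
#' faceted by outcome; filled points mark pairs passing the Bonferroni gate.
#'
#' @param object An `mr_study` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_study <- function(object, ...) {
  df <- object$reported
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high,
                   shape = .data$significant)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL, shape = "significant") +
    ggplot2::theme_minimal()
}

#' Forest plot of multivariable direct effects
#'
#' @param object An `mvmr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvmr_result <- function(object, ...) {
  ggplot2::ggplot(object$estimates, ggplot2::aes(x = .data$or, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "conditional odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Profile log-likelihood of a contamination-mixture fit
#'
#' @param object An `mr_conmix` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_conmix <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$theta, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$estimate$beta, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$estimate$ci_low, object$estimate$ci_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "candidate causal effect", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}

#' Scatter of instrument effects with fitted MR slopes
#'
#' Plots outcome against exposure associations for one harmonized set with
#' the IVW (through the origin) and MR-Egger (free intercept) fits overlaid.
#'
#' @param h A harmonized set from [harmonize()].
#' @param outcome Label of the outcome columns (default `"y"`).
#' @return A ggplot object.
#' @export
plot_instruments <- function(h, outcome = "y") {
  d <- h_cols(h, outcome)
  ivw <- mr_ivw(h, outcome = outcome)
  eg <- mr_egger(h, outcome = outcome)
  df <- tibble::tibble(bx = abs(d$bx), by = d$by * ifelse(d$bx < 0, -1, 1),
                       sy = d$sy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - 1.96 * .data$sy,
                                        ymax = .data$by + 1.96 * .data$sy),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = ivw$beta, intercept = 0, colour = "steelblue") +
    ggplot2::geom_abline(slope = eg$slope$beta, intercept = eg$intercept$beta,
                         colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
}
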
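#' Bonferroni-corrected significance threshold
#'
#' `alpha_family / n_comparisons`. With the default family level 0.05 over 6
#' exposure-outcome pairs this is 8.33e-3 (3 significant figures), the gate
#' applied to the univariable screen.
#'
#' @param alpha_family Familywise level (default 0.05).
#' @param n_comparisons Number of tests in the family (default 6).
#' @return The per-test threshold (exact; reports display 3 significant
#'   figures).
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_comparisons = 6) {
  if (n_comparisons < 1) abort("n_comparisons must be at least 1")
  if (alpha_family <= 0 || alpha_family >= 1) abort("alpha_family must lie in (0, 1)")
  alpha_family / n_comparisons
}

screen_pair <- function(exp_panel, out_panel, cfg, ld_r2, seed, n_boot, n_sim,
                        alpha, palindrome_band) {
  iv <- select_genomewide(exp_panel, cfg)
  if (!is.null(ld_r2)) iv <- clump(iv, ld_r2, cfg)
  if (nrow(iv) < 3) return(NULL)
  h <- harmonize(iv, out_panel, palindrome_band)
  if (nrow(h) < 3) return(NULL)
  ivw <- mr_ivw(h)
  wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  eg <- mr_egger(h)
  cm <- mr_conmix(h)
  sens <- sensitivity_report(h, alpha = alpha, presso = "auto",
                             n_sim = n_sim, seed = seed)
  decision <- decide_reported(ivw, wm, sens, sens$presso)
  methods <- dplyr::bind_rows(tidy(ivw), tidy(wm), tidy(eg), tidy(cm))
  list(h = h, methods = methods, sensitivity = sens, decision = decision)
}

#' Run the full study design: screen, classify, mediate
#'
#' Orchestrates the three-stage analysis on a set of exposure panels and
#' outcome panels.
#'
#' Stage 1 screens every exposure-outcome pair univariably: instruments are
#' selected (significance, MAF, optional LD clumping), harmonized with the
#' outcome, estimated by IVW / weighted median / MR-Egger / contamination
#' mixture, diagnosed for heterogeneity and pleiotropy, and summarised by
#' the [decide_reported()] rule; a pair survives when the reported
#' estimate's p-value falls below the Bonferroni threshold. Stage 2 runs
#' multivariable MR per outcome over the survivors and classifies each as
#' independent (direct effect persists) or mediated. Stage 3 builds, for
#' each mediated survivor, mediation chains through every other survivor
#' singly and through all of them jointly, reporting adjusted effects and
#' proportions mediated. Stages with empty inputs are skipped with a logged
#' reason.
#'
#' @param exposures Named list of exposure panels.
#' @param outcomes Named list of outcome panels (or a single panel, labelled
#'   `"y"`).
#' @param cfg An [instrument_config()].
#' @param ld_r2 Optional LD matrix for clumping.
#' @param alpha_family,n_comparisons Bonferroni family for the univariable
#'   gate; `n_comparisons` defaults to the number of exposures (the family
#'   is applied per outcome).
#' @param mvmr_alpha Level for the independent/mediated classification;
#'   defaults to the same Bonferroni threshold as the univariable gate.
#' @param sens_alpha Level for the heterogeneity and pleiotropy gates.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Seed driving every stochastic step.
#' @param palindrome_band Passed to [harmonize()].
#' @return A list of class `mr_study`: tibbles `univariable` (all method
#'   rows per pair), `reported` (one decided row per pair with the
#'   significance call), `mvmr` (direct effects and classification per
#'   outcome), `mediation` (per-mediator and joint proportions mediated),
#'   plus `threshold` and a character `log` of skipped stages.
#' @export
run_study <- function(exposures, outcomes, cfg = instrument_config(),
                      ld_r2 = NULL, alpha_family = 0.05,
                      n_comparisons = length(exposures),
                      mvmr_alpha = alpha_family / n_comparisons,
                      sens_alpha = 0.05, n_boot = 500, n_sim = 1000, seed = 1,
                      palindrome_band = c(0.42, 0.58)) {
  if (is.data.frame(outcomes)) outcomes <- list(y = outcomes)
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  threshold <- bonferroni_threshold(alpha_family, n_comparisons)
  log <- character(0)
  uni_rows <- list()
  rep_rows <- list()
  mvmr_rows <- list()
  med_rows <- list()

  for (oc in names(outcomes)) {
    survivors <- character(0)
    for (ex in names(exposures)) {
      sc <- screen_pair(exposures[[ex]], outcomes[[oc]], cfg, ld_r2, seed,
                        n_boot, n_sim, sens_alpha, palindrome_band)
      if (is.null(sc)) {
        log <- c(log, sprintf("pair %s~%s skipped: fewer than 3 usable instruments", ex, oc))
        next
      }
      uni_rows[[paste(ex, oc)]] <- dplyr::mutate(sc$methods, exposure = ex, outcome = oc,
                                                 .before = 1)
      dec <- tidy(sc$decision)
      sg <- glance(sc$sensitivity)
      rep_rows[[paste(ex, oc)]] <- dplyr::mutate(
        dplyr::bind_cols(dec, sg),
        exposure = ex, outcome = oc,
        significant = dec$pvalue < threshold, .before = 1
      )
      if (dec$pvalue < threshold) survivors <- c(survivors, ex)
    }

    if (length(survivors) == 0) {
      log <- c(log, sprintf("outcome %s: zero univariable survivors; multivariable and mediation stages skipped", oc))
      next
    }

    surv_panels <- exposures[survivors]
    snps <- intersect(pool_instruments(unname(surv_panels), cfg, ld_r2),
                      outcomes[[oc]]$snp)
    ref <- surv_panels[[1]]
    others <- c(surv_panels[-1], setNames(outcomes[oc], "y"))
    h <- harmonize(ref[match(intersect(snps, ref$snp), ref$snp), ], others,
                   palindrome_band)
    labels <- c("x", names(surv_panels)[-1])
    mv <- mr_mvmr(h, exposures = labels)
    mv$estimates$exposure <- survivors
    cls <- classify_independence(survivors, mv, mvmr_alpha)
    mvmr_rows[[oc]] <- dplyr::mutate(
      dplyr::left_join(mv$estimates, cls[, c("exposure", "class")], by = "exposure"),
      outcome = oc, n_snp = mv$n_snp, .before = 1
    )

    mediated <- cls$exposure[cls$class == "mediated"]
    if (length(mediated) == 0) {
      log <- c(log, sprintf("outcome %s: all survivors independent; mediation stage skipped", oc))
      next
    }
    for (ex in mediated) {
      meds <- surv_panels[setdiff(survivors, ex)]
      if (length(meds) == 0) {
        log <- c(log, sprintf("outcome %s: no candidate mediators for %s", oc, ex))
        next
      }
      chains <- c(
        purrr::imap(meds, function(m, id) build_chain(exposures[[ex]], meds[id], outcomes[[oc]],
                                                      cfg, ld_r2, palindrome_band)),
        list(all = build_chain(exposures[[ex]], meds, outcomes[[oc]],
                               cfg, ld_r2, palindrome_band))
      )
      med_rows[[paste(ex, oc)]] <- purrr::imap_dfr(chains, function(ch, id) {
        pm <- proportion_mediated(ch)
        dplyr::mutate(tidy(pm), outcome = oc, exposure = ex,
                      mediator = if (id == "all") "all" else id,
                      beta3 = ch$beta3, se3 = ch$se3,
                      or_adjusted = exp(ch$beta3),
                      or_adj_low = exp(ch$beta3 - 1.96 * ch$se3),
                      or_adj_high = exp(ch$beta3 + 1.96 * ch$se3),
                      .before = 1)
      })
    }
  }

  structure(
    list(
      univariable = dplyr::bind_rows(uni_rows),
      reported = dplyr::bind_rows(rep_rows),
      mvmr = dplyr::bind_rows(mvmr_rows),
      mediation = dplyr::bind_rows(med_rows),
      threshold = threshold,
      log = log,
      seed = seed
    ),
    class = "mr_study"
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("<mr_study> %d screened pairs (threshold %.3g), %d multivariable rows, %d mediation rows\n",
              nrow(x$reported), x$threshold, nrow(x$mvmr), nrow(x$mediation)))
  if (length(x$log) > 0) cat(paste0("  note: ", x$log, "\n"), sep = "")
  invisible(x)
}

#' @export
tidy.mr_study <- function(x, ...) x$reported

#' @export
glance.mr_study <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$reported),
    n_significant = sum(x$reported$significant),
    n_independent = sum(x$mvmr$class == "independent"),
    n_mediated = sum(x$mvmr$class == "mediated"),
    threshold = x$threshold,
    seed = x$seed
  )
}

#' Write the study report tables to a directory
#'
#' Writes `univariable.tsv`, `reported.tsv`, `mvmr.tsv`, `mediation.tsv`
#' and `decisions.log` under `dir`.
#'
#' @param study An `mr_study` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$univariable, file.path(dir, "univariable.tsv"), progress = FALSE)
  readr::write_tsv(study$reported, file.path(dir, "reported.tsv"), progress = FALSE)
  readr::write_tsv(study$mvmr, file.path(dir, "mvmr.tsv"), progress = FALSE)
  readr::write_tsv(study$mediation, file.path(dir, "mediation.tsv"), progress = FALSE)
  writeLines(study$log, file.path(dir, "decisions.log"))
  invisible(dir)
}
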
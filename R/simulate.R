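#' Configuration for a synthetic GWAS summary-statistic study
#'
#' Describes a causal diagram over traits (one or more exposures, optional
#' mediators, one outcome) and the per-trait GWAS that would have been run
#' on it. Instrumented traits each get their own block of instruments with
#' per-SNP effects drawn at random; every trait's panel reports all SNPs,
#' with effects propagated along the diagram's directed edges, so that
#' downstream panels carry the induced associations real summary statistics
#' would show. Standard errors are sample-size driven:
#' `se = 1 / sqrt(2 * N * eaf * (1 - eaf))` (for binary traits, on the
#' log-odds scale).
#'
#' @param n_snp Named integer vector: instruments simulated per instrumented
#'   trait (e.g. `c(x = 150)`), emulating instrument counts in the tens to
#'   hundreds per risk factor.
#' @param true_effects Named numeric vector of directed edges,
#'   `c("x->y" = 0.3)`; effects on the outcome are log odds ratios.
#' @param sample_sizes Named per-trait GWAS sizes. Traits not named default
#'   to `4e5` (biobank-scale); a binary outcome panel is typically much
#'   smaller.
#' @param n_cases,n_controls Case/control bookkeeping for the binary outcome
#'   trait; their sum overrides the outcome's entry in `sample_sizes` when
#'   it is absent.
#' @param outcome Name of the outcome trait (default `"y"`).
#' @param eaf_range Effect-allele frequencies are drawn uniformly on this
#'   interval.
#' @param gamma_range Instrument effect magnitudes are drawn uniformly on
#'   this interval with random sign; the default keeps instruments
#'   genome-wide significant at biobank sample sizes without being
#'   unrealistically strong.
#' @param invalid_fraction Share of `invalid_trait`'s instruments given a
#'   direct (pleiotropic) effect on the outcome.
#' @param pleiotropy_mode `"balanced"` (pleiotropic effects symmetric about
#'   zero) or `"directional"` (shifted mean, violating the zero-average
#'   assumption). Pleiotropic effects are oriented relative to the
#'   exposure-increasing allele.
#' @param pleiotropy_scale Scale of the pleiotropic effects: the SD in
#'   balanced mode, the mean (with SD half of it) in directional mode, on
#'   the outcome log-odds scale.
#' @param invalid_trait Trait whose instruments may be invalid; defaults to
#'   the first instrumented trait.
#' @param label_swap_prob Probability that a non-reference panel reports a
#'   SNP with swapped allele labels (beta and frequency flipped
#'   accordingly), exercising harmonization.
#' @param seed Mandatory seed; panels are bit-reproducible given
#'   (config, seed).
#' @return A list of class `dag_config`.
#' @export
dag_config <- function(n_snp = c(x = 150),
                       true_effects = c("x->y" = 0.3),
                       sample_sizes = NULL,
                       n_cases = 11348, n_controls = 15861,
                       outcome = "y",
                       eaf_range = c(0.05, 0.95),
                       gamma_range = c(0.02, 0.1),
                       invalid_fraction = 0,
                       pleiotropy_mode = c("balanced", "directional"),
                       pleiotropy_scale = 0.05,
                       invalid_trait = names(n_snp)[1],
                       label_swap_prob = 0.3,
                       seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) abort("seed is mandatory")
  if (invalid_fraction < 0 || invalid_fraction > 1) abort("invalid_fraction must lie in [0, 1]")
  edges <- parse_edges(true_effects)
  traits <- unique(c(names(n_snp), edges$from, edges$to, outcome))
  sizes <- setNames(rep(4e5, length(traits)), traits)
  if (outcome %in% traits) sizes[outcome] <- n_cases + n_controls
  if (!is.null(sample_sizes)) sizes[names(sample_sizes)] <- sample_sizes
  if (any(sizes <= 0)) abort("sample sizes must be positive")
  structure(
    list(n_snp = n_snp, edges = edges, traits = traits, outcome = outcome,
         sample_sizes = sizes, n_cases = n_cases, n_controls = n_controls,
         eaf_range = eaf_range, gamma_range = gamma_range,
         invalid_fraction = invalid_fraction, pleiotropy_mode = pleiotropy_mode,
         pleiotropy_scale = pleiotropy_scale, invalid_trait = invalid_trait,
         label_swap_prob = label_swap_prob, seed = seed),
    class = "dag_config"
  )
}

parse_edges <- function(true_effects) {
  if (length(true_effects) == 0) {
    return(tibble::tibble(from = character(), to = character(), effect = numeric()))
  }
  parts <- strsplit(names(true_effects), "->", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) abort("edges must be named 'from->to'")
  tibble::tibble(
    from = trimws(vapply(parts, `[[`, "", 1)),
    to = trimws(vapply(parts, `[[`, "", 2)),
    effect = unname(true_effects)
  )
}

topo_order <- function(traits, edges) {
  order <- character(0)
  remaining <- traits
  while (length(remaining) > 0) {
    free <- remaining[!remaining %in% edges$to[edges$from %in% remaining]]
    if (length(free) == 0) abort("causal diagram contains a cycle")
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

ALLELE_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("A", "T"), c("C", "A"), c("C", "G"), c("C", "T"),
  c("G", "A"), c("G", "C"), c("G", "T"), c("T", "A"), c("T", "C"), c("T", "G")
)

#' Simulate GWAS summary-statistic panels from a causal diagram
#'
#' Draws, for every instrumented trait, a block of instruments with true
#' per-allele effects; propagates total genetic effects to downstream traits
#' along the configured edges; optionally gives a fraction of one trait's
#' instruments a direct pleiotropic effect on the outcome; and adds
#' independent sampling noise per panel (no sample overlap between panels).
#' Every simulated quantity is returned in the truth record so planted
#' effects can be compared with estimates.
#'
#' @param cfg A [dag_config()].
#' @return A list with `panels` (named list of validated panel tibbles, one
#'   per trait) and `truth` (list: `snp` tibble with each SNP's owner trait,
#'   true effect `gamma`, pleiotropic effect `alpha`, `eaf`; `total_effects`
#'   matrix of SNP-by-trait true associations; `edges`; `config`).
#' @export
simulate_panels <- function(cfg) {
  stopifnot(inherits(cfg, "dag_config"))
  withr::with_seed(cfg$seed, {
    owners <- rep(names(cfg$n_snp), cfg$n_snp)
    n_total <- length(owners)
    snp_ids <- sprintf("rs%06d", seq_len(n_total))
    eaf <- runif(n_total, cfg$eaf_range[1], cfg$eaf_range[2])
    gamma <- runif(n_total, cfg$gamma_range[1], cfg$gamma_range[2]) *
      sample(c(-1, 1), n_total, replace = TRUE)
    pair_idx <- sample.int(nrow(ALLELE_PAIRS), n_total, replace = TRUE)
    ea <- ALLELE_PAIRS[pair_idx, 1]
    oa <- ALLELE_PAIRS[pair_idx, 2]

    # direct per-SNP genetic effects: each SNP affects only its owner trait
    order <- topo_order(cfg$traits, cfg$edges)
    total <- matrix(0, n_total, length(order), dimnames = list(snp_ids, order))
    for (tr in order) {
      tot <- ifelse(owners == tr, gamma, 0)
      parents <- cfg$edges[cfg$edges$to == tr, ]
      if (nrow(parents) > 0) {
        for (i in seq_len(nrow(parents))) {
          tot <- tot + parents$effect[i] * total[, parents$from[i]]
        }
      }
      total[, tr] <- tot
    }

    alpha <- rep(0, n_total)
    own <- which(owners == cfg$invalid_trait)
    n_invalid <- round(cfg$invalid_fraction * length(own))
    if (n_invalid > 0 && cfg$outcome %in% order) {
      invalid <- sample(own, n_invalid)
      alpha[invalid] <- if (cfg$pleiotropy_mode == "balanced") {
        rnorm(n_invalid, 0, cfg$pleiotropy_scale)
      } else {
        rnorm(n_invalid, cfg$pleiotropy_scale, cfg$pleiotropy_scale / 2)
      }
      # pleiotropy acts on the exposure-increasing allele: orient by the sign
      # of the instrument's own effect so a directional mean cannot cancel
      total[, cfg$outcome] <- total[, cfg$outcome] + alpha * sign(gamma)
    }

    panels <- list()
    for (tr in order) {
      n_tr <- cfg$sample_sizes[[tr]]
      se <- 1 / sqrt(2 * n_tr * eaf * (1 - eaf))
      beta <- unname(total[, tr]) + rnorm(n_total, 0, se)
      ea_t <- ea; oa_t <- oa; eaf_t <- eaf; beta_t <- beta
      if (tr != order[1] && cfg$label_swap_prob > 0) {
        swap <- runif(n_total) < cfg$label_swap_prob
        ea_t[swap] <- oa[swap]
        oa_t[swap] <- ea[swap]
        beta_t[swap] <- -beta[swap]
        eaf_t[swap] <- 1 - eaf[swap]
      }
      panels[[tr]] <- summary_stats(
        tibble::tibble(
          snp = snp_ids, effect_allele = ea_t, other_allele = oa_t,
          eaf = eaf_t, beta = beta_t, se = se,
          pval = p_from_z(beta_t, se), n = n_tr
        ),
        phenotype_id = tr,
        trait_type = if (tr == cfg$outcome) "binary" else "continuous"
      )
    }

    list(
      panels = panels,
      truth = list(
        snp = tibble::tibble(snp = snp_ids, owner = owners, gamma = gamma,
                             alpha = alpha, eaf = eaf),
        total_effects = total,
        edges = cfg$edges,
        config = cfg
      )
    )
  })
}

#' Block-diagonal LD (r-squared) matrix
#'
#' Consecutive SNPs are grouped into blocks of `block_size`; pairs within a
#' block have r-squared `within_r2`, pairs across blocks 0, and the diagonal
#' is 1. A trailing partial block is allowed.
#'
#' @param snp_ids SNP identifiers (row/column names), or an integer count
#'   (ids are then `rs000001`, ... matching [simulate_panels()]).
#' @param block_size SNPs per block; `1` gives the identity matrix.
#' @param within_r2 Within-block r-squared, in \[0, 1).
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
simulate_ld_blocks <- function(snp_ids, block_size, within_r2) {
  if (within_r2 < 0 || within_r2 >= 1) abort("within_r2 must lie in [0, 1)")
  if (is.numeric(snp_ids) && length(snp_ids) == 1) {
    snp_ids <- sprintf("rs%06d", seq_len(snp_ids))
  }
  n <- length(snp_ids)
  block <- (seq_len(n) - 1) %/% block_size
  m <- outer(block, block, `==`) * within_r2
  diag(m) <- 1
  dimnames(m) <- list(snp_ids, snp_ids)
  m
}

#' The documented four-exposure study scenario
#'
#' The default synthetic scenario exercised by the study driver: four risk
#' factors and one binary outcome, where exposures `a` and `b` act on the
#' outcome directly (log-OR 0.5 and -0.5) while `c` and `d` have no direct
#' path and act only through `a` and `b` respectively (edge effects 0.4).
#' Every trait contributes 150 instruments; exposure GWAS are
#' biobank-scale and the outcome panel has 11,348 cases and 15,861
#' controls. Univariable MR should find all four factors associated with
#' the outcome; multivariable MR should classify `a`, `b` as independent
#' and `c`, `d` as mediated.
#'
#' @param seed Simulation seed.
#' @param n_snp_per_trait Instruments per trait (default 150).
#' @return As [simulate_panels()]: a list with `panels` and `truth`.
#' @export
simulate_study_scenario <- function(seed, n_snp_per_trait = 150) {
  cfg <- dag_config(
    n_snp = setNames(rep(n_snp_per_trait, 4), c("a", "b", "c", "d")),
    true_effects = c("c->a" = 0.4, "d->b" = 0.4, "a->y" = 0.5, "b->y" = -0.5),
    seed = seed
  )
  simulate_panels(cfg)
}
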
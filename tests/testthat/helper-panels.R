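# quick builders for small fixtures used across test files

make_panel <- function(snp, beta, se, eaf = 0.3, pval = NULL,
                       ea = "A", oa = "G", n = 1e5, ...) {
  k <- length(snp)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  summary_stats(tibble::tibble(
    snp = snp,
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = beta, se = se,
    pval = pval, n = rep_len(n, k)
  ), ...)
}

# harmonized-set shaped tibble built directly from effect vectors
make_h <- function(bx, by, sx = rep(0.001, length(bx)), sy = rep(0.01, length(bx)),
                   snp = sprintf("rs%03d", seq_along(bx))) {
  tibble::tibble(snp = snp, eaf = 0.3, beta_x = bx, se_x = sx,
                 beta_y = by, se_y = sy)
}

# one simulated exposure->outcome harmonized set under the default conditions
sim_h <- function(seed, effect = 0.3, n_snp = 150, ...) {
  cfg <- dag_config(n_snp = c(x = n_snp), true_effects = c("x->y" = effect),
                    seed = seed, ...)
  sim <- simulate_panels(cfg)
  iv <- select_genomewide(sim$panels$x)
  harmonize(iv, sim$panels$y)
}
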
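test_that("proportion mediated follows the effect-decomposition identity", {
  # fully mediated: no direct effect left after adjustment
  ch <- mediation_chain("x", "m", beta1 = 0.4, se1 = 0.02,
                        beta2 = 0.5, se2 = 0.03, beta3 = 0, se3 = 0.01)
  expect_equal(proportion_mediated(ch)$proportion, 100)

  # direct and indirect equal: half mediated
  ch <- mediation_chain("x", "m", beta1 = 0.4, se1 = 0.02,
                        beta2 = 0.5, se2 = 0.03, beta3 = 0.2, se3 = 0.01)
  res <- proportion_mediated(ch)
  expect_equal(res$proportion, 50)
  expect_equal(res$indirect, 0.2)
  expect_equal(res$total, 0.4)
  expect_equal(res$proportion, 100 * res$indirect / res$total)

  # multi-mediator indirect path sums over mediators
  ch3 <- mediation_chain("x", c("m1", "m2", "m3"),
                         beta1 = c(0.3, 0.2, 0.1), se1 = rep(0.02, 3),
                         beta2 = c(0.5, -0.2, 0.4), se2 = rep(0.03, 3),
                         beta3 = 0.11, se3 = 0.02)
  res3 <- proportion_mediated(ch3)
  expect_equal(res3$indirect, 0.3 * 0.5 + 0.2 * -0.2 + 0.1 * 0.4)
  expect_equal(res3$proportion, 100 * res3$indirect / (0.11 + res3$indirect))

  ch0 <- mediation_chain("x", "m", beta1 = 0.4, se1 = 0.02,
                         beta2 = 0.5, se2 = 0.03, beta3 = -0.2, se3 = 0.01)
  expect_error(proportion_mediated(ch0), "undefined")
  expect_error(mediation_chain("x", "m", 0.4, 0, 0.5, 0.03, 0.2, 0.01), "SEs")
})

test_that("delta-method SE agrees with Monte-Carlo error propagation", {
  ch <- mediation_chain("x", c("m1", "m2"),
                        beta1 = c(0.35, 0.2), se1 = c(0.03, 0.025),
                        beta2 = c(0.4, 0.3), se2 = c(0.04, 0.05),
                        beta3 = 0.25, se3 = 0.04)
  delta <- proportion_mediated(ch, method = "delta")
  mc <- proportion_mediated(ch, method = "mc", n_draws = 1e5, seed = 42)
  expect_equal(delta$proportion, mc$proportion)
  expect_equal(delta$se, mc$se, tolerance = 0.05)
  # interval is symmetric about the point estimate
  expect_equal(delta$ci_high - delta$proportion, delta$proportion - delta$ci_low)
})

test_that("the proportion is invariant to rescaling a mediator's units", {
  ch <- mediation_chain("x", "m", beta1 = 0.4, se1 = 0.02,
                        beta2 = 0.5, se2 = 0.03, beta3 = 0.2, se3 = 0.01)
  c_scale <- 2.7
  ch2 <- mediation_chain("x", "m", beta1 = 0.4 * c_scale, se1 = 0.02 * c_scale,
                         beta2 = 0.5 / c_scale, se2 = 0.03 / c_scale,
                         beta3 = 0.2, se3 = 0.01)
  expect_equal(proportion_mediated(ch2)$proportion,
               proportion_mediated(ch)$proportion)
})

test_that("negative proportions and out-of-range intervals are never truncated", {
  ch <- mediation_chain("x", "m", beta1 = 0.1, se1 = 0.05,
                        beta2 = -0.3, se2 = 0.2, beta3 = 0.5, se3 = 0.1)
  res <- proportion_mediated(ch)
  expect_lt(res$proportion, 0)
  expect_lt(res$ci_low, res$proportion)
})

test_that("a fully mediated diagram yields E near 100% and null direct effect", {
  cfg <- dag_config(n_snp = c(x = 150, m = 150),
                    true_effects = c("x->m" = 0.4, "m->y" = 0.75),
                    seed = 505)
  sim <- simulate_panels(cfg)
  ch <- build_chain(sim$panels$x, sim$panels["m"], sim$panels$y)
  # adjusted direct effect compatible with zero
  expect_lt(abs(ch$beta3), 3 * ch$se3)
  res <- proportion_mediated(ch)
  expect_gt(res$proportion, 85)
  expect_lt(res$proportion, 115)
})

test_that("a direct-only diagram yields E near 0", {
  cfg <- dag_config(n_snp = c(x = 150, m = 150),
                    true_effects = c("x->y" = 0.5),
                    seed = 506)
  sim <- simulate_panels(cfg)
  ch <- build_chain(sim$panels$x, sim$panels["m"], sim$panels$y)
  res <- proportion_mediated(ch)
  expect_lt(abs(res$proportion), 3 * res$se)
  expect_lt(abs(res$proportion), 15)
})

test_that("three-mediator chains recover planted per-path contributions", {
  # x -> m1,m2,m3 -> y plus a direct path; per-mediator shares of the total
  cfg <- dag_config(
    n_snp = c(x = 150, m1 = 150, m2 = 150, m3 = 150),
    true_effects = c("x->m1" = 0.4, "x->m2" = 0.3, "x->m3" = 0.2,
                     "m1->y" = 0.25, "m2->y" = 0.5, "m3->y" = 0.25,
                     "x->y" = 0.2),
    seed = 507
  )
  total <- 0.4 * 0.25 + 0.3 * 0.5 + 0.2 * 0.25 + 0.2
  sim <- simulate_panels(cfg)
  meds <- sim$panels[c("m1", "m2", "m3")]
  joint <- build_chain(sim$panels$x, meds, sim$panels$y)
  res <- proportion_mediated(joint)
  truth_joint <- 100 * (0.4 * 0.25 + 0.3 * 0.5 + 0.2 * 0.25) / total
  expect_lt(abs(res$proportion - truth_joint), 3 * res$se)
  for (m in names(meds)) {
    ch <- build_chain(sim$panels$x, meds[m], sim$panels$y)
    e1 <- cfg$edges$effect[cfg$edges$from == "x" & cfg$edges$to == m]
    e2 <- cfg$edges$effect[cfg$edges$from == m & cfg$edges$to == "y"]
    truth_m <- 100 * e1 * e2 / total
    res_m <- proportion_mediated(ch)
    expect_lt(abs(res_m$proportion - truth_m), 3 * res_m$se)
  }
})
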
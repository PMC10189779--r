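test_that("Wald ratio and its delta-method SEs are correct", {
  expect_equal(wald_ratio(1, 0.01, 0.42, 0.05)$beta, 0.42)
  est <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "nonzero")

  # second-order SE against a Monte-Carlo propagation oracle
  bx <- 0.5; sx <- 0.04; by <- 0.3; sy <- 0.03
  est2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  set.seed(404)
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_equal(est2$se, sd(draws), tolerance = 0.02)
  expect_gt(est2$se, wald_ratio(bx, sx, by, sy)$se)
})

test_that("IVW reduces correctly and matches a WLS oracle to 10 digits", {
  # all per-SNP ratios equal -> that ratio with zero heterogeneity
  h <- make_h(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.10, 0.20))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$q_stat, 0)

  h1 <- make_h(bx = 0.1, by = 0.07, sy = 0.02)
  expect_equal(mr_ivw(h1)$beta, wald_ratio(0.1, 0.001, 0.07, 0.02)$beta)
  expect_equal(mr_ivw(h1)$se, wald_ratio(0.1, 0.001, 0.07, 0.02)$se)

  set.seed(21)
  h5 <- make_h(bx = runif(5, 0.05, 0.2), by = rnorm(5, 0.1, 0.02),
               sy = runif(5, 0.005, 0.02))
  fit <- lm(beta_y ~ 0 + beta_x, data = h5, weights = 1 / h5$se_y^2)
  expect_equal(mr_ivw(h5, model = "fixed")$beta, unname(coef(fit)),
               tolerance = 1e-10)
  # fixed-model beta is the weighted mean of ratios with weights bx^2/sy^2
  expect_equal(mr_ivw(h5, model = "fixed")$beta,
               weighted.mean(h5$beta_y / h5$beta_x, h5$beta_x^2 / h5$se_y^2),
               tolerance = 1e-12)
  # random-model SE inflates the fixed SE by max(1, sqrt(Q/(k-1)))
  q <- mr_ivw(h5)$q_stat
  expect_equal(mr_ivw(h5)$se,
               mr_ivw(h5, model = "fixed")$se * max(1, sqrt(q / 4)))
  expect_error(mr_ivw(make_h(bx = c(0, 0), by = c(0.1, 0.2))), "zero")
})

test_that("Egger matches closed-form weighted normal equations", {
  h3 <- make_h(bx = c(0.05, 0.12, 0.2), by = c(0.04, 0.07, 0.12),
               sy = c(0.01, 0.02, 0.015))
  eg <- mr_egger(h3)
  w <- 1 / h3$se_y^2
  X <- cbind(1, h3$beta_x)
  cf <- solve(t(X) %*% (w * X), t(X) %*% (w * h3$beta_y))
  expect_equal(eg$intercept$beta, cf[1], tolerance = 1e-10)
  expect_equal(eg$slope$beta, cf[2], tolerance = 1e-10)
  fit <- lm(beta_y ~ beta_x, data = h3, weights = w)
  expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)

  # adding a constant to every outcome effect shifts the intercept only
  h3b <- h3
  h3b$beta_y <- h3$beta_y + 0.05
  egb <- mr_egger(h3b)
  expect_equal(egb$slope$beta, eg$slope$beta)
  expect_equal(egb$intercept$beta, eg$intercept$beta + 0.05)
  expect_error(mr_egger(make_h(bx = c(0.1, 0.2), by = c(0.1, 0.2))), "3 SNPs")
})

test_that("Egger intercept CI covers zero at close to nominal rate without pleiotropy", {
  covered <- vapply(1:400, function(i) {
    h <- sim_h(seed = 5000 + i, n_snp = 60)
    eg <- mr_egger(h)
    eg$intercept$ci_low <= 0 && 0 <= eg$intercept$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("weighted median handles degenerate and textbook cases", {
  h <- make_h(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.10, 0.20))
  est <- mr_weighted_median(h, n_boot = 200, seed = 3)
  expect_equal(est$beta, 0.5)
  expect_lt(est$se, 0.05)

  # equal weights, ratios {0.2, 0.5, 0.9} -> plain median 0.5
  h3 <- make_h(bx = rep(1, 3), by = c(0.2, 0.5, 0.9), sy = rep(0.1, 3))
  expect_equal(mr_weighted_median(h3, n_boot = 100, seed = 1)$beta, 0.5)
  # deterministic given the seed
  expect_equal(mr_weighted_median(h3, n_boot = 100, seed = 1)$se,
               mr_weighted_median(h3, n_boot = 100, seed = 1)$se)
})

test_that("weighted median resists 40% invalid instruments where IVW does not", {
  # breakdown property: below 50% contaminated weight, the weighted median
  # stays consistent when per-ratio noise is small against the contamination
  set.seed(77)
  k <- 50
  bx <- runif(k, 0.05, 0.15) * sample(c(-1, 1), k, TRUE)
  sy <- rep(0.0005, k)
  invalid <- seq_len(k) <= 20
  by <- 0.3 * bx + rnorm(k, 0, sy) + ifelse(invalid, 0.4 * bx, 0)
  h <- make_h(bx = bx, by = by, sy = sy)
  wm <- mr_weighted_median(h, n_boot = 300, seed = 7)
  ivw <- mr_ivw(h)
  expect_lt(abs(wm$beta - 0.3) / wm$se, 3)
  expect_gt(abs(ivw$beta - 0.3) / ivw$se, 3)
  expect_gt(abs(ivw$beta - 0.3), 3 * abs(wm$beta - 0.3))
})

test_that("contamination mixture is consistent with IVW on clean data", {
  h <- sim_h(seed = 123)
  cm <- mr_conmix(h)
  ivw <- mr_ivw(h)
  joint_se <- sqrt(cm$estimate$se^2 + ivw$se^2)
  expect_lt(abs(cm$estimate$beta - ivw$beta), joint_se)
  # profile maximum is attained at the reported estimate
  expect_equal(cm$profile$theta[which.max(cm$profile$loglik)], cm$estimate$beta)
  expect_true(all(cm$valid_snps %in% h$snp))

  h1 <- make_h(bx = 0.1, by = 0.05, sy = 0.01)
  cm1 <- mr_conmix(h1)
  expect_equal(cm1$estimate$beta, 0.5)
})

test_that("contamination mixture recovers planted invalid instruments", {
  set.seed(88)
  k <- 100
  bx <- runif(k, 0.05, 0.15) * sample(c(-1, 1), k, TRUE)
  sy <- runif(k, 0.002, 0.005)
  invalid <- seq_len(k) <= 30
  by <- 0.3 * bx + rnorm(k, 0, sy) + ifelse(invalid, 0.5 * bx, 0)
  h <- make_h(bx = bx, by = by, sy = sy)
  cm <- mr_conmix(h)
  called_invalid <- !h$snp %in% cm$valid_snps
  accuracy <- mean(called_invalid == invalid)
  expect_gte(accuracy, 0.8)
  expect_error(mr_conmix(h, psi = -1), "psi")
})

test_that("estimators are scale- and sign-equivariant", {
  h <- sim_h(seed = 55, n_snp = 40)
  ests <- function(h) c(
    ivw = mr_ivw(h)$beta,
    egger = mr_egger(h)$slope$beta,
    wm = mr_weighted_median(h, n_boot = 50, seed = 2)$beta,
    cm = mr_conmix(h)$estimate$beta
  )
  base <- ests(h)
  hs <- h; hs$beta_x <- 3 * h$beta_x; hs$se_x <- 3 * h$se_x
  expect_equal(ests(hs), base / 3, tolerance = 1e-8)
  hn <- h; hn$beta_y <- -h$beta_y
  expect_equal(ests(hn), -base, tolerance = 1e-8)
})

test_that("IVW interval covers a null effect at close to nominal rate", {
  covered <- vapply(1:300, function(i) {
    h <- sim_h(seed = 20000 + i, effect = 0, n_snp = 60)
    est <- mr_ivw(h)
    est$ci_low <= 0 && 0 <= est$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})

test_that("the estimator battery stacks one tidy row per method", {
  h <- sim_h(seed = 9, n_snp = 30)
  tbl <- mr_univariable(h, seed = 4, n_boot = 100)
  expect_setequal(tbl$method, c("ivw_random", "egger_slope", "egger_intercept",
                                "weighted_median", "conmix"))
  expect_true(all(tbl$ci_low <= tbl$beta & tbl$beta <= tbl$ci_high))
  expect_equal(tbl$or, exp(tbl$beta))
})
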
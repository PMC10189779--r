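test_that("a well-formed TSV reads into a panel and unparseable rows are dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.3\t0.1\t0.02\t5.7e-7\t10000",
    "rs2\tC\tT\t0.5\t-0.05\t0.01\t5.7e-7\t10000",
    "rs3\tG\tA\t0.2\t0.02\t0.02\t0.32\t10000"
  ), path)
  panel <- read_summary_stats(path)
  expect_equal(nrow(panel), 3)
  expect_equal(attr(panel, "n_dropped"), 0)
  expect_equal(panel$beta, c(0.1, -0.05, 0.02))

  writeLines(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.3\t0.1\t0.02\t5.7e-7\t10000",
    "rs2\tC\tT\t0.5\t-0.05\tNA\t5.7e-7\t10000"
  ), path)
  panel <- read_summary_stats(path)
  expect_equal(nrow(panel), 1)
  expect_equal(attr(panel, "n_dropped"), 1)
})

test_that("missing mandatory columns are reported by name; column maps apply", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\teaf\tbeta\tpval\tn",
               "rs1\tA\tG\t0.3\t0.1\t5.7e-7\t10000"), path)
  expect_error(read_summary_stats(path), "se")

  writeLines(c("rsid\tA1\tA2\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.3\t0.1\t0.02\t5.7e-7\t10000"), path)
  panel <- read_summary_stats(path, column_map = c(
    snp = "rsid", effect_allele = "A1", other_allele = "A2", eaf = "freq",
    beta = "b", se = "stderr", pval = "p", n = "N"
  ))
  expect_equal(panel$snp, "rs1")
  expect_equal(panel$se, 0.02)
})

test_that("write/read round-trip preserves every field at full precision", {
  set.seed(42)
  panel <- make_panel(sprintf("rs%d", 1:8), beta = rnorm(8) / 10,
                      se = runif(8, 0.001, 0.02), eaf = runif(8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(panel, path)
  back <- read_summary_stats(path)
  attr(back, "n_dropped") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(panel), tolerance = 0)
})

test_that("panel invariants are enforced and inconsistent p-values flagged", {
  expect_error(make_panel("rs1", 0.1, 0.02, ea = "A", oa = "A"), "allele")
  expect_error(make_panel("rs1", 0.1, -0.02), "se")
  expect_error(make_panel(c("rs1", "rs1"), c(0.1, 0.2), c(0.02, 0.02)), "duplicate")
  expect_error(make_panel("rs1", 0.1, 0.02, eaf = 1.2), "eaf")
  # stated p far from the normal-test p implied by beta/se -> flagged
  p_ok <- make_panel("rs1", 0.1, 0.02)
  expect_false(p_ok$p_flag)
  p_bad <- make_panel("rs1", 0.1, 0.02, pval = 0.5)
  expect_true(p_bad$p_flag)
})

test_that("harmonization keeps, flips, and drops per the allele rules", {
  exposure <- make_panel("rs1", 0.1, 0.01, eaf = 0.25, ea = "A", oa = "G")
  same <- make_panel("rs1", 0.05, 0.01, eaf = 0.25, ea = "A", oa = "G")
  h <- harmonize(exposure, same)
  expect_equal(h$beta_y, 0.05)
  expect_equal(harmonization_log(h)$action, "kept")

  swapped <- make_panel("rs1", 0.05, 0.01, eaf = 0.3, ea = "G", oa = "A")
  h <- harmonize(exposure, swapped)
  expect_equal(h$beta_y, -0.05)
  expect_equal(harmonization_log(h)$action, "flipped")

  # strand-complement pair (T/C complements to A/G): kept without flip
  strand <- make_panel("rs1", 0.05, 0.01, eaf = 0.25, ea = "T", oa = "C")
  h <- harmonize(exposure, strand)
  expect_equal(h$beta_y, 0.05)

  mism <- make_panel("rs1", 0.05, 0.01, ea = "A", oa = "C")
  h <- harmonize(exposure, mism)
  expect_equal(nrow(h), 0)
  expect_equal(harmonization_log(h)$action, "dropped-mismatch")

  expect_error(harmonize(exposure, make_panel("rs9", 0.1, 0.01)), "shared")
})

test_that("palindromic SNPs follow the frequency band rule over a 10-SNP fixture", {
  eafs <- seq(0.05, 0.95, by = 0.1)
  exposure <- make_panel(sprintf("rs%02d", 1:10), beta = rep(0.1, 10),
                         se = rep(0.01, 10), ea = "A", oa = "T")
  exposure$eaf <- eafs
  outcome <- exposure
  outcome$beta <- rep(0.05, 10)
  h <- harmonize(exposure, outcome, palindrome_band = c(0.42, 0.58))
  # independent brute-force application of the band rule
  expected_drop <- eafs >= 0.42 & eafs <= 0.58
  expect_setequal(h$snp, exposure$snp[!expected_drop])
  log <- harmonization_log(h)
  expect_setequal(log$snp[log$action == "dropped-palindromic"],
                  exposure$snp[expected_drop])
  # same-side frequencies, so every retained palindromic SNP is kept unflipped
  expect_true(all(log$action[!expected_drop] == "kept"))

  # eaf exactly 0.50 inside the default band is dropped
  e1 <- make_panel("rs1", 0.1, 0.01, eaf = 0.5, ea = "A", oa = "T")
  expect_equal(nrow(harmonize(e1, e1)), 0)
})

test_that("harmonization is idempotent and label-flip invariant", {
  sim <- simulate_panels(dag_config(n_snp = c(x = 60), seed = 31))
  iv <- select_genomewide(sim$panels$x)
  h1 <- harmonize(iv, sim$panels$y)

  # feed the harmonized set back in as two already-aligned panels
  px <- make_panel(h1$snp, h1$beta_x, h1$se_x)
  px$eaf <- h1$eaf
  py <- make_panel(h1$snp, h1$beta_y, h1$se_y)
  py$eaf <- h1$eaf
  h2 <- harmonize(px, py)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_equal(h2$beta_y, h1$beta_y)

  # flipping both panels' allele labels leaves ratio estimates unchanged
  flip_panel <- function(p) {
    tmp <- p$effect_allele
    p$effect_allele <- p$other_allele
    p$other_allele <- tmp
    p$beta <- -p$beta
    p$eaf <- 1 - p$eaf
    p
  }
  h3 <- harmonize(flip_panel(px), flip_panel(py))
  expect_equal(h3$beta_y / h3$beta_x, h1$beta_y / h1$beta_x)
})
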
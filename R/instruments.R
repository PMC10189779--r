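#' Instrument-selection configuration
#'
#' Bundles the thresholds used to pick genetic instruments for an exposure:
#' genome-wide significance, minor-allele frequency, LD clumping, and the
#' minimum instrument strength.
#'
#' @param p_threshold Significance cutoff; records with `pval <
#'   p_threshold` survive (strict). Default `5e-8`, the conventional
#'   genome-wide level.
#' @param clump_r2 LD r-squared above which a SNP is removed in favour of a
#'   more significant index SNP. Default `0.001`.
#' @param clump_window_kb Window within which clumping applies when SNP
#'   positions are available; with a plain r-squared matrix all pairs are
#'   eligible. Default `10000`.
#' @param maf_min Minimum minor-allele frequency, `min(eaf, 1 - eaf)`.
#'   Default `0.01`.
#' @param f_min Minimum F statistic for an instrument set to be considered
#'   strong. Default `10`.
#'
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                              clump_window_kb = 10000, maf_min = 0.01,
                              f_min = 10) {
  stopifnot(p_threshold > 0, clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0, maf_min > 0, f_min > 0)
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, maf_min = maf_min, f_min = f_min),
    class = "instrument_config"
  )
}

#' Select genome-wide significant instruments
#'
#' Keeps records with `pval < p_threshold` (strict inequality) and minor
#' allele frequency `min(eaf, 1 - eaf) >= maf_min`. Records with missing
#' `eaf` pass the frequency filter (frequency only enters the variance
#' explained, not the association evidence).
#'
#' @param panel A panel tibble (see [summary_stats()]).
#' @param cfg An [instrument_config()].
#' @return The filtered panel; a warning (not an error) is raised when no
#'   record survives.
#' @export
select_genomewide <- function(panel, cfg = instrument_config()) {
  if (nrow(panel) == 0) abort("empty panel")
  maf <- pmin(panel$eaf, 1 - panel$eaf)
  keep <- panel$pval < cfg$p_threshold & (is.na(maf) | maf >= cfg$maf_min)
  out <- panel[keep, ]
  if (nrow(out) == 0) warn("no records survive the significance/MAF filter")
  out
}

#' Greedy LD clumping on a supplied r-squared matrix
#'
#' Repeatedly takes the unclaimed SNP with the smallest p-value as an index
#' SNP and removes every unclaimed SNP whose r-squared with it exceeds
#' `clump_r2`. Ties on p-value are broken lexicographically by SNP id for
#' determinism. Positions are not used: the supplied matrix defines which
#' pairs are in LD.
#'
#' @param panel A panel tibble.
#' @param ld_r2 Symmetric numeric matrix of pairwise r-squared values with
#'   SNP ids as dimnames; the diagonal must be 1. Must cover every SNP in
#'   `panel`.
#' @param cfg An [instrument_config()]; only `clump_r2` is used.
#' @return The panel restricted to index SNPs, in the order they were chosen.
#' @export
clump <- function(panel, ld_r2, cfg = instrument_config()) {
  missing <- setdiff(panel$snp, rownames(ld_r2))
  if (length(missing) > 0) {
    abort(paste0("SNP(s) absent from LD matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  ord <- order(panel$pval, panel$snp)
  remaining <- panel$snp[ord]
  pv <- setNames(panel$pval[ord], remaining)
  index <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    index <- c(index, idx)
    r2 <- ld_r2[idx, remaining]
    remaining <- remaining[!(r2 > cfg$clump_r2)]
    remaining <- setdiff(remaining, idx)
  }
  panel[match(index, panel$snp), ]
}

#' Variance in the phenotype explained by one SNP
#'
#' For an additive per-allele effect `beta` at effect-allele frequency
#' `eaf`, the proportion of phenotypic variance explained is
#' `2 * beta^2 * eaf * (1 - eaf) / sd^2`.
#'
#' @param beta Per-allele effect.
#' @param eaf Effect-allele frequency in \[0, 1\].
#' @param sd Phenotype standard deviation; defaults to 1 (standardized
#'   phenotype).
#' @return The proportion of variance explained (vectorised).
#' @export
r2_explained <- function(beta, eaf, sd = 1) {
  if (any(sd <= 0)) abort("sd must be > 0")
  if (any(!is.na(eaf) & (eaf < 0 | eaf > 1))) abort("eaf must lie in [0, 1]")
  2 * beta^2 * (1 - eaf) * eaf / sd^2
}

#' F statistic for instrument strength
#'
#' `((n - k - 1) / k) * (r2 / (1 - r2))` for an instrument set of `k` SNPs
#' jointly explaining a proportion `r2` of the exposure variance in a sample
#' of size `n`. Values above 10 conventionally indicate negligible
#' weak-instrument bias.
#'
#' @param total_r2 Proportion of variance explained, in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of SNPs.
#' @return The F statistic.
#' @export
f_statistic <- function(total_r2, n, k) {
  if (any(total_r2 >= 1) || any(total_r2 < 0)) abort("total_r2 must lie in [0, 1)")
  if (any(n <= k + 1)) abort("need n > k + 1")
  ((n - k - 1) / k) * (total_r2 / (1 - total_r2))
}

#' Instrument-strength report for a selected panel
#'
#' Computes per-SNP and aggregate variance explained and F statistics for a
#' set of instruments. SNPs with missing `eaf` are excluded from the
#' variance-explained sums. The aggregate F (over all k SNPs) drives the
#' strength gate; per-SNP F values (k = 1) are also reported because the
#' "strength greater than 10" convention is sometimes applied per variant.
#'
#' @param panel A selected instrument panel.
#' @param sd Phenotype standard deviation (default 1, standardized trait).
#' @param f_min Strength gate applied to the aggregate F.
#' @return A list of class `strength_report` with elements `per_snp` (tibble
#'   of `snp`, `r2`, `f`), `total_r2`, `f_stat`, `n`, `k` and `passes`.
#' @export
instrument_strength <- function(panel, sd = 1, f_min = 10) {
  usable <- !is.na(panel$eaf)
  per_r2 <- ifelse(usable, r2_explained(panel$beta, panel$eaf, sd), NA_real_)
  n <- round(median(panel$n))
  k <- sum(usable)
  total_r2 <- sum(per_r2[usable])
  f <- f_statistic(total_r2, n, k)
  per_f <- rep(NA_real_, nrow(panel))
  per_f[usable] <- f_statistic(pmin(per_r2[usable], 1 - 1e-12), panel$n[usable], 1)
  structure(
    list(
      per_snp = tibble::tibble(snp = panel$snp, r2 = per_r2, f = per_f),
      total_r2 = total_r2, f_stat = f, n = n, k = k,
      passes = f > f_min
    ),
    class = "strength_report"
  )
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf(
    "<strength_report> k = %d SNPs, N = %d: total R2 = %.4g, F = %.2f (%s)\n",
    x$k, x$n, x$total_r2, x$f_stat, if (x$passes) "strong" else "weak"
  ))
  invisible(x)
}

#' @export
tidy.strength_report <- function(x, ...) x$per_snp

#' @export
glance.strength_report <- function(x, ...) {
  tibble::tibble(total_r2 = x$total_r2, f_stat = x$f_stat,
                 n = x$n, k = x$k, passes = x$passes)
}

#' Read a pairwise LD matrix from TSV
#'
#' Accepts either a square matrix with a header row and a first column of
#' SNP ids, or a long-format triple (`snp_a`, `snp_b`, `r2`), which is
#' symmetrised with a unit diagonal.
#'
#' @param path Path to the TSV file.
#' @return A symmetric numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) == 3 && all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(raw$snp_a, raw$snp_b)] <- raw$r2
    m[cbind(raw$snp_b, raw$snp_a)] <- raw$r2
    diag(m) <- 1
    return(m)
  }
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}
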
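#' Validate a table of GWAS summary statistics
#'
#' A phenotype panel is a tibble with one row per SNP and columns
#' `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' Effects (`beta`) are per-allele additive effects on the phenotype; for
#' binary phenotypes they are log odds ratios. This constructor checks the
#' panel invariants (distinct alleles, positive SE, frequencies in \[0, 1\],
#' unique SNP ids) and flags records whose stated p-value is inconsistent
#' with a two-sided normal test of `beta / se`.
#'
#' @param x A data frame with the panel columns; `eaf` may be `NA`.
#' @param phenotype_id Optional label stored as an attribute.
#' @param trait_type `"continuous"` or `"binary"`; stored as an attribute.
#' @param p_consistency_factor Records are flagged (`p_flag == TRUE`) when the
#'   stated p-value and the one implied by `beta / se` differ by more than
#'   this multiplicative factor in either direction.
#'
#' @return A validated tibble with an added logical `p_flag` column.
#' @export
summary_stats <- function(x, phenotype_id = NULL, trait_type = c("continuous", "binary"),
                          p_consistency_factor = 2) {
  trait_type <- match.arg(trait_type)
  x <- tibble::as_tibble(x)
  needed <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  bad_allele <- !(x$effect_allele %in% names(DNA_COMPLEMENT)) |
    !(x$other_allele %in% names(DNA_COMPLEMENT)) |
    x$effect_allele == x$other_allele
  if (any(bad_allele)) {
    abort(paste0("invalid allele pair for SNP(s): ",
                 paste(head(x$snp[bad_allele], 5), collapse = ", ")))
  }
  if (anyDuplicated(x$snp)) abort("duplicate snp ids in panel")
  if (any(x$se <= 0)) abort("se must be > 0 for every record")
  if (any(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))) abort("eaf must lie in [0, 1]")
  if (any(x$pval <= 0 | x$pval > 1)) abort("pval must lie in (0, 1]")
  if (any(x$n <= 0)) abort("n must be positive")
  p_implied <- p_from_z(x$beta, x$se)
  ratio <- x$pval / p_implied
  x$p_flag <- is.finite(ratio) &
    (ratio > p_consistency_factor | ratio < 1 / p_consistency_factor)
  attr(x, "phenotype_id") <- phenotype_id
  attr(x, "trait_type") <- trait_type
  x[, c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n", "p_flag")]
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a header-ed TSV of per-SNP associations and returns a validated
#' panel tibble. Rows whose numeric fields cannot be parsed (for example a
#' literal `"NA"` standard error) are dropped; the number dropped is stored
#' in the `"n_dropped"` attribute of the result.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping the canonical column
#'   names (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`) to the names used in the file. Only the names that differ
#'   need to be supplied.
#' @param ... Passed on to [summary_stats()] (e.g. `phenotype_id`,
#'   `trait_type`).
#'
#' @return A panel tibble (see [summary_stats()]) with attribute
#'   `"n_dropped"`.
#' @export
read_summary_stats <- function(path, column_map = NULL, ...) {
  canonical <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- setdiff(canonical, "eaf")
  missing <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s) in ", path, ": ",
                 paste(map[missing], collapse = ", ")))
  }
  present <- canonical[map[canonical] %in% names(raw)]
  out <- setNames(raw[, map[present], drop = FALSE], present)
  num_cols <- intersect(c("eaf", "beta", "se", "pval", "n"), names(out))
  for (col in num_cols) out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  must_parse <- setdiff(num_cols, "eaf")
  ok <- !Reduce(`|`, lapply(out[must_parse], is.na))
  n_dropped <- sum(!ok)
  panel <- summary_stats(out[ok, , drop = FALSE], ...)
  attr(panel, "n_dropped") <- n_dropped
  panel
}

#' Write a panel of summary statistics to a tab-separated file
#'
#' Inverse of [read_summary_stats()]: values round-trip at full double
#' precision.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(panel, path) {
  cols <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n")
  out <- panel[, cols]
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Harmonize effect alleles across phenotype panels
#'
#' Aligns one or more panels (outcome, mediators, co-exposures) to the
#' exposure panel's effect alleles so that per-SNP effects are comparable
#' across phenotypes. For each SNP shared by all panels:
#'
#' * identical allele pair: kept as is;
#' * swapped alleles: the non-reference panel's `beta` is sign-flipped and
#'   its `eaf` replaced by `1 - eaf`;
#' * strand-complement alleles: resolved by complementing (with a sign flip
#'   when the complemented pair is also swapped);
#' * palindromic SNPs (A/T or C/G): ambiguous under strand flips, so they
#'   are dropped whenever `eaf` falls inside `palindrome_band` in any panel
#'   (or is missing); otherwise they are aligned by frequency — panels whose
#'   `eaf` sits on the opposite side of 0.5 from the exposure are flipped;
#' * any other allele pair: dropped as a mismatch.
#'
#' @param exposure The reference panel; its effect alleles define the shared
#'   orientation.
#' @param others A single panel or a named list of panels to align. A single
#'   unnamed panel is labelled `"y"`.
#' @param palindrome_band Interval of `eaf` within which palindromic SNPs
#'   are considered unresolvable and dropped.
#'
#' @return A tibble with one row per retained SNP: `snp`, the exposure's
#'   `eaf`, `beta_x`, `se_x`, and `beta_<label>`, `se_<label>` for every
#'   panel in `others`. The per-SNP actions are recorded in the
#'   `"alignment_log"` attribute (see [harmonization_log()]).
#' @export
harmonize <- function(exposure, others, palindrome_band = c(0.42, 0.58)) {
  if (is.data.frame(others)) others <- list(y = others)
  if (is.null(names(others)) || any(names(others) == "")) {
    abort("every panel in `others` must be named")
  }
  shared <- Reduce(intersect, c(list(exposure$snp), lapply(others, `[[`, "snp")))
  if (length(shared) == 0) abort("no shared SNPs between exposure and other panels")

  exp_rows <- exposure[match(shared, exposure$snp), ]
  log_rows <- list()
  keep <- rep(TRUE, length(shared))
  aligned <- list()

  palin <- is_palindromic(exp_rows$effect_allele, exp_rows$other_allele)
  in_band <- function(f) !is.na(f) & f >= palindrome_band[1] & f <= palindrome_band[2]

  for (lab in names(others)) {
    pan <- others[[lab]]
    rows <- pan[match(shared, pan$snp), ]
    beta <- rows$beta; se <- rows$se; eaf <- rows$eaf
    ea <- rows$effect_allele; oa <- rows$other_allele
    cea <- DNA_COMPLEMENT[ea]; coa <- DNA_COMPLEMENT[oa]
    ref_ea <- exp_rows$effect_allele; ref_oa <- exp_rows$other_allele
    same <- ea == ref_ea & oa == ref_oa
    swap <- ea == ref_oa & oa == ref_ea
    strand <- cea == ref_ea & coa == ref_oa
    strand_swap <- cea == ref_oa & coa == ref_ea
    mismatch <- !(same | swap | strand | strand_swap)

    # palindromic SNPs: strand is unresolvable from alleles alone, so use
    # frequency alignment outside the ambiguity band and drop inside it
    ambiguous <- palin & !mismatch &
      (in_band(exp_rows$eaf) | in_band(eaf) | is.na(exp_rows$eaf) | is.na(eaf))
    freq_flip <- palin & !mismatch & !ambiguous &
      ((eaf > 0.5) != (exp_rows$eaf > 0.5))
    flip <- ifelse(palin, freq_flip, swap | strand_swap)

    action <- dplyr::case_when(
      mismatch ~ "dropped-mismatch",
      ambiguous ~ "dropped-palindromic",
      flip ~ "flipped",
      TRUE ~ "kept"
    )
    beta <- ifelse(flip, -beta, beta)
    eaf <- ifelse(flip, 1 - eaf, eaf)
    keep <- keep & !startsWith(action, "dropped")
    log_rows[[lab]] <- tibble::tibble(
      snp = shared, panel = lab, action = action,
      reason = dplyr::case_when(
        action == "dropped-palindromic" ~ "palindromic eaf in ambiguity band or missing",
        action == "dropped-mismatch" ~ "allele pair irreconcilable with exposure",
        action == "flipped" ~ "effect allele swapped relative to exposure",
        TRUE ~ "alleles already aligned"
      )
    )
    aligned[[lab]] <- tibble::tibble(beta = beta, se = se)
  }

  out <- tibble::tibble(
    snp = shared,
    eaf = exp_rows$eaf,
    beta_x = exp_rows$beta,
    se_x = exp_rows$se
  )
  for (lab in names(aligned)) {
    out[[paste0("beta_", lab)]] <- aligned[[lab]]$beta
    out[[paste0("se_", lab)]] <- aligned[[lab]]$se
  }
  out <- out[keep, ]
  attr(out, "alignment_log") <- dplyr::bind_rows(log_rows)
  out
}

#' Retrieve the per-SNP alignment log of a harmonized set
#'
#' @param h A harmonized set produced by [harmonize()].
#' @return A tibble with columns `snp`, `panel`, `action`
#'   (kept / flipped / dropped-palindromic / dropped-mismatch) and `reason`.
#' @export
harmonization_log <- function(h) {
  attr(h, "alignment_log") %||% tibble::tibble(
    snp = character(), panel = character(), action = character(), reason = character()
  )
}

#' Write a harmonization log as TSV
#'
#' @param h A harmonized set from [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(h, path) {
  readr::write_tsv(harmonization_log(h), path, progress = FALSE)
  invisible(path)
}
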
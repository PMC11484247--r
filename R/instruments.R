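#' Genome-wide significance filter
#'
#' Retains exactly the variants with `pvalue` strictly below the threshold,
#' preserving input order. This is the first stage of instrument selection;
#' the conventional genome-wide threshold is 5e-8.
#'
#' @param data A summary tibble (see [read_summary_set()]).
#' @param p_threshold Significance threshold; retention requires
#'   `pvalue < p_threshold` (strict).
#' @return The filtered tibble. An empty result is permitted and messaged.
#' @export
filter_significant <- function(data, p_threshold = 5e-8) {
  check_columns(data, "pvalue", "summary set")
  assert_scalar_number(p_threshold, "p_threshold", 0, 1, strict_lower = TRUE)
  out <- data[data$pvalue < p_threshold, , drop = FALSE]
  if (nrow(out) == 0) {
    inform(sprintf("no variants pass P < %g", p_threshold))
  }
  out
}

#' Greedy LD clumping
#'
#' Thins a set of associated variants to approximately independent index
#' SNPs. Candidates are processed in order of ascending p-value (ties broken
#' by chromosome, position, then rsid); at each step the most significant
#' remaining SNP is kept as an index and every remaining SNP on the same
#' chromosome strictly within `window_kb` kilobases whose known r-squared
#' with the index is at or above `r2_threshold` is removed. Pairs with no
#' entry in the LD table are treated as independent (unknown is not zero, but
#' absent pairs are assumed unlinked and this is messaged once). Output
#' preserves the input row order of the retained SNPs.
#'
#' @param data A summary tibble with `rsid`, `chrom`, `pos`, `pvalue`.
#' @param ld An [ld_table()] (or `NULL` for no known LD).
#' @param r2_threshold Removal threshold: a candidate is removed when its
#'   r-squared with the index is `>= r2_threshold`.
#' @param window_kb Maximum index-candidate distance considered, in kb; a
#'   pair exactly at `window_kb * 1000` base pairs is outside the window and
#'   retained.
#' @return The clumped tibble, in input order.
#' @export
clump <- function(data, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  check_columns(data, c("rsid", "chrom", "pos", "pvalue"), "summary set")
  assert_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  assert_scalar_number(window_kb, "window_kb", 0, Inf, strict_lower = TRUE)
  n <- nrow(data)
  if (n <= 1) return(data)
  proc <- order(data$pvalue, data$chrom, data$pos, data$rsid)
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, n)
  kept <- logical(n)
  any_unknown <- FALSE
  for (i in proc) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    data$chrom == data$chrom[i] &
                    abs(data$pos - data$pos[i]) < window_bp)
    if (length(near) > 0) {
      r2 <- ld_lookup(ld, data$rsid[i], data$rsid[near])
      any_unknown <- any_unknown || anyNA(r2)
      drop <- near[!is.na(r2) & r2 >= r2_threshold]
      alive[drop] <- FALSE
    }
  }
  if (any_unknown) {
    inform("some in-window pairs had no LD entry and were treated as independent")
  }
  data[kept, , drop = FALSE]
}

#' Secondary-phenotype screening
#'
#' Removes instruments known to associate, at genome-wide significance, with
#' phenotypes directly related to the outcome or with confounders (e.g.
#' cardiovascular disease, hypertension, diabetes), emulating a
#' PhenoScanner-style lookup from an offline table.
#'
#' @param data A summary tibble of candidate instruments.
#' @param secondary A secondary-association tibble
#'   (see [read_secondary_table()]); `NULL` or empty leaves the input
#'   unchanged.
#' @param p_threshold Associations with `pvalue < p_threshold` and category
#'   `outcome_related` or `confounder` trigger removal.
#' @return The screened tibble; removals are messaged with the offending
#'   phenotype label.
#' @export
screen_secondary <- function(data, secondary = NULL, p_threshold = 5e-8) {
  check_columns(data, "rsid", "summary set")
  if (is.null(secondary) || nrow(secondary) == 0) return(data)
  check_columns(secondary, c("rsid", "phenotype_label", "pvalue", "category"),
                "secondary-association table")
  hits <- secondary[secondary$category %in% c("outcome_related", "confounder") &
                      secondary$pvalue < p_threshold, , drop = FALSE]
  remove <- data$rsid %in% hits$rsid
  if (any(remove)) {
    for (rs in data$rsid[remove]) {
      labs <- unique(hits$phenotype_label[hits$rsid == rs])
      inform(sprintf("removed %s (secondary association: %s)",
                     rs, paste(labs, collapse = ", ")))
    }
  }
  data[!remove, , drop = FALSE]
}

#' Instrument-strength F-statistic
#'
#' The single-SNP strength statistic \eqn{F = (\hat\beta / se(\hat\beta))^2}.
#' F > 10 is the conventional weak-instrument cutoff.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all strictly positive.
#' @return Numeric vector of F values (always non-negative).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) {
    abort("`se` must be strictly positive and finite", class = "panelmr_domain_error")
  }
  (beta / se)^2
}

#' Weak-instrument filter
#'
#' Retains variants with `F = (beta/se)^2` strictly greater than the
#' threshold and records the per-variant F in an `f_stat` column.
#'
#' @param data A summary tibble.
#' @param f_threshold Strength threshold; retention requires `F > f_threshold`
#'   (strict).
#' @return The filtered tibble with an added `f_stat` column.
#' @export
filter_strength <- function(data, f_threshold = 10) {
  check_columns(data, c("beta", "se"), "summary set")
  assert_scalar_number(f_threshold, "f_threshold", 0, Inf)
  data$f_stat <- f_statistic(data$beta, data$se)
  data[data$f_stat > f_threshold, , drop = FALSE]
}

#' Select instrumental variables for an exposure
#'
#' Runs the four-stage instrument-selection chain in its fixed order:
#' genome-wide significance filter, greedy LD clumping, secondary-phenotype
#' screening, and the weak-instrument F filter. Every input variant appears
#' exactly once in the provenance table with the stage at which it was
#' removed (or `retained`).
#'
#' @param exposure Exposure summary tibble.
#' @param ld Optional [ld_table()] consumed by [clump()].
#' @param secondary Optional secondary-association table consumed by
#'   [screen_secondary()].
#' @param p_threshold Genome-wide significance threshold (strict `<`).
#' @param r2_threshold,window_kb Clumping parameters, see [clump()].
#' @param f_threshold Strength threshold (strict `>`), see [filter_strength()].
#' @return The instrument tibble (with `f_stat`), carrying the audit trail in
#'   attribute `"provenance"`; retrieve it with [instrument_provenance()].
#' @export
select_instruments <- function(exposure, ld = NULL, secondary = NULL,
                               p_threshold = 5e-8, r2_threshold = 0.001,
                               window_kb = 10000, f_threshold = 10) {
  check_columns(exposure, c("rsid", "chrom", "pos", "beta", "se", "pvalue"),
                "exposure summary set")
  if (nrow(exposure) == 0) {
    abort("exposure summary set is empty", class = "panelmr_input_error")
  }
  s1 <- filter_significant(exposure, p_threshold)
  s2 <- clump(s1, ld, r2_threshold, window_kb)
  s3 <- screen_secondary(s2, secondary, p_threshold)
  s4 <- filter_strength(s3, f_threshold)
  stage <- rep("retained", nrow(exposure))
  stage[!exposure$rsid %in% s1$rsid] <- "significance"
  stage[exposure$rsid %in% s1$rsid & !exposure$rsid %in% s2$rsid] <- "clump"
  stage[exposure$rsid %in% s2$rsid & !exposure$rsid %in% s3$rsid] <- "secondary"
  stage[exposure$rsid %in% s3$rsid & !exposure$rsid %in% s4$rsid] <- "strength"
  provenance <- tibble(
    rsid = exposure$rsid,
    status = ifelse(stage == "retained", "passed", "removed"),
    stage = stage,
    reason = dplyr::case_when(
      stage == "significance" ~ sprintf("pvalue >= %g", p_threshold),
      stage == "clump" ~ sprintf("in LD (r2 >= %g) with a better index SNP", r2_threshold),
      stage == "secondary" ~ "secondary phenotype association",
      stage == "strength" ~ sprintf("F <= %g", f_threshold),
      TRUE ~ "instrument"
    )
  )
  attr(s4, "provenance") <- provenance
  attr(s4, "exposure_trait_id") <- if ("trait_id" %in% names(exposure)) {
    exposure$trait_id[1]
  } else NA_character_
  s4
}

#' Instrument-selection audit trail
#'
#' @param instruments The result of [select_instruments()].
#' @return A tibble with one row per input variant: `rsid`, `status`
#'   (`passed`/`removed`), `stage`, `reason`.
#' @export
instrument_provenance <- function(instruments) {
  prov <- attr(instruments, "provenance")
  if (is.null(prov)) {
    abort("no provenance attribute; was this produced by select_instruments()?",
          class = "panelmr_input_error")
  }
  prov
}
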
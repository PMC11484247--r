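#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele, SNP by SNP, so
#' that every estimator consumes effect pairs expressed per copy of the same
#' allele. For each instrument SNP present in the outcome set:
#'
#' * identical allele pairs are kept as-is;
#' * swapped pairs (effect and other allele interchanged) have the outcome
#'   beta negated and, when present, the outcome allele frequency replaced by
#'   its complement;
#' * pairs matching after strand complementation (A<->T, C<->G), with or
#'   without a swap, are complemented and then treated as above;
#' * palindromic SNPs (exposure allele pair A/T or C/G) are dropped, because
#'   strand cannot be resolved from the alleles alone;
#' * irreconcilable pairs, and instruments absent from the outcome set, are
#'   dropped.
#'
#' Every instrument SNP receives exactly one action in the harmonization log
#' (attribute `"log"`, see [harmonization_log()]), so retained plus dropped
#' counts always equal the instrument count.
#'
#' @param instruments Exposure-side instrument tibble (e.g. from
#'   [select_instruments()]): columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, optionally `eaf`, `chrom`, `pos`.
#' @param outcome Outcome summary tibble with the same variant columns.
#' @param infer_palindromic If `TRUE`, palindromic SNPs whose minor-allele
#'   frequency is below `maf_limit` in both datasets are rescued: kept as-is
#'   when the frequencies are concordant (same side of 0.5), sign-flipped
#'   otherwise. Off by default; the faithful behaviour is unconditional
#'   removal.
#' @param maf_limit Frequency bound for the optional rescue.
#' @return A harmonized tibble with one row per retained SNP: `rsid`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_x`, `se_x`,
#'   `eaf_x`, `beta_y`, `se_y`, `eaf_y`. A warning is raised when no SNP
#'   survives.
#' @export
harmonize_pair <- function(instruments, outcome, infer_palindromic = FALSE,
                           maf_limit = 0.3) {
  check_columns(instruments, c("rsid", "effect_allele", "other_allele", "beta", "se"),
                "instrument set")
  check_columns(outcome, c("rsid", "effect_allele", "other_allele", "beta", "se"),
                "outcome summary set")
  n <- nrow(instruments)
  idx <- match(instruments$rsid, outcome$rsid)
  grab <- function(d, col, i = seq_len(nrow(d))) {
    if (col %in% names(d)) d[[col]][i] else rep(NA_real_, length(i))
  }

  action <- character(n)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (is.na(idx[j])) {
      action[j] <- "dropped_missing"
      next
    }
    ea_x <- instruments$effect_allele[j]
    oa_x <- instruments$other_allele[j]
    o <- idx[j]
    ea_o <- outcome$effect_allele[o]
    oa_o <- outcome$other_allele[o]
    b <- outcome$beta[o]
    s <- outcome$se[o]
    f <- grab(outcome, "eaf", o)
    if (is_palindromic(ea_x, oa_x)) {
      rescued <- FALSE
      if (infer_palindromic) {
        f_x <- grab(instruments, "eaf", j)
        same_pair <- setequal(c(ea_o, oa_o), c(ea_x, oa_x))
        if (same_pair && !is.na(f_x) && !is.na(f) &&
            pmin(f_x, 1 - f_x) < maf_limit && pmin(f, 1 - f) < maf_limit) {
          concordant <- (f_x < 0.5) == (f < 0.5)
          if (!concordant) {
            b <- -b
            f <- 1 - f
          }
          action[j] <- if (concordant) "kept" else "sign_flipped"
          beta_y[j] <- b; se_y[j] <- s; eaf_y[j] <- f
          rescued <- TRUE
        }
      }
      if (!rescued) action[j] <- "dropped_palindromic"
      next
    }
    flipped <- FALSE
    if (!setequal(c(ea_o, oa_o), c(ea_x, oa_x))) {
      ea_c <- complement_allele(ea_o)
      oa_c <- complement_allele(oa_o)
      if (setequal(c(ea_c, oa_c), c(ea_x, oa_x))) {
        ea_o <- ea_c
        oa_o <- oa_c
        flipped <- TRUE
      } else {
        action[j] <- "dropped_incompatible"
        next
      }
    }
    if (ea_o == ea_x && oa_o == oa_x) {
      action[j] <- if (flipped) "strand_flipped" else "kept"
    } else if (ea_o == oa_x && oa_o == ea_x) {
      b <- -b
      if (!is.na(f)) f <- 1 - f
      action[j] <- if (flipped) "strand_sign_flipped" else "sign_flipped"
    } else {
      action[j] <- "dropped_incompatible"
      next
    }
    beta_y[j] <- b
    se_y[j] <- s
    eaf_y[j] <- f
  }

  keep <- !startsWith(action, "dropped")
  out <- tibble(
    rsid = instruments$rsid[keep],
    chrom = if ("chrom" %in% names(instruments)) instruments$chrom[keep] else NA_character_,
    pos = grab(instruments, "pos", which(keep)),
    effect_allele = instruments$effect_allele[keep],
    other_allele = instruments$other_allele[keep],
    beta_x = instruments$beta[keep],
    se_x = instruments$se[keep],
    eaf_x = grab(instruments, "eaf", which(keep)),
    beta_y = beta_y[keep],
    se_y = se_y[keep],
    eaf_y = eaf_y[keep]
  )
  log <- tibble(rsid = instruments$rsid, action = action)
  if (nrow(out) == 0 && n > 0) {
    warn("no SNPs survived harmonization; downstream estimators will fail")
  }
  attr(out, "log") <- log
  out
}

#' Harmonization log
#'
#' @param harmonized Output of [harmonize_pair()].
#' @return A tibble with one row per instrument SNP: `rsid` and the `action`
#'   taken (`kept`, `sign_flipped`, `strand_flipped`, `strand_sign_flipped`,
#'   `dropped_palindromic`, `dropped_incompatible`, `dropped_missing`).
#' @export
harmonization_log <- function(harmonized) {
  log <- attr(harmonized, "log")
  if (is.null(log)) {
    abort("no log attribute; was this produced by harmonize_pair()?",
          class = "panelmr_input_error")
  }
  log
}

#' Orient exposure effects to be non-negative
#'
#' Relabels alleles so that every exposure effect is non-negative: each SNP
#' with `beta_x < 0` has both `beta_x` and `beta_y` negated (and allele
#' frequencies complemented, with effect and other allele swapped). Per-SNP
#' Wald ratios are unchanged; this fixes the sign convention the MR-Egger
#' intercept needs to be interpretable as average directional pleiotropy.
#'
#' @param harmonized A harmonized tibble (see [harmonize_pair()]).
#' @return The oriented tibble, with `beta_x >= 0` everywhere.
#' @export
orient_positive <- function(harmonized) {
  check_columns(harmonized, c("beta_x", "beta_y"), "harmonized set")
  neg <- harmonized$beta_x < 0
  if (!any(neg)) return(harmonized)
  out <- harmonized
  out$beta_x[neg] <- -out$beta_x[neg]
  out$beta_y[neg] <- -out$beta_y[neg]
  if (all(c("effect_allele", "other_allele") %in% names(out))) {
    ea <- out$effect_allele[neg]
    out$effect_allele[neg] <- out$other_allele[neg]
    out$other_allele[neg] <- ea
  }
  for (col in c("eaf_x", "eaf_y")) {
    if (col %in% names(out)) out[[col]][neg] <- 1 - out[[col]][neg]
  }
  out
}
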
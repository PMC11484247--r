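#' Panel run configuration
#'
#' Thresholds and method settings for [mr_panel()], defaulting to the
#' conventional two-sample MR pipeline: genome-wide significance 5e-8,
#' clumping at r-squared 0.001 within 10,000 kb, F > 10, Q-gated
#' fixed/random IVW, nominal significance 0.05 with no multiplicity
#' correction (Benjamini-Hochberg available via [adjust_multiplicity()]).
#'
#' @param p_threshold Genome-wide significance threshold (strict `<`).
#' @param r2_threshold,window_kb Clumping parameters.
#' @param f_threshold Instrument-strength threshold (strict `>`).
#' @param alpha Significance level for the primary-method flag.
#' @param model IVW model rule: `"auto"`, `"fixed"` or `"random"`.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param nsim_presso MR-PRESSO simulation count.
#' @param run_egger,run_median,run_presso Toggle the sensitivity analyses.
#' @param seed Integer seed; per-trait seeds are derived as `seed + trait
#'   index`, so a full run is deterministic.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 10000, f_threshold = 10, alpha = 0.05,
                         model = c("auto", "fixed", "random"),
                         n_boot = 1000, nsim_presso = 1000,
                         run_egger = TRUE, run_median = TRUE, run_presso = TRUE,
                         seed = 1L) {
  model <- match.arg(model)
  assert_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(seed, "seed")
  structure(list(
    p_threshold = p_threshold, r2_threshold = r2_threshold,
    window_kb = window_kb, f_threshold = f_threshold, alpha = alpha,
    model = model, n_boot = n_boot, nsim_presso = nsim_presso,
    run_egger = isTRUE(run_egger), run_median = isTRUE(run_median),
    run_presso = isTRUE(run_presso), seed = as.integer(seed)
  ), class = "panel_config")
}

#' Run the full two-sample MR chain over a panel of outcomes
#'
#' Selects instruments from the exposure once (significance, clumping,
#' secondary screening, strength), then for every outcome trait harmonizes
#' the pair and runs the primary IVW analysis plus the configured
#' sensitivity analyses (MR-Egger, weighted median, MR-PRESSO). A failure on
#' a single outcome (for example too few overlapping SNPs) is recorded as a
#' status row and never aborts the panel.
#'
#' @param exposure Exposure summary tibble.
#' @param outcomes A named list of outcome summary tibbles, or one long
#'   tibble split by its `trait_id` column.
#' @param ld Optional [ld_table()].
#' @param secondary Optional secondary-association table.
#' @param config A [panel_config()].
#' @return A tibble of class `mr_panel`: one row per (trait, method) plus
#'   status rows, with columns `trait_id`, `category`, `method`, `model`,
#'   `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, heterogeneity
#'   `Q`/`Q_df`/`Q_pvalue`, `presso_global_p`, `n_outliers`, `significant`
#'   (IVW rows only), `status`. The instrument set and per-trait
#'   harmonization logs are attached as attributes `"instruments"` and
#'   `"logs"`; `attr(x, "alpha")` records the significance level.
#' @export
mr_panel <- function(exposure, outcomes, ld = NULL, secondary = NULL,
                     config = panel_config()) {
  if (!inherits(config, "panel_config")) {
    abort("`config` must be created by panel_config()", class = "panelmr_config_error")
  }
  if (is.data.frame(outcomes)) {
    check_columns(outcomes, "trait_id", "outcome table")
    outcomes <- split(outcomes, outcomes$trait_id)
  }
  if (length(outcomes) < 1) {
    abort("at least one outcome trait is required", class = "panelmr_input_error")
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- purrr::map_chr(outcomes, function(o) {
      if ("trait_id" %in% names(o)) as.character(o$trait_id[1]) else NA_character_
    })
  }
  inst <- select_instruments(exposure, ld, secondary,
                             p_threshold = config$p_threshold,
                             r2_threshold = config$r2_threshold,
                             window_kb = config$window_kb,
                             f_threshold = config$f_threshold)
  if (nrow(inst) == 0) {
    abort("no instruments survived selection; cannot run the panel",
          class = "panelmr_estimation_error")
  }

  logs <- list()
  rows <- purrr::imap(outcomes, function(outcome, trait_id) {
    i <- match(trait_id, names(outcomes))
    trait_seed <- config$seed + i
    category <- if ("category" %in% names(outcome)) outcome$category[1] else "other"
    h <- harmonize_pair(inst, outcome)
    logs[[trait_id]] <<- harmonization_log(h)
    base <- tibble(trait_id = trait_id, category = category)
    if (nrow(h) < 2) {
      return(dplyr::mutate(base, method = "IVW", model = NA_character_,
                           nsnp = nrow(h), beta = NA_real_, se = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_,
                           pvalue = NA_real_, Q = NA_real_, Q_df = NA_integer_,
                           Q_pvalue = NA_real_, presso_global_p = NA_real_,
                           n_outliers = NA_integer_,
                           status = "insufficient instruments"))
    }
    ivw <- mr_ivw(h, model = config$model)
    presso_p <- NA_real_
    n_out <- NA_integer_
    presso_rows <- NULL
    if (config$run_presso && nrow(h) >= 4) {
      pr <- mr_presso(h, nsim = config$nsim_presso, seed = trait_seed)
      presso_p <- pr$global_p
      n_out <- length(pr$outlier_indices)
      if (!is.null(pr$estimate_no_outliers)) {
        presso_rows <- dplyr::mutate(result_row(pr$estimate_no_outliers),
                                     method = "IVW_outliers_removed")
      }
    }
    out <- dplyr::bind_cols(base, result_row(ivw)) |>
      mutate(Q = ivw$Q, Q_df = ivw$Q_df, Q_pvalue = ivw$Q_pvalue,
             presso_global_p = presso_p, n_outliers = n_out, status = "ok")
    extra <- list()
    if (config$run_egger && nrow(h) >= 3) {
      extra <- c(extra, list(tidy(mr_egger(h))))
    }
    if (config$run_median) {
      extra <- c(extra, list(result_row(
        mr_weighted_median(h, n_boot = config$n_boot, seed = trait_seed))))
    }
    if (!is.null(presso_rows)) extra <- c(extra, list(presso_rows))
    if (length(extra) > 0) {
      extra <- dplyr::bind_cols(base, bind_rows(extra)) |>
        mutate(status = "ok")
      out <- bind_rows(out, extra)
    }
    out
  })
  result <- bind_rows(rows)
  result$significant <- ifelse(result$method == "IVW" & result$status == "ok",
                               result$pvalue < config$alpha, NA)
  result <- structure(result, class = c("mr_panel", class(tibble())))
  attr(result, "alpha") <- config$alpha
  attr(result, "config") <- config
  attr(result, "instruments") <- inst
  attr(result, "logs") <- logs
  result
}

#' Directional consistency across methods
#'
#' A trait's causal evidence is called directionally consistent when the
#' IVW, MR-Egger and weighted-median point estimates share a sign (an exact
#' zero agrees with either sign). Traits missing any of the three method
#' rows get an `NA` flag and a message.
#'
#' @param panel An `mr_panel` tibble.
#' @return A tibble with `trait_id` and logical `consistent`.
#' @export
directional_consistency <- function(panel) {
  check_columns(panel, c("trait_id", "method", "beta"), "panel result")
  need <- c("IVW", "Egger", "WeightedMedian")
  panel |>
    filter(.data$method %in% need) |>
    group_by(.data$trait_id) |>
    summarise(consistent = {
      if (dplyr::n() < 3 || anyNA(.data$beta)) {
        inform(sprintf("trait %s lacks a method row; flag set to NA",
                       dplyr::cur_group()$trait_id))
        NA
      } else {
        s <- sign(.data$beta)
        length(unique(s[s != 0])) <= 1
      }
    }, .groups = "drop")
}

#' Multiplicity adjustment across the panel
#'
#' The pipeline's default follows the nominal-significance convention (no
#' correction across outcome traits). `method = "bh"` appends
#' Benjamini-Hochberg adjusted p-values computed across the primary (IVW)
#' rows, without altering the stored significance flags.
#'
#' @param panel An `mr_panel` tibble.
#' @param method `"none"` (identity) or `"bh"`.
#' @return The panel, with a `pvalue_adjusted` column on IVW rows when
#'   `method = "bh"`.
#' @export
adjust_multiplicity <- function(panel, method = c("none", "bh")) {
  method <- match.arg(method)
  if (method == "none") return(panel)
  check_columns(panel, c("method", "pvalue"), "panel result")
  primary <- panel$method == "IVW" & !is.na(panel$pvalue)
  panel$pvalue_adjusted <- NA_real_
  panel$pvalue_adjusted[primary] <- stats::p.adjust(panel$pvalue[primary],
                                                   method = "BH")
  panel
}

#' Plain-text panel summary
#'
#' @param object An `mr_panel` tibble.
#' @param ... Unused.
#' @return Invisibly, the tibble of significant primary rows.
#' @export
summary.mr_panel <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  prim <- object[object$method == "IVW" & object$status == "ok", , drop = FALSE]
  sig <- prim[!is.na(prim$significant) & prim$significant, , drop = FALSE]
  cat(sprintf("MR panel: %d traits analysed, %d significant at alpha = %g\n",
              nrow(prim), nrow(sig), alpha))
  if (nrow(sig) > 0) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s [%s]: beta = %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
                  sig$trait_id[i], sig$category[i], sig$beta[i],
                  sig$ci_low[i], sig$ci_high[i], sig$pvalue[i]))
    }
  }
  invisible(sig)
}
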
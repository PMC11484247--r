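#' Per-SNP Wald ratios
#'
#' The per-SNP causal estimate `beta_y / beta_x` and its standard error. The
#' default first-order SE, `se_y / |beta_x|`, ignores the exposure-side
#' sampling error, the standard default when instruments pass a strength
#' filter; the second-order form adds the `beta_y^2 se_x^2 / beta_x^4` term.
#'
#' @param harmonized A harmonized tibble (see [harmonize_pair()]).
#' @param second_order Use the second-order delta-method SE.
#' @return The input with columns `ratio` and `ratio_se` appended.
#' @export
wald_ratios <- function(harmonized, second_order = FALSE) {
  check_columns(harmonized, c("beta_x", "se_x", "beta_y", "se_y"), "harmonized set")
  zero <- which(harmonized$beta_x == 0)
  if (length(zero) > 0) {
    id <- if ("rsid" %in% names(harmonized)) harmonized$rsid[zero[1]] else
      sprintf("row %d", zero[1])
    abort(sprintf("beta_x is zero for %s; Wald ratio undefined", id),
          class = "panelmr_domain_error")
  }
  out <- harmonized
  out$ratio <- out$beta_y / out$beta_x
  out$ratio_se <- if (second_order) {
    sqrt(out$se_y^2 / out$beta_x^2 + out$beta_y^2 * out$se_x^2 / out$beta_x^4)
  } else {
    out$se_y / abs(out$beta_x)
  }
  out
}

CI_Z <- stats::qnorm(0.975)

new_mr_result <- function(method, model, nsnp, beta, se, pvalue,
                          ci_low, ci_high, extra = list(), class) {
  structure(
    c(list(method = method, model = model, nsnp = nsnp, beta = beta, se = se,
           ci_low = ci_low, ci_high = ci_high, pvalue = pvalue), extra),
    class = c(class, "mr_result")
  )
}

result_row <- function(x) {
  tibble(method = x$method, model = x$model, nsnp = x$nsnp, beta = x$beta,
         se = x$se, ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue)
}

#' Inverse-variance weighted estimator
#'
#' Combines per-SNP Wald ratios with weights `1 / ratio_se^2`. The
#' fixed-effects SE is `(sum w)^(-1/2)`; heterogeneity is measured by
#' Cochran's Q (`sum w (ratio - theta)^2`, chi-square on `nsnp - 1` df) and
#' the multiplicative random-effects SE inflates the fixed SE by
#' `max(1, sqrt(Q/df))`, so it is never narrower. Under `model = "auto"` the
#' fixed model is reported when the Q p-value exceeds 0.05 and the random
#' model otherwise — the conventional heterogeneity-driven rule. P-values use
#' a two-sided normal reference; the 95% CI is `beta +/- 1.96 se`.
#'
#' A single-SNP input returns that SNP's Wald ratio with `model = "n/a"` and
#' no heterogeneity statistic.
#'
#' @param harmonized A harmonized tibble with at least one SNP.
#' @param model `"auto"` (Q-gated), `"fixed"`, or `"random"`.
#' @param second_order Passed to [wald_ratios()].
#' @return An object of class `mr_ivw`; see [tidy.mr_ivw()] and
#'   [glance.mr_ivw()].
#' @export
mr_ivw <- function(harmonized, model = c("auto", "fixed", "random"),
                   second_order = FALSE) {
  model <- match.arg(model)
  if (nrow(harmonized) == 0) {
    abort("cannot estimate from an empty harmonized set",
          class = "panelmr_estimation_error")
  }
  wr <- wald_ratios(harmonized, second_order)
  n <- nrow(wr)
  if (n == 1) {
    beta <- wr$ratio[1]
    se <- wr$ratio_se[1]
    return(new_mr_result(
      "IVW", "n/a", 1L, beta, se, z_pvalue(beta, se),
      beta - CI_Z * se, beta + CI_Z * se,
      extra = list(Q = NA_real_, Q_df = NA_integer_, Q_pvalue = NA_real_,
                   se_fixed = se, se_random = se),
      class = "mr_ivw"
    ))
  }
  w <- 1 / wr$ratio_se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (wr$ratio - beta)^2)
  df <- n - 1L
  Q_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  se_random <- se_fixed * max(1, sqrt(Q / df))
  used <- switch(model,
                 fixed = "fixed",
                 random = "random",
                 auto = if (Q_p > 0.05) "fixed" else "random")
  se <- if (used == "fixed") se_fixed else se_random
  new_mr_result(
    "IVW", used, n, beta, se, z_pvalue(beta, se),
    beta - CI_Z * se, beta + CI_Z * se,
    extra = list(Q = Q, Q_df = df, Q_pvalue = Q_p,
                 se_fixed = se_fixed, se_random = se_random),
    class = "mr_ivw"
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' unconstrained intercept and weights `1 / se_y^2`. The slope is the causal
#' estimate (consistent under the InSIDE assumption even when all
#' instruments are pleiotropic); the intercept estimates average directional
#' pleiotropy. Exposure effects are first oriented non-negative (see
#' [orient_positive()]) so the intercept's sign convention is well defined.
#' Coefficient SEs carry a residual-SD multiplier floored at 1 (the SE is
#' never deflated below the homoskedastic weighted model), and inference uses
#' a t reference with `nsnp - 2` df.
#'
#' @param harmonized A harmonized tibble with at least three SNPs.
#' @return An object of class `mr_egger` holding slope and intercept
#'   estimates; see [tidy.mr_egger()].
#' @export
mr_egger <- function(harmonized) {
  if (nrow(harmonized) < 3) {
    abort("MR-Egger needs at least 3 SNPs", class = "panelmr_estimation_error")
  }
  o <- orient_positive(harmonized)
  if (stats::var(o$beta_x) == 0) {
    abort("exposure effects are constant; Egger slope is not identified",
          class = "panelmr_estimation_error")
  }
  n <- nrow(o)
  fit <- stats::lm(beta_y ~ beta_x, data = o, weights = 1 / o$se_y^2)
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  # summary() SE = base SE * sigma; dividing by min(1, sigma) applies the
  # max(1, sigma) multiplier to the unit-dispersion SE
  se <- sm$coefficients[, "Std. Error"] / min(1, sm$sigma)
  df <- n - 2L
  pv <- 2 * stats::pt(-abs(est / se), df)
  tq <- stats::qt(0.975, df)
  slope <- new_mr_result(
    "Egger", "n/a", n, est[["beta_x"]], se[["beta_x"]], pv[["beta_x"]],
    est[["beta_x"]] - tq * se[["beta_x"]], est[["beta_x"]] + tq * se[["beta_x"]],
    extra = list(df = df, ci_reference = "t"), class = "mr_egger_slope"
  )
  intercept <- new_mr_result(
    "EggerIntercept", "n/a", n, est[["(Intercept)"]], se[["(Intercept)"]],
    pv[["(Intercept)"]],
    est[["(Intercept)"]] - tq * se[["(Intercept)"]],
    est[["(Intercept)"]] + tq * se[["(Intercept)"]],
    extra = list(df = df, ci_reference = "t"), class = "mr_egger_intercept"
  )
  structure(list(slope = slope, intercept = intercept, nsnp = n,
                 sigma = sm$sigma),
            class = "mr_egger")
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios, consistent when valid
#' instruments carry more than half the total inverse-variance weight. With
#' ratios sorted ascending and normalized weights `w'_j`, the estimate
#' interpolates linearly between the ordered ratios where the function
#' `s_j = cumsum(w')_j - w'_j / 2` crosses one half. The SE comes from a
#' parametric bootstrap: exposure and outcome effects are redrawn from normal
#' distributions centred at the observed values with the observed SEs, the
#' weighted median recomputed, and the SE taken as the SD over replicates.
#' SNPs are sorted (by ratio, then rsid) before resampling, so both the point
#' estimate and the bootstrap SE are invariant to the input row order at a
#' fixed seed.
#'
#' @param harmonized A harmonized tibble with at least two SNPs.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Mandatory integer seed for the bootstrap.
#' @return An object of class `mr_wmedian`.
#' @export
mr_weighted_median <- function(harmonized, n_boot = 1000, seed) {
  if (nrow(harmonized) < 2) {
    abort("weighted median needs at least 2 SNPs",
          class = "panelmr_estimation_error")
  }
  if (missing(seed)) {
    abort("`seed` is required for the bootstrap SE", class = "panelmr_config_error")
  }
  wr <- wald_ratios(harmonized)
  ord <- if ("rsid" %in% names(wr)) order(wr$ratio, wr$rsid) else order(wr$ratio)
  wr <- wr[ord, , drop = FALSE]
  w <- 1 / wr$ratio_se^2
  beta <- weighted_median_point(wr$ratio, w)
  n <- nrow(wr)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, wr$beta_x, wr$se_x)
      by <- stats::rnorm(n, wr$beta_y, wr$se_y)
      weighted_median_point(by / bx, (bx / wr$se_y)^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_result(
    "WeightedMedian", "n/a", n, beta, se, z_pvalue(beta, se),
    beta - CI_Z * se, beta + CI_Z * se,
    extra = list(n_boot = n_boot, seed = seed), class = "mr_wmedian"
  )
}

# weighted median with linear interpolation at the 0.5 crossing of
# s_j = cumsum(w')_j - w'_j/2; clamps to the extreme ratios when the
# crossing falls outside the grid
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  wn <- w[o] / sum(w)
  s <- cumsum(wn) - wn / 2
  n <- length(r)
  if (s[1] >= 0.5) return(r[1])
  if (s[n] <= 0.5) return(r[n])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%s): %d SNPs\n", x$method, x$model, x$nsnp))
  cat(sprintf("  beta = %.6g (se %.6g), 95%% CI [%.6g, %.6g], p = %.4g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n")
  print(x$slope)
  print(x$intercept)
  invisible(x)
}

#' Tidy an IVW fit
#'
#' @param x An `mr_ivw` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `model`, `nsnp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`.
#' @method tidy mr_ivw
#' @export
tidy.mr_ivw <- function(x, ...) result_row(x)

#' Model-level summary of an IVW fit
#'
#' @param x An `mr_ivw` object.
#' @param ... Unused.
#' @return A one-row tibble with the model used, Cochran's Q, its df and
#'   p-value, and both candidate SEs.
#' @method glance mr_ivw
#' @export
glance.mr_ivw <- function(x, ...) {
  tibble(nsnp = x$nsnp, model = x$model, Q = x$Q, Q_df = x$Q_df,
         Q_pvalue = x$Q_pvalue, se_fixed = x$se_fixed, se_random = x$se_random)
}

#' Tidy an MR-Egger fit
#'
#' @param x An `mr_egger` object.
#' @param ... Unused.
#' @return A two-row tibble (slope, then intercept).
#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, ...) {
  bind_rows(result_row(x$slope), result_row(x$intercept))
}

#' Model-level summary of an MR-Egger fit
#'
#' @param x An `mr_egger` object.
#' @param ... Unused.
#' @return A one-row tibble with `nsnp`, residual SD, and the t df.
#' @method glance mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  tibble(nsnp = x$nsnp, sigma = x$sigma, df = x$slope$df)
}

#' Tidy a weighted-median fit
#'
#' @param x An `mr_wmedian` object.
#' @param ... Unused.
#' @return A one-row tibble of the estimate.
#' @method tidy mr_wmedian
#' @export
tidy.mr_wmedian <- function(x, ...) result_row(x)
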
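#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal pleiotropy via a simulated null on the residual sum of
#' squares, flags individual outlier SNPs, and tests whether removing them
#' distorts the causal estimate.
#'
#' For each SNP `j` the leave-one-out fixed-effects IVW estimate
#' `theta(-j)` is computed and the weighted squared residual is
#' `r_j = (beta_y_j - theta(-j) beta_x_j)^2 / se_y_j^2`; the observed global
#' statistic is `RSS = sum r_j`. The null distribution is simulated `nsim`
#' times by drawing `beta_x*_j ~ N(beta_x_j, se_x_j^2)` and
#' `beta_y*_j ~ N(theta(-j) beta_x_j, se_y_j^2)` and recomputing the full
#' statistic identically (including the leave-one-out estimates on the
#' simulated data). Empirical p-values carry the add-one correction, so the
#' smallest attainable p is `1/(nsim+1)`:
#'
#' * global test: `p = (1 + #\{RSS* >= RSS\}) / (nsim + 1)`;
#' * outlier test: per-SNP `p_j = (1 + #\{r*_j >= r_j\}) / (nsim + 1)`,
#'   Bonferroni-adjusted by `nsnp`, flagged when the adjusted p is below
#'   `sig`;
#' * distortion test (only when outliers are flagged): the percent change
#'   `100 (theta_all - theta_out) / |theta_out|` between the IVW estimate on
#'   all SNPs and after outlier removal, referred to a null built from `nsim`
#'   random removals of the same number of SNPs.
#'
#' When outliers are found, the set is re-analysed with the same Q-gated IVW
#' rule as the main analysis. All randomness derives from `seed`; identical
#' inputs and seed give an identical report.
#'
#' @param harmonized A harmonized tibble with at least four SNPs (the
#'   leave-one-out estimates must remain estimable).
#' @param nsim Number of null simulations.
#' @param seed Mandatory integer seed.
#' @param sig Significance level for flagging outliers (on the adjusted p).
#' @return An object of class `mr_presso`: a list with `rss_obs`,
#'   `global_p`, `nsim`, `outliers` (per-SNP tibble of raw and adjusted
#'   p-values and flags), `outlier_indices`, `estimate_all`,
#'   `estimate_no_outliers` (`NULL` when nothing was removed or everything
#'   was flagged), `distortion_coef`, `distortion_p`, `status`, `seed`.
#' @export
mr_presso <- function(harmonized, nsim = 1000, seed, sig = 0.05) {
  if (nrow(harmonized) < 4) {
    abort("MR-PRESSO needs at least 4 SNPs", class = "panelmr_estimation_error")
  }
  if (missing(seed)) {
    abort("`seed` is required", class = "panelmr_config_error")
  }
  assert_scalar_number(sig, "sig", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_columns(harmonized, c("beta_x", "se_x", "beta_y", "se_y"), "harmonized set")
  h <- harmonized
  n <- nrow(h)
  bx <- h$beta_x; by <- h$beta_y; sx <- h$se_x; sy <- h$se_y
  if (any(bx == 0)) {
    abort("beta_x of zero is not supported", class = "panelmr_domain_error")
  }

  loo <- loo_ivw(bx, by, sy)
  resid_obs <- (by - loo * bx)^2 / sy^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(nsim * n, mean = rep(bx, each = nsim),
                                   sd = rep(sx, each = nsim)), nrow = nsim)
    by_star <- matrix(stats::rnorm(nsim * n, mean = rep(loo * bx, each = nsim),
                                   sd = rep(sy, each = nsim)), nrow = nsim)
    list(bx = bx_star, by = by_star)
  })
  # leave-one-out fixed-effects IVW recomputed row-wise on the simulated data
  sy_m <- matrix(sy, nrow = nsim, ncol = n, byrow = TRUE)
  w_star <- sims$bx^2 / sy_m^2
  s1 <- rowSums(sims$bx * sims$by / sy_m^2)
  s0 <- rowSums(w_star)
  ratio_star <- sims$by / sims$bx
  loo_star <- (s1 - w_star * ratio_star) / (s0 - w_star)
  resid_star <- (sims$by - loo_star * sims$bx)^2 / sy_m^2
  rss_star <- rowSums(resid_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (nsim + 1)
  exceed <- colSums(resid_star >= matrix(resid_obs, nrow = nsim, ncol = n,
                                         byrow = TRUE))
  p_raw <- (1 + exceed) / (nsim + 1)
  p_adj <- pmin(1, n * p_raw)
  flagged <- which(p_adj < sig)

  outliers <- tibble(
    rsid = if ("rsid" %in% names(h)) h$rsid else as.character(seq_len(n)),
    index = seq_len(n),
    residual = resid_obs,
    p_raw = p_raw,
    p_adjusted = p_adj,
    outlier = p_adj < sig
  )

  estimate_all <- mr_ivw(h, model = "auto")
  estimate_no <- NULL
  distortion_coef <- NA_real_
  distortion_p <- NA_real_
  status <- "ok"
  if (length(flagged) == n) {
    status <- "all_snps_flagged"
  } else if (length(flagged) > 0) {
    keep <- setdiff(seq_len(n), flagged)
    estimate_no <- mr_ivw(h[keep, , drop = FALSE], model = "auto")
    theta_all <- ivw_point(bx, by, sy)
    theta_no <- ivw_point(bx[keep], by[keep], sy[keep])
    distortion_coef <- 100 * (theta_all - theta_no) / abs(theta_no)
    k <- length(flagged)
    coef_star <- with_seed(seed + 1L, {
      vapply(seq_len(nsim), function(b) {
        drop <- sample.int(n, k)
        th <- ivw_point(bx[-drop], by[-drop], sy[-drop])
        100 * (theta_all - th) / abs(th)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(coef_star) >= abs(distortion_coef))) / (nsim + 1)
  }

  structure(list(
    rss_obs = rss_obs, global_p = global_p, nsim = nsim,
    outliers = outliers, outlier_indices = flagged,
    estimate_all = estimate_all, estimate_no_outliers = estimate_no,
    distortion_coef = distortion_coef, distortion_p = distortion_p,
    status = status, sig = sig, seed = seed, nsnp = n
  ), class = "mr_presso")
}

# fixed-effects IVW point estimate on the Wald-ratio scale
ivw_point <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  sum(w * by / bx) / sum(w)
}

# leave-one-out fixed-effects IVW estimates, O(n) via totals
loo_ivw <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d SNPs, %d simulations)\n", x$nsnp, x$nsim))
  cat(sprintf("  global RSS = %.6g, p = %.4g\n", x$rss_obs, x$global_p))
  cat(sprintf("  outliers flagged: %d\n", length(x$outlier_indices)))
  if (!is.na(x$distortion_coef)) {
    cat(sprintf("  distortion = %.3f%%, p = %.4g\n",
                x$distortion_coef, x$distortion_p))
  }
  if (x$status != "ok") cat(sprintf("  status: %s\n", x$status))
  invisible(x)
}

#' Tidy an MR-PRESSO report
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return A tibble of the IVW estimates before and (when outliers were
#'   removed) after outlier removal, with an `analysis` column.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  out <- dplyr::mutate(result_row(x$estimate_all), analysis = "all_snps",
                       .before = 1)
  if (!is.null(x$estimate_no_outliers)) {
    out <- bind_rows(out, dplyr::mutate(result_row(x$estimate_no_outliers),
                                        analysis = "outliers_removed",
                                        .before = 1))
  }
  out
}

#' Test-level summary of an MR-PRESSO report
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return A one-row tibble with the global, outlier-count and distortion
#'   results.
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(nsnp = x$nsnp, nsim = x$nsim, rss_obs = x$rss_obs,
         global_p = x$global_p, n_outliers = length(x$outlier_indices),
         distortion_coef = x$distortion_coef, distortion_p = x$distortion_p,
         status = x$status)
}
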
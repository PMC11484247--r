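test_that("Wald ratios follow the delta formula and are symmetric under joint negation", {
  h <- tibble::tibble(rsid = "rs1", beta_x = 0.5, se_x = 0.02,
                      beta_y = 0.1, se_y = 0.05)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$ratio_se, 0.1)
  neg <- dplyr::mutate(h, beta_x = -beta_x, beta_y = -beta_y)
  expect_equal(wald_ratios(neg)$ratio, wr$ratio)
  expect_equal(wald_ratios(neg)$ratio_se, wr$ratio_se)
  expect_equal(wald_ratios(dplyr::mutate(h, beta_y = 0))$ratio, 0)
  expect_error(wald_ratios(dplyr::mutate(h, beta_x = 0)),
               "rs1", class = "panelmr_domain_error")
  # second-order SE is never smaller than first-order
  h2 <- random_harmonized(10, seed = 3)
  expect_true(all(wald_ratios(h2, second_order = TRUE)$ratio_se >=
                    wald_ratios(h2)$ratio_se))
})

test_that("IVW degenerate cases: single SNP, equal weights, homogeneity", {
  one <- tibble::tibble(rsid = "rs1", beta_x = 0.5, se_x = 0.02,
                        beta_y = 0.1, se_y = 0.05)
  fit1 <- mr_ivw(one)
  expect_equal(fit1$beta, 0.2)
  expect_equal(fit1$model, "n/a")
  expect_true(is.na(fit1$Q))

  two <- tibble::tibble(rsid = c("a", "b"), beta_x = c(1, 1), se_x = 0.01,
                        beta_y = c(0.1, 0.3), se_y = c(0.05, 0.05))
  expect_equal(mr_ivw(two)$beta, 0.2)

  same <- tibble::tibble(rsid = letters[1:4], beta_x = c(1, 2, 1, 2),
                         se_x = 0.01, beta_y = c(0.1, 0.2, 0.1, 0.2),
                         se_y = c(0.03, 0.05, 0.04, 0.06))
  fit <- mr_ivw(same)
  expect_equal(fit$Q, 0, tolerance = 1e-20)
  expect_equal(fit$model, "fixed")
  expect_equal(fit$se_random, fit$se_fixed)
  expect_error(mr_ivw(same[0, ]), class = "panelmr_estimation_error")
})

test_that("IVW matches the weighted-mean oracle and the WLS-through-origin cross-check", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      h <- random_harmonized(sample(5:12, 1), seed = sample.int(1e6, 1))
      fit <- mr_ivw(h)
      orc <- oracle_ivw(h$beta_x, h$beta_y, h$se_y)
      expect_equal(fit$beta, orc$theta, tolerance = 1e-10)
      expect_equal(fit$se_fixed, orc$se_fixed, tolerance = 1e-10)
      expect_equal(fit$se_random, orc$se_random, tolerance = 1e-10)
      expect_equal(fit$Q, orc$Q, tolerance = 1e-10)
      # the regression-through-origin formulation agrees exactly with the
      # Wald-ratio weighted mean when the first-order SE defines the weights
      expect_equal(fit$beta, oracle_ivw_regression(h$beta_x, h$beta_y, h$se_y),
                   tolerance = 1e-10)
      expect_gte(fit$se_random, fit$se_fixed)
      expect_equal(fit$ci_low, fit$beta - qnorm(0.975) * fit$se, tolerance = 1e-12)
    }
  })
})

test_that("IVW auto rule picks fixed above the Q threshold and random below", {
  h <- random_harmonized(10, seed = 21)
  fit <- mr_ivw(h, model = "auto")
  expect_equal(fit$model, if (fit$Q_pvalue > 0.05) "fixed" else "random")
  # heterogeneous set: inflate one ratio far beyond its SE
  h$beta_y[1] <- h$beta_y[1] + 30 * h$se_y[1]
  het <- mr_ivw(h, model = "auto")
  expect_lt(het$Q_pvalue, 0.05)
  expect_equal(het$model, "random")
  expect_gt(het$se, mr_ivw(h, model = "fixed")$se)
})

test_that("estimators are invariant under permutation of SNP order", {
  h <- random_harmonized(10, seed = 13)
  perm <- h[sample(nrow(h)), ]
  expect_equal(mr_ivw(perm)$beta, mr_ivw(h)$beta, tolerance = 1e-14)
  expect_equal(mr_egger(perm)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  wm1 <- mr_weighted_median(h, n_boot = 200, seed = 4)
  wm2 <- mr_weighted_median(perm, n_boot = 200, seed = 4)
  expect_equal(wm2$beta, wm1$beta, tolerance = 1e-14)
  expect_equal(wm2$se, wm1$se)     # identical: resampling indexed after sorting
})

test_that("Egger recovers a noiseless affine relation exactly", {
  h <- tibble::tibble(rsid = sprintf("rs%d", 1:6),
                      beta_x = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35),
                      se_x = 0.01,
                      beta_y = 0.03 + 0.4 * c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35),
                      se_y = c(0.02, 0.03, 0.04, 0.02, 0.03, 0.04))
  fit <- mr_egger(h)
  expect_equal(fit$slope$beta, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept$beta, 0.03, tolerance = 1e-12)
})

test_that("Egger errors on degenerate designs", {
  const <- tibble::tibble(rsid = letters[1:4], beta_x = 0.2, se_x = 0.01,
                          beta_y = rnorm(4, 0, 0.01), se_y = 0.02)
  expect_error(mr_egger(const), class = "panelmr_estimation_error")
  expect_error(mr_egger(random_harmonized(2, seed = 1)),
               class = "panelmr_estimation_error")
})

test_that("Egger matches the normal-equations oracle with the SE multiplier and t reference", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      h <- random_harmonized(sample(6:15, 1), seed = sample.int(1e6, 1))
      fit <- mr_egger(h)
      orc <- oracle_egger(h$beta_x, h$beta_y, h$se_y)
      expect_equal(fit$slope$beta, orc$slope, tolerance = 1e-10)
      expect_equal(fit$intercept$beta, orc$intercept, tolerance = 1e-10)
      expect_equal(fit$slope$se, orc$se_slope, tolerance = 1e-10)
      expect_equal(fit$intercept$se, orc$se_intercept, tolerance = 1e-10)
      expect_equal(fit$slope$pvalue, orc$p_slope, tolerance = 1e-10)
      tq <- qt(0.975, nrow(h) - 2)
      expect_equal(fit$slope$ci_high - fit$slope$beta, tq * fit$slope$se,
                   tolerance = 1e-10)
    }
  })
})

test_that("weighted median interpolates the 0.5 crossing and matches the oracle", {
  eq <- tibble::tibble(rsid = c("a", "b", "c"), beta_x = 1, se_x = 0.01,
                       beta_y = c(0.1, 0.2, 0.9), se_y = 0.05)
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 0.2)

  withr::with_seed(23, {
    for (rep in 1:10) {
      h <- random_harmonized(10, seed = sample.int(1e6, 1))
      fit <- mr_weighted_median(h, n_boot = 50, seed = 2)
      wr <- wald_ratios(h)
      expect_equal(fit$beta,
                   oracle_weighted_median(wr$ratio, 1 / wr$ratio_se^2),
                   tolerance = 1e-12)
    }
  })
})

test_that("weighted median SE is seed-reproducible and collapses with the input noise", {
  h <- random_harmonized(10, seed = 31)
  a <- mr_weighted_median(h, n_boot = 300, seed = 9)
  b <- mr_weighted_median(h, n_boot = 300, seed = 9)
  expect_identical(a$se, b$se)
  expect_identical(a$beta, b$beta)

  # all ratios equal and SEs shrinking: estimate c, bootstrap SE -> 0
  mk <- function(s) tibble::tibble(rsid = letters[1:5], beta_x = 0.5, se_x = s,
                                   beta_y = 0.15, se_y = s)
  big <- mr_weighted_median(mk(0.01), n_boot = 200, seed = 3)
  small <- mr_weighted_median(mk(0.0001), n_boot = 200, seed = 3)
  expect_equal(big$beta, 0.3)
  expect_lt(small$se, big$se)
  expect_lt(small$se, 1e-3)
})

test_that("tidy and glance return the documented shapes", {
  h <- random_harmonized(8, seed = 41)
  ti <- tidy(mr_ivw(h))
  expect_equal(nrow(ti), 1)
  expect_named(ti, c("method", "model", "nsnp", "beta", "se",
                     "ci_low", "ci_high", "pvalue"))
  gl <- glance(mr_ivw(h))
  expect_true(all(c("Q", "Q_df", "Q_pvalue") %in% names(gl)))
  te <- tidy(mr_egger(h))
  expect_equal(te$method, c("Egger", "EggerIntercept"))
  tw <- tidy(mr_weighted_median(h, n_boot = 50, seed = 1))
  expect_equal(tw$method, "WeightedMedian")
})
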
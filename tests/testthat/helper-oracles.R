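# Independent brute-force oracles, deliberately coded differently from the
# package implementation (explicit loops, normal equations), plus small
# fixture builders used across test files.

# weighted mean of Wald ratios, computed element by element
oracle_ivw <- function(bx, by, sy) {
  r <- numeric(length(bx))
  w <- numeric(length(bx))
  for (j in seq_along(bx)) {
    r[j] <- by[j] / bx[j]
    w[j] <- (abs(bx[j]) / sy[j])^2
  }
  theta <- sum(w * r) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- 0
  for (j in seq_along(bx)) Q <- Q + w[j] * (r[j] - theta)^2
  df <- length(bx) - 1
  list(theta = theta, se_fixed = se_fixed,
       se_random = se_fixed * max(1, sqrt(Q / df)),
       Q = Q, df = df, Q_p = pchisq(Q, df, lower.tail = FALSE))
}

# cross-check formulation: weighted least squares through the origin of
# beta_y on beta_x with weights 1/se_y^2, solved in closed form
oracle_ivw_regression <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

# weighted regression with intercept solved by explicit normal equations,
# applied after orienting beta_x >= 0
oracle_egger <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]
  by[flip] <- -by[flip]
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * by)
  est <- solve(XtWX, XtWy)
  resid <- by - X %*% est
  n <- length(bx)
  sigma2 <- sum(w * resid^2) / (n - 2)
  base_se <- sqrt(diag(solve(XtWX)))
  se <- base_se * max(1, sqrt(sigma2))
  list(intercept = unname(est[1]), slope = unname(est[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       p_slope = unname(2 * pt(-abs(est[2] / se[2]), n - 2)))
}

# weighted quantile by direct scan over the sorted cumulative weights
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  wn <- w[o] / sum(w)
  s <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    s[j] <- acc + wn[j] / 2
    acc <- acc + wn[j]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(r)] <= 0.5) return(r[length(r)])
  for (j in seq_along(r)[-1]) {
    if (s[j] >= 0.5) {
      return(r[j - 1] + (r[j] - r[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1]))
    }
  }
}

# exhaustive greedy clumping: repeatedly pick the best remaining SNP and
# delete linked in-window neighbours, checking every pair explicitly
oracle_clump <- function(data, ld_mat, r2_threshold, window_bp) {
  remaining <- seq_len(nrow(data))
  kept <- integer(0)
  while (length(remaining) > 0) {
    ord <- remaining[order(data$pvalue[remaining], data$chrom[remaining],
                           data$pos[remaining], data$rsid[remaining])]
    idx <- ord[1]
    kept <- c(kept, idx)
    remaining <- setdiff(remaining, idx)
    drop <- integer(0)
    for (j in remaining) {
      if (data$chrom[j] != data$chrom[idx]) next
      if (abs(data$pos[j] - data$pos[idx]) >= window_bp) next
      r2 <- ld_mat[data$rsid[idx], data$rsid[j]]
      if (!is.na(r2) && r2 >= r2_threshold) drop <- c(drop, j)
    }
    remaining <- setdiff(remaining, drop)
  }
  data$rsid[sort(kept)]
}

# step-up BH adjustment done by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# random harmonized set on realistic scales
random_harmonized <- function(n, seed, theta = 0.2) {
  withr::with_seed(seed, {
    se_x <- runif(n, 0.005, 0.05)
    se_y <- runif(n, 0.005, 0.05)
    gamma <- runif(n, 0.08, 0.4) * sample(c(-1, 1), n, replace = TRUE)
    tibble::tibble(
      rsid = sprintf("rs%03d", seq_len(n)),
      effect_allele = "A", other_allele = "G",
      beta_x = rnorm(n, gamma, se_x), se_x = se_x,
      beta_y = rnorm(n, theta * gamma, se_y), se_y = se_y
    )
  })
}

# minimal exposure summary tibble for filter/clump tests
make_summary <- function(rsid, pvalue, chrom = "1", pos = seq_along(rsid) * 1e6,
                         beta = 0.1, se = 0.01, eaf = 0.3,
                         ea = "A", oa = "G", trait_id = "exposure") {
  tibble::tibble(
    trait_id = trait_id, trait_label = trait_id, category = "exposure",
    ancestry = "European",
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = 10000
  )
}
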
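test_that("significance filter is strict at the threshold and idempotent", {
  s <- make_summary(c("rs1", "rs2", "rs3"), c(1e-9, 5e-8, 1e-7))
  out <- filter_significant(s)
  expect_equal(out$rsid, "rs1")
  expect_equal(filter_significant(out), out)

  expect_equal(nrow(suppressMessages(
    filter_significant(make_summary("rs1", 0.5)))), 0)
  expect_equal(nrow(filter_significant(s, p_threshold = 1)), 3)
})

test_that("clumping drops a dominated in-LD neighbour but respects the window", {
  ld <- ld_table(tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9))
  near <- make_summary(c("rs1", "rs2"), c(1e-10, 1e-9), pos = c(1e6, 1e6 + 1e3))
  expect_equal(clump(near, ld)$rsid, "rs1")

  far <- make_summary(c("rs1", "rs2"), c(1e-10, 1e-9), pos = c(1e6, 1e6 + 2e7))
  expect_equal(clump(far, ld)$rsid, c("rs1", "rs2"))

  # exactly at the window boundary: outside, retained
  edge <- make_summary(c("rs1", "rs2"), c(1e-10, 1e-9), pos = c(1e6, 1e6 + 1e7))
  expect_equal(clump(edge, ld, window_kb = 10000)$rsid, c("rs1", "rs2"))

  # r2 exactly at the threshold: removed
  ld2 <- ld_table(tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.001))
  expect_equal(clump(near, ld2, r2_threshold = 0.001)$rsid, "rs1")

  # unknown r2 treated as independent
  expect_message(out <- clump(make_summary(c("rs1", "rs9"), c(1e-10, 1e-9),
                                           pos = c(1e6, 1.1e6)), ld),
                 "independent")
  expect_equal(out$rsid, c("rs1", "rs9"))
})

test_that("clumping matches the brute-force greedy oracle on random instances", {
  withr::with_seed(2024, {
    for (rep in 1:30) {
      n <- sample(5:25, 1)
      rsids <- sprintf("rs%03d", sample(1:999, n))
      data <- make_summary(rsids, runif(n, 1e-12, 1e-6),
                           chrom = as.character(sample(1:3, n, replace = TRUE)),
                           pos = runif(n, 1, 3e7))
      pairs <- t(combn(n, 2))
      r2 <- runif(nrow(pairs))
      # sprinkle exact-threshold and near-zero values
      r2[sample(length(r2), min(3, length(r2)))] <- 0.001
      ld <- ld_table(tibble::tibble(rsid_a = rsids[pairs[, 1]],
                                    rsid_b = rsids[pairs[, 2]], r2 = r2))
      ld_mat <- matrix(NA_real_, n, n, dimnames = list(rsids, rsids))
      for (k in seq_len(nrow(pairs))) {
        ld_mat[pairs[k, 1], pairs[k, 2]] <- r2[k]
        ld_mat[pairs[k, 2], pairs[k, 1]] <- r2[k]
      }
      got <- clump(data, ld, r2_threshold = 0.001, window_kb = 10000)$rsid
      want <- oracle_clump(data, ld_mat, 0.001, 1e7)
      expect_equal(got, want)
    }
  })
})

test_that("secondary screening removes confounder hits below threshold only", {
  s <- make_summary(c("rs1", "rs2", "rs3"), c(1e-9, 1e-9, 1e-9))
  tab <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    phenotype_label = c("hypertension", "diabetes", "height"),
    pvalue = c(1e-9, 1e-6, 1e-20),
    category = c("confounder", "confounder", "other")
  )
  out <- suppressMessages(screen_secondary(s, tab))
  expect_equal(out$rsid, c("rs2", "rs3"))
  expect_equal(screen_secondary(s, tab[0, ]), s)
  expect_equal(screen_secondary(s, NULL), s)
})

test_that("F-statistic is (beta/se)^2 and errors on non-positive se", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0.02, 0.02), 1)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_error(f_statistic(0.1, 0), class = "panelmr_domain_error")
})

test_that("strength filter is strict at F = threshold and idempotent", {
  # integer-exact F values so the boundary test is a true equality: F = {4, 36, 1}
  s <- make_summary(c("rs1", "rs2", "rs3"), rep(1e-9, 3),
                    beta = c(4, 12, 2), se = c(2, 2, 2))
  out <- filter_strength(s, f_threshold = 4)
  expect_equal(out$rsid, "rs2")      # F exactly at the threshold removed
  expect_equal(out$f_stat, 36)
  expect_equal(filter_strength(out)$rsid, out$rsid)
  # reported F equals direct recomputation over the retained set
  expect_equal(range(out$f_stat), range((out$beta / out$se)^2))
})

test_that("selection provenance covers every SNP exactly once, in stage order", {
  ld <- ld_table(tibble::tibble(rsid_a = "rs2", rsid_b = "rs3", r2 = 0.8))
  s <- make_summary(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                    c(0.5, 1e-10, 1e-9, 1e-9, 1e-9),
                    pos = c(1e6, 2e6, 2.5e6, 5e7, 6e7),
                    beta = c(0.1, 0.1, 0.1, 0.1, 0.02),
                    se = c(0.01, 0.01, 0.01, 0.01, 0.01))
  tab <- tibble::tibble(rsid = "rs4", phenotype_label = "cardiovascular disease",
                        pvalue = 1e-12, category = "outcome_related")
  inst <- suppressMessages(select_instruments(s, ld, tab))
  prov <- instrument_provenance(inst)
  expect_equal(nrow(prov), 5)
  expect_equal(sort(prov$rsid), sort(s$rsid))
  expect_equal(prov$stage[prov$rsid == "rs1"], "significance")
  expect_equal(prov$stage[prov$rsid == "rs3"], "clump")
  expect_equal(prov$stage[prov$rsid == "rs4"], "secondary")
  expect_equal(prov$stage[prov$rsid == "rs5"], "strength")
  expect_equal(inst$rsid, "rs2")
  expect_true(all(inst$pvalue < 5e-8 & inst$f_stat > 10))
})
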
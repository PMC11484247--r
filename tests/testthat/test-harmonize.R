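make_inst <- function(rsid, ea, oa, beta = 0.1, se = 0.01, eaf = 0.3) {
  tibble::tibble(rsid = rsid, chrom = "1", pos = seq_along(rsid) * 1e6,
                 effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pvalue = 1e-9, n = 10000)
}

test_that("allele swaps flip the outcome sign and frequency", {
  inst <- make_inst("rs1", "A", "G", beta = 0.1)
  out <- make_inst("rs1", "G", "A", beta = 0.05, eaf = 0.7)
  h <- harmonize_pair(inst, out)
  expect_equal(h$beta_y, -0.05)
  expect_equal(h$eaf_y, 0.3)
  expect_equal(harmonization_log(h)$action, "sign_flipped")
})

test_that("palindromic SNPs are dropped regardless of outcome alleles", {
  inst <- make_inst(c("rs1", "rs2"), c("A", "C"), c("T", "G"))
  out <- make_inst(c("rs1", "rs2"), c("A", "C"), c("T", "G"), beta = 0.05)
  h <- suppressWarnings(harmonize_pair(inst, out))
  expect_equal(nrow(h), 0)
  expect_equal(harmonization_log(h)$action,
               rep("dropped_palindromic", 2))
})

test_that("strand complements resolve with and without a swap", {
  inst <- make_inst(c("rs1", "rs2"), c("A", "A"), c("G", "G"), beta = 0.1)
  out <- make_inst(c("rs1", "rs2"), c("T", "C"), c("C", "T"), beta = 0.05)
  h <- harmonize_pair(inst, out)
  expect_equal(h$beta_y, c(0.05, -0.05))
  expect_equal(harmonization_log(h)$action,
               c("strand_flipped", "strand_sign_flipped"))
})

test_that("incompatible and missing SNPs are dropped with conservation of counts", {
  inst <- make_inst(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "G"))
  out <- make_inst(c("rs1", "rs2"), c("A", "A"), c("G", "C"), beta = 0.05)
  h <- harmonize_pair(inst, out)
  log <- harmonization_log(h)
  expect_equal(log$action, c("kept", "dropped_incompatible", "dropped_missing"))
  expect_equal(nrow(h) + sum(startsWith(log$action, "dropped")), nrow(inst))
})

test_that("harmonization is an involution on a harmonized, palindrome-free pair", {
  sim <- simulate_pair(sim_config(n_snps = 25, theta = 0.2, seed = 11,
                                  palindromic_fraction = 0.3))
  inst <- filter_strength(filter_significant(sim$exposure))
  h1 <- harmonize_pair(inst, sim$outcome)
  expect_gt(nrow(h1), 0)
  # re-feed the harmonized records as exposure and outcome
  exp2 <- dplyr::transmute(h1, rsid, chrom, pos, effect_allele, other_allele,
                           eaf = eaf_x, beta = beta_x, se = se_x,
                           pvalue = 1e-9, n = 1e4)
  out2 <- dplyr::transmute(h1, rsid, chrom, pos, effect_allele, other_allele,
                           eaf = eaf_y, beta = beta_y, se = se_y,
                           pvalue = 0.5, n = 4e4)
  h2 <- harmonize_pair(exp2, out2)
  expect_equal(nrow(h2), nrow(h1))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_true(all(harmonization_log(h2)$action == "kept"))
})

test_that("optional frequency rescue keeps concordant low-MAF palindromic SNPs", {
  inst <- make_inst(c("rs1", "rs2"), c("A", "A"), c("T", "T"), eaf = 0.1)
  out <- make_inst(c("rs1", "rs2"), c("A", "A"), c("T", "T"),
                   beta = 0.05, eaf = c(0.12, 0.88))
  h <- harmonize_pair(inst, out, infer_palindromic = TRUE)
  expect_equal(harmonization_log(h)$action, c("kept", "sign_flipped"))
  expect_equal(h$beta_y, c(0.05, -0.05))
  # default behaviour still drops them
  h0 <- suppressWarnings(harmonize_pair(inst, out))
  expect_equal(nrow(h0), 0)
})

test_that("orientation negates jointly, preserves Wald ratios and the IVW estimate", {
  h <- random_harmonized(12, seed = 5)
  o <- orient_positive(h)
  expect_true(all(o$beta_x >= 0))
  wr_before <- wald_ratios(h)
  wr_after <- wald_ratios(o)
  ord <- order(wr_before$rsid)
  expect_equal(wr_after$ratio[ord], wr_before$ratio[ord])
  expect_equal(wr_after$ratio_se[ord], wr_before$ratio_se[ord])
  expect_equal(mr_ivw(o)$beta, mr_ivw(h)$beta, tolerance = 1e-15)
  # already-positive input is untouched
  expect_equal(orient_positive(o), o)
  # single explicit case
  one <- tibble::tibble(beta_x = -0.2, se_x = 0.01, beta_y = 0.1, se_y = 0.01)
  expect_equal(orient_positive(one)$beta_x, 0.2)
  expect_equal(orient_positive(one)$beta_y, -0.1)
})
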
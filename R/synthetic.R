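#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Builds and validates the generative parameters for [simulate_pair()] and
#' [simulate_panel()]. The generator emulates the statistical form of
#' two-sample MR inputs: per-SNP effect estimates are normally distributed
#' around their true values with standard errors
#' `1 / sqrt(2 n maf (1 - maf))` (the standardized-trait approximation,
#' optionally rescaled for a log-odds exposure), a true causal effect
#' `theta` propagates SNP-exposure effects into SNP-outcome effects, and
#' horizontal pleiotropy is configurable. Defaults mirror the shape of an
#' SLE case-control exposure GWAS (about 14k individuals) paired with a
#' 40k-participant imaging-trait outcome GWAS: roughly forty genome-wide
#' significant instruments with F-statistics in the tens to hundreds.
#'
#' @param n_snps Number of true instrument SNPs.
#' @param theta True causal effect of exposure on outcome.
#' @param n_exposure,n_outcome Effective sample sizes driving the SE model.
#' @param maf_range Interval within (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly.
#' @param gamma_dist True SNP-exposure effect distribution: one of
#'   `list(type = "fixed", value = g)`, `list(type = "normal", sd = s)`
#'   (zero-mean), or `list(type = "uniform", min = a, max = b)`. The uniform
#'   option provides positive, varying instrument strengths, which the
#'   MR-Egger design needs (a fixed gamma is collinear; a zero-mean gamma
#'   makes directional pleiotropy cancel after effect-allele orientation).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects),
#'   `"directional"` (mean `alpha_mean`), or `"outlier"` (a contaminated
#'   subset).
#' @param alpha_sd SD of per-SNP direct (pleiotropic) effects on the outcome.
#' @param alpha_mean Mean direct effect under `"directional"`.
#' @param outlier_fraction Fraction of instruments contaminated under
#'   `"outlier"` (the count is `round(fraction * n_snps)`).
#' @param outlier_magnitude Contamination size in per-SNP outcome-SE units:
#'   a contaminated SNP's direct effect is `magnitude * se_y_j * sign`, i.e.
#'   a displacement of `magnitude` ratio-SDs, with a random sign.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G allele
#'   pairs (removed wholesale by harmonization).
#' @param swap_fraction Fraction of outcome records emitted with effect and
#'   other allele interchanged (and beta/eaf adjusted), exercising
#'   harmonization's sign-flip path.
#' @param strand_flip_fraction Fraction of outcome records emitted on the
#'   opposite strand (alleles complemented), exercising the strand-flip path.
#' @param ld_block_spec Optional list of `list(size =, r2 =)` blocks; each
#'   block adds `size` duplicate-signal SNPs near an instrument, with the
#'   stated pairwise r-squared recorded in the LD table, exercising clumping.
#' @param null_snp_count Number of non-associated SNPs (gamma = 0) included
#'   to exercise the significance filter.
#' @param correlate_pleiotropy If `TRUE`, pleiotropic effects are made
#'   proportional in magnitude to instrument strength, violating the InSIDE
#'   assumption (for demonstrating, not asserting, Egger breakdown).
#' @param se_scale_exposure Multiplier on exposure SEs, mimicking a
#'   log-odds-scale binary exposure.
#' @param seed Mandatory integer seed; all generator randomness derives from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 40, theta = 0,
                       n_exposure = 14267, n_outcome = 40000,
                       maf_range = c(0.05, 0.5),
                       gamma_dist = list(type = "fixed", value = 0.15),
                       pleiotropy_mode = c("none", "balanced", "directional", "outlier"),
                       alpha_sd = 0.01, alpha_mean = 0.01,
                       outlier_fraction = 0.05, outlier_magnitude = 5,
                       palindromic_fraction = 0.15,
                       swap_fraction = 0.25, strand_flip_fraction = 0.05,
                       ld_block_spec = NULL, null_snp_count = 0,
                       correlate_pleiotropy = FALSE,
                       se_scale_exposure = 1, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  assert_scalar_number(n_snps, "n_snps", 1, Inf)
  assert_scalar_number(theta, "theta")
  assert_scalar_number(n_exposure, "n_exposure", 1, Inf, strict_lower = TRUE)
  assert_scalar_number(n_outcome, "n_outcome", 1, Inf, strict_lower = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]",
          class = "panelmr_config_error")
  }
  if (!is.list(gamma_dist) || is.null(gamma_dist$type) ||
      !gamma_dist$type %in% c("fixed", "normal", "uniform")) {
    abort("`gamma_dist` must be list(type = 'fixed'|'normal'|'uniform', ...)",
          class = "panelmr_config_error")
  }
  if (gamma_dist$type == "fixed") assert_scalar_number(gamma_dist$value, "gamma_dist$value")
  if (gamma_dist$type == "normal") assert_scalar_number(gamma_dist$sd, "gamma_dist$sd", 0, Inf, strict_lower = TRUE)
  if (gamma_dist$type == "uniform") {
    assert_scalar_number(gamma_dist$min, "gamma_dist$min")
    assert_scalar_number(gamma_dist$max, "gamma_dist$max", gamma_dist$min, Inf)
  }
  assert_scalar_number(alpha_sd, "alpha_sd", 0, Inf)
  assert_scalar_number(alpha_mean, "alpha_mean")
  assert_scalar_number(outlier_fraction, "outlier_fraction", 0, 1, strict_upper = TRUE)
  assert_scalar_number(outlier_magnitude, "outlier_magnitude", 0, Inf)
  assert_scalar_number(palindromic_fraction, "palindromic_fraction", 0, 1)
  assert_scalar_number(swap_fraction, "swap_fraction", 0, 1)
  assert_scalar_number(strand_flip_fraction, "strand_flip_fraction", 0, 1)
  assert_scalar_number(null_snp_count, "null_snp_count", 0, Inf)
  assert_scalar_number(se_scale_exposure, "se_scale_exposure", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(seed, "seed")
  if (!is.null(ld_block_spec)) {
    ok <- is.list(ld_block_spec) && all(vapply(ld_block_spec, function(b) {
      is.list(b) && is.numeric(b$size) && b$size >= 1 &&
        is.numeric(b$r2) && b$r2 >= 0 && b$r2 <= 1
    }, logical(1)))
    if (!ok) {
      abort("`ld_block_spec` must be a list of list(size =, r2 =) entries",
            class = "panelmr_config_error")
    }
  }
  structure(list(
    n_snps = as.integer(n_snps), theta = theta,
    n_exposure = n_exposure, n_outcome = n_outcome,
    maf_range = maf_range, gamma_dist = gamma_dist,
    pleiotropy_mode = pleiotropy_mode,
    alpha_sd = alpha_sd, alpha_mean = alpha_mean,
    outlier_fraction = outlier_fraction, outlier_magnitude = outlier_magnitude,
    palindromic_fraction = palindromic_fraction,
    swap_fraction = swap_fraction, strand_flip_fraction = strand_flip_fraction,
    ld_block_spec = ld_block_spec, null_snp_count = as.integer(null_snp_count),
    correlate_pleiotropy = isTRUE(correlate_pleiotropy),
    se_scale_exposure = se_scale_exposure, seed = as.integer(seed)
  ), class = "sim_config")
}

NONPALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# exposure-side scaffold: variant identities, frequencies, true effects
gen_scaffold <- function(config) {
  n_inst <- config$n_snps
  n_null <- config$null_snp_count
  blocks <- config$ld_block_spec %||% list()
  n_dup <- sum(vapply(blocks, function(b) as.integer(b$size), integer(1)))
  n_tot <- n_inst + n_null + n_dup

  maf <- stats::runif(n_tot, config$maf_range[1], config$maf_range[2])
  gamma <- switch(config$gamma_dist$type,
    fixed = rep(config$gamma_dist$value, n_tot),
    normal = stats::rnorm(n_tot, 0, config$gamma_dist$sd),
    uniform = stats::runif(n_tot, config$gamma_dist$min, config$gamma_dist$max)
  )
  type <- rep(c("instrument", "null"), c(n_inst, n_null))

  chrom <- as.character(rep_len(1:22, n_inst + n_null))
  pos <- 1e6 + 2e7 * (seq_len(n_inst + n_null) %/% 22)

  pal <- stats::runif(n_tot) < config$palindromic_fraction
  pair_idx_np <- sample.int(nrow(NONPALINDROMIC_PAIRS), n_tot, replace = TRUE)
  pair_idx_p <- sample.int(nrow(PALINDROMIC_PAIRS), n_tot, replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[pair_idx_p, 1], NONPALINDROMIC_PAIRS[pair_idx_np, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[pair_idx_p, 2], NONPALINDROMIC_PAIRS[pair_idx_np, 2])

  scaffold <- tibble(
    rsid = sprintf("rs%06d", seq_len(n_tot)),
    chrom = c(chrom, rep(NA_character_, n_dup)),
    pos = c(pos, rep(NA_real_, n_dup)),
    effect_allele = ea, other_allele = oa,
    maf = maf, gamma = gamma, type = c(type, rep("ld_dup", n_dup)),
    block = NA_integer_
  )
  scaffold$gamma[scaffold$type == "null"] <- 0

  # LD-block duplicates shadow an instrument's signal at a nearby position
  ld <- tibble(rsid_a = character(), rsid_b = character(), r2 = double())
  if (n_dup > 0) {
    cursor <- n_inst + n_null
    for (bi in seq_along(blocks)) {
      size <- as.integer(blocks[[bi]]$size)
      anchor <- ((bi - 1L) %% n_inst) + 1L
      members <- anchor
      for (k in seq_len(size)) {
        cursor <- cursor + 1L
        scaffold$chrom[cursor] <- scaffold$chrom[anchor]
        scaffold$pos[cursor] <- scaffold$pos[anchor] + 5e4 * k
        scaffold$gamma[cursor] <- scaffold$gamma[anchor]
        scaffold$block[cursor] <- bi
        members <- c(members, cursor)
      }
      pairs <- utils::combn(members, 2)
      ld <- bind_rows(ld, tibble(
        rsid_a = scaffold$rsid[pairs[1, ]],
        rsid_b = scaffold$rsid[pairs[2, ]],
        r2 = blocks[[bi]]$r2
      ))
    }
  }
  list(scaffold = scaffold, ld = ld_table(ld))
}

# per-SNP direct effects on one outcome trait under the configured
# pleiotropy regime; magnitudes in outcome-SE units for the outlier mode
gen_alpha <- function(config, scaffold, se_y) {
  n <- nrow(scaffold)
  alpha <- rep(0, n)
  outlier <- rep(FALSE, n)
  inst <- which(scaffold$type != "null")
  if (config$pleiotropy_mode == "balanced") {
    alpha[inst] <- stats::rnorm(length(inst), 0, config$alpha_sd)
  } else if (config$pleiotropy_mode == "directional") {
    alpha[inst] <- stats::rnorm(length(inst), config$alpha_mean, config$alpha_sd)
  } else if (config$pleiotropy_mode == "outlier") {
    k <- round(config$outlier_fraction * length(inst))
    if (k > 0) {
      chosen <- sample(inst, k)
      outlier[chosen] <- TRUE
      alpha[chosen] <- config$outlier_magnitude * se_y[chosen] *
        sample(c(-1, 1), k, replace = TRUE)
    }
  }
  if (config$correlate_pleiotropy && config$pleiotropy_mode %in% c("balanced", "directional")) {
    # scale direct effects by relative instrument strength: InSIDE violated
    rel <- abs(scaffold$gamma[inst]) / max(abs(scaffold$gamma[inst]), 1e-12)
    alpha[inst] <- alpha[inst] * rel * 2
  }
  list(alpha = alpha, outlier = outlier)
}

se_model <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

gen_exposure <- function(config, scaffold, trait_id = "exposure") {
  se_x <- se_model(config$n_exposure, scaffold$maf) * config$se_scale_exposure
  beta_x <- stats::rnorm(nrow(scaffold), scaffold$gamma, se_x)
  tibble(
    trait_id = trait_id, trait_label = trait_id, category = "exposure",
    ancestry = "European",
    rsid = scaffold$rsid, chrom = scaffold$chrom, pos = scaffold$pos,
    effect_allele = scaffold$effect_allele, other_allele = scaffold$other_allele,
    eaf = scaffold$maf, beta = beta_x, se = se_x,
    pvalue = z_pvalue(beta_x, se_x), n = config$n_exposure
  )
}

gen_outcome <- function(config, scaffold, theta, trait_id, trait_label = trait_id,
                        category = "other") {
  n <- nrow(scaffold)
  se_y <- se_model(config$n_outcome, scaffold$maf)
  pl <- gen_alpha(config, scaffold, se_y)
  beta_y <- stats::rnorm(n, theta * scaffold$gamma + pl$alpha, se_y)
  out <- tibble(
    trait_id = trait_id, trait_label = trait_label, category = category,
    ancestry = "European",
    rsid = scaffold$rsid, chrom = scaffold$chrom, pos = scaffold$pos,
    effect_allele = scaffold$effect_allele, other_allele = scaffold$other_allele,
    eaf = scaffold$maf, beta = beta_y, se = se_y,
    pvalue = z_pvalue(beta_y, se_y), n = config$n_outcome
  )
  # vary the outcome's allele representation to exercise harmonization
  u <- stats::runif(n)
  swap <- u < config$swap_fraction
  flip <- u >= config$swap_fraction &
    u < config$swap_fraction + config$strand_flip_fraction
  ea <- out$effect_allele
  out$effect_allele[swap] <- out$other_allele[swap]
  out$other_allele[swap] <- ea[swap]
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  out$effect_allele[flip] <- complement_allele(out$effect_allele[flip])
  out$other_allele[flip] <- complement_allele(out$other_allele[flip])
  list(outcome = out, alpha = pl$alpha, outlier = pl$outlier)
}

#' Simulate one exposure/outcome GWAS summary pair
#'
#' Generates matched exposure and outcome summary statistics under the
#' configured causal effect and pleiotropy regime, along with the LD table
#' the clumping stage consumes and the per-SNP ground truth. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (summary tibbles),
#'   `ld` (an [ld_table()]), and `truth` (per-SNP tibble of `gamma`,
#'   `alpha`, `outlier`, `type`, plus attribute `"theta"`).
#' @export
simulate_pair <- function(config) {
  sim <- simulate_panel(config, n_traits = 1)
  list(exposure = sim$exposure, outcome = sim$outcomes[[1]], ld = sim$ld,
       truth = sim$truth)
}

#' Simulate a panel of outcome traits sharing one exposure
#'
#' One exposure summary set is generated, then `n_traits` outcome sets with
#' trait-specific causal effects, emulating a many-outcome imaging-trait
#' design. Trait categories are assigned round-robin over LA, LV, RA, RV,
#' AAO, DAO.
#'
#' @param config A [sim_config()]; `config$theta` is the default effect for
#'   traits not named in `effect_map`.
#' @param n_traits Number of outcome traits.
#' @param effect_map Optional numeric vector of per-trait causal effects,
#'   either unnamed of length `n_traits` or named by trait id
#'   (`"trait_01"`, ...).
#' @return A list with `exposure`, `outcomes` (named list of summary
#'   tibbles), `ld`, and `truth` (per-SNP tibble with per-trait `alpha_*`
#'   columns; attribute `"trait_effects"` maps trait id to true theta).
#' @export
simulate_panel <- function(config, n_traits = 1, effect_map = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config()", class = "panelmr_config_error")
  }
  assert_scalar_number(n_traits, "n_traits", 1, Inf)
  n_traits <- as.integer(n_traits)
  trait_ids <- sprintf("trait_%02d", seq_len(n_traits))
  thetas <- rep(config$theta, n_traits)
  names(thetas) <- trait_ids
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map))) {
      if (length(effect_map) != n_traits) {
        abort("unnamed `effect_map` must have length n_traits",
              class = "panelmr_config_error")
      }
      thetas[] <- effect_map
    } else {
      bad <- setdiff(names(effect_map), trait_ids)
      if (length(bad) > 0) {
        abort(sprintf("unknown trait id in effect_map: %s", bad[1]),
              class = "panelmr_config_error")
      }
      thetas[names(effect_map)] <- effect_map
    }
  }
  categories <- rep_len(c("LA", "LV", "RA", "RV", "AAO", "DAO"), n_traits)

  with_seed(config$seed, {
    sc <- gen_scaffold(config)
    exposure <- gen_exposure(config, sc$scaffold)
    outcomes <- list()
    truth <- dplyr::select(sc$scaffold, "rsid", "type", "block", "maf", "gamma")
    outlier_any <- rep(FALSE, nrow(truth))
    for (i in seq_len(n_traits)) {
      g <- gen_outcome(config, sc$scaffold, thetas[i], trait_ids[i],
                       category = categories[i])
      outcomes[[trait_ids[i]]] <- g$outcome
      truth[[paste0("alpha_", trait_ids[i])]] <- g$alpha
      outlier_any <- outlier_any | g$outlier
    }
    truth$outlier <- outlier_any
    attr(truth, "theta") <- unname(thetas[1])
    attr(truth, "trait_effects") <- tibble(trait_id = trait_ids,
                                           theta = unname(thetas),
                                           category = categories)
    list(exposure = exposure, outcomes = outcomes, ld = sc$ld, truth = truth)
  })
}
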
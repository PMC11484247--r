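---
title: "Two-sample Mendelian randomization with panelmr: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with panelmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmr)
```

## The causal model

Two-sample MR treats each genetic variant $j$ as an instrument for an
exposure $X$ acting on an outcome $Y$. With summary statistics
$(\hat\beta_{Xj}, \sigma_{Xj})$ from an exposure GWAS and
$(\hat\beta_{Yj}, \sigma_{Yj})$ from an independent outcome GWAS, the
structural assumption is

$$\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j,$$

where $\theta$ is the causal effect and $\alpha_j$ is the variant's direct
(horizontally pleiotropic) effect on the outcome, zero for a valid
instrument. Every estimator in the package is a different compromise over
the unknown $\alpha_j$:

* the per-SNP **Wald ratio** $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
  with first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$;
* **IVW** pools ratios with weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$,
  assuming all $\alpha_j = 0$;
* **MR-Egger** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with an
  intercept, consistent for $\theta$ when pleiotropy is independent of
  instrument strength (InSIDE), with the intercept estimating mean
  directional pleiotropy;
* the **weighted median** of the ratios is consistent when valid
  instruments carry more than 50% of the weight;
* **MR-PRESSO** asks whether the residual dispersion of the observed
  effects around the IVW fit exceeds what its own sampling model predicts,
  and which individual SNPs are responsible.

## Heterogeneity and the fixed/random rule

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ is referred to
$\chi^2_{n-1}$. Following the convention used in applied two-sample MR
screens, `mr_ivw(model = "auto")` reports the fixed-effects standard error
$(\sum_j w_j)^{-1/2}$ when the $Q$ p-value exceeds 0.05, and otherwise a
*multiplicative* random-effects standard error, the fixed value inflated by
$\max(1, \sqrt{Q/(n-1)})$. The multiplicative form was chosen over an
additive (DerSimonian–Laird-style) component because it is the standard
choice for summary-data MR and can never shrink the interval below the
fixed-effects one; the floor at 1 keeps under-dispersed samples at the
fixed-effects width.

Inference uses a two-sided normal reference for IVW and the weighted
median, and a $t_{n-2}$ reference for both MR-Egger coefficients: Egger
estimates two parameters from few points, so the normal reference would be
anti-conservative at typical instrument counts. All 95% intervals are
symmetric (estimate $\pm$ quantile $\times$ SE); published MR tables
sometimes show asymmetric intervals produced by rounding or
transformation, which the package deliberately does not imitate.

## Instrument selection

The four stages run in a fixed order — significance, LD clumping,
secondary-phenotype screening, instrument strength — and both inequality
thresholds are strict (`P < 5e-8`, `F > 10`), matching the usual wording
of selection criteria. Clumping is the standard greedy procedure: take the
most significant remaining SNP as an index (p-value ties broken by genomic
position then rsid, for determinism), remove every SNP on the same
chromosome strictly within the window whose known $r^2$ with the index is
at or above the threshold, repeat. A pair exactly at the window distance
is outside the window; an $r^2$ exactly at the threshold is removed. Pairs
absent from the LD table are treated as independent — in the synthetic
data absence genuinely means unlinked, and the treatment is messaged so
users supplying sparse real LD tables can audit it.

The secondary-association table replaces live PhenoScanner queries with an
offline file of (rsid, phenotype, p-value, category) rows; SNPs with an
`outcome_related` or `confounder` association below the significance
threshold are removed, which captures exactly what an interactive lookup
would have screened on without a network dependency.

## Harmonization

Matching is by rsid alone, not position, because the two GWAS may sit on
different genome builds; positions are treated as opaque coordinates
within each dataset. Missing SNPs are dropped (and logged), never proxied.
Palindromic SNPs are removed unconditionally by default. An optional
frequency-based rescue (`infer_palindromic = TRUE`) keeps palindromic SNPs
whose minor-allele frequency is below 0.3 in both datasets, resolving
orientation from frequency concordance; it is off by default because
unconditional removal is the more conservative, more reproducible choice.

Effect-allele orientation (all $\hat\beta_{Xj} \ge 0$) is applied inside
the MR-Egger path only: IVW and the median are invariant to per-SNP sign
relabelling, and leaving the stored harmonized set untouched makes audits
against the input files straightforward.

## MR-PRESSO internals

The observed statistic sums weighted squared residuals around
leave-one-out IVW predictions,
$r_j = (\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2/\sigma_{Yj}^2$,
so an outlying SNP cannot mask itself through its own influence on the
fit. The null distribution resamples
$\beta_{Xj}^* \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$ and
$\beta_{Yj}^* \sim N(\hat\theta_{(-j)}\hat\beta_{Xj}, \sigma_{Yj}^2)$ and
recomputes the statistic identically, including the leave-one-out fits on
the simulated data. Empirical p-values use the add-one correction,
$(1 + \#\{\cdot\})/(n_{\mathrm{sim}}+1)$, so they are never zero and their
resolution is transparent; per-SNP outlier p-values are
Bonferroni-adjusted by the SNP count. When outliers are flagged, the
reduced set is re-fitted with the same $Q$-gated IVW rule as the primary
analysis, and the distortion test compares the percent change in estimate
against random removals of equally many SNPs. The default
$n_{\mathrm{sim}} = 1000$ resolves p-values to $10^{-3}$ in well under a
second at typical instrument counts.

## The synthetic generator

The generator emulates the statistical form of the data a two-sample MR
consumes, not the biology that produced it. For each SNP a minor-allele
frequency is drawn uniformly from `maf_range`, and standard errors follow
the standardized-trait approximation
$\sigma = 1/\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}$; estimates are
normal around their true values, $\hat\beta_{Xj} \sim N(\gamma_j,
\sigma_{Xj}^2)$ and $\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j,
\sigma_{Yj}^2)$, with two-sided normal p-values. The defaults are fixed to
the shape of a case-control autoimmune-disease exposure GWAS of about
14,000 individuals paired with a 40,000-participant imaging-trait outcome
GWAS: 40 instruments with per-allele effect 0.15 give F-statistics of
roughly 30–160 across the frequency range, the same order (tens to
hundreds) seen in that design. Pleiotropy regimes: `none`; `balanced`
($\alpha_j$ zero-mean normal); `directional` (mean `alpha_mean`, the
regime the Egger intercept estimates); `outlier`, where a `round(fraction
× n)` subset receives a direct effect of `outlier_magnitude` per-SNP
outcome standard errors — i.e. a displacement of exactly that many
ratio-SDs, the unit in which outlier detectability is naturally stated —
with random sign. Palindromic allele pairs, swapped and strand-flipped
outcome records, LD-duplicate blocks and null SNPs exercise every
selection and harmonization path; all randomness derives from the
mandatory seed, and identical configurations yield byte-identical output
files.

`gamma_dist` offers three shapes. `fixed` reproduces the homogeneous-F
design of the defaults but is degenerate for MR-Egger: with no true spread
in instrument strength the regression's x-variation is pure noise, the
slope is fully attenuated and the intercept absorbs the causal signal (the
classic violation of the no-measurement-error condition). `normal` is
zero-mean, which makes directional pleiotropy cancel after effect-allele
orientation. The `uniform` option (positive range) therefore exists for
any study of the Egger estimator, and is what the Egger recovery tests
use. A `correlate_pleiotropy` flag scales direct effects with instrument
strength to *demonstrate* InSIDE violation; nothing is asserted about
Egger's behaviour there.

## What passing tests do and do not show

The generator draws independent SNPs with exactly normal, exactly
calibrated errors. Real summary data add genome-wide LD beyond the
explicit pairwise table, participant overlap between the two samples,
liability-scale effects for binary exposures, imputation-quality
variation, and mis-specified sample sizes — none of which are emulated.
Calibration and recovery results on the synthetic data therefore validate
the *estimators and plumbing*, not any real-data conclusion.

Replicated checks run in a strong-instrument regime (per-allele effect
0.5, exposure n = 100,000). This is deliberate: the two-sample IVW
estimate carries a finite-sample attenuation of order $\theta/\bar F$, so
at the default case-control scale ($\bar F \approx 120$) a 500-replicate
mean-bias test would detect that real, well-understood weak-instrument
attenuation rather than an implementation error. Raising $\bar F$ to
$\sim 9000$ pushes the attenuation an order of magnitude below the
Monte-Carlo resolution, making the bias test a check of the code rather
than of asymptotics. Problem sizes used by the test suite: 2,000
replicates for null calibration, 500 for recovery and coverage, 200
(at 500 internal simulations) for outlier-detection power, 30 random
instances for the clumping oracle, and 20 for estimator-oracle
equivalence.

## Panel conventions

The panel driver selects instruments once per exposure, shares them across
outcomes, and records per-outcome instrument counts after harmonization —
outcome-to-outcome variation in usable SNPs (a familiar feature of
published screens, e.g. "39–41 instruments" across traits) arises from
missingness and palindromic loss, not re-selection. Significance is
nominal at $\alpha = 0.05$ with no correction across traits, matching
common practice for hypothesis-generating panels; Benjamini–Hochberg
adjustment is available explicitly via `adjust_multiplicity(panel, "bh")`
and annotates rather than overwrites the nominal flags. Directional
consistency across IVW, Egger and the median treats an exact zero as
agreeing with either sign. Per-trait seeds derive deterministically from
the run seed (`seed + trait index`), so a panel is reproducible
end-to-end, byte for byte.

## Degenerate inputs and numerical choices

* A single harmonized SNP yields its Wald ratio with `model = "n/a"` and
  no heterogeneity statistic; MR-Egger requires 3 SNPs, MR-PRESSO 4.
* `beta_x = 0` is a domain error naming the SNP (precluded in practice by
  the F filter).
* The weighted median interpolates linearly at the 0.5 crossing of the
  half-offset cumulative weights and clamps to the extreme ratios when the
  crossing falls outside the grid; SNPs are sorted by ratio (then rsid)
  before bootstrap resampling so the standard error is invariant to input
  row order at a fixed seed.
* Simulated p-values are floored at `1e-300` to honour the $(0,1]$
  contract under extreme z-scores.
* Parsers drop and count rows violating the per-variant contract rather
  than failing the file; zero valid rows is an error. Indels and
  multi-allelic records are rejected at parse time because the
  harmonization rules assume biallelic SNVs.

## Known limitations

No proxy-SNP substitution for instruments missing from an outcome; no
reference-panel $r^2$ computation (the LD table must be supplied); no
Steiger filtering, mode-based or multivariable estimators; no liability
-scale modelling of binary traits; forest plots are deliberately minimal.
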
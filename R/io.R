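#' Read a GWAS summary-statistics table
#'
#' Parses a delimited text file of per-variant association statistics into the
#' tidy summary format used throughout the package: one row per variant with
#' columns `trait_id`, `trait_label`, `category`, `ancestry`, `rsid`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' Rows violating the per-variant contract (non-ACGT or identical alleles,
#' `se <= 0`, p-value outside (0, 1], allele frequency outside (0, 1),
#' multi-character alleles such as indels) are dropped and counted; the drop
#' count is reported via a message and stored in the `"n_dropped"` attribute.
#'
#' @param path Path to a delimited text file with a header line.
#' @param column_map Named character vector mapping the canonical column names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n`) to the names used in the file. Canonical names absent
#'   from the map are assumed to appear verbatim in the header. `eaf` and `n`
#'   are optional and filled with `NA` when the file lacks them.
#' @param trait_id Identifier for the trait the file describes.
#' @param trait_label Human-readable trait name (defaults to `trait_id`).
#' @param category Trait category; one of `"exposure"`, `"LA"`, `"LV"`,
#'   `"RA"`, `"RV"`, `"AAO"`, `"DAO"`, `"other"`.
#' @param ancestry Ancestry label carried through to output (default
#'   `"European"`).
#' @param delim Field delimiter, tab by default.
#' @return A tibble of validated variant associations, one row per variant,
#'   unique by `rsid`.
#' @export
read_summary_set <- function(path, column_map = NULL, trait_id,
                             trait_label = trait_id, category = "other",
                             ancestry = "European", delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("summary-statistics file not found: %s", path),
          class = "panelmr_io_error")
  }
  category <- match.arg(category, TRAIT_CATEGORIES)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, na = c("NA", ""))
  canonical <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  mandatory <- setdiff(canonical, c("eaf", "n"))
  absent <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(absent) > 0) {
    abort(sprintf("mapped column%s not found in header: %s",
                  if (length(absent) > 1) "s" else "",
                  paste(map[absent], collapse = ", ")),
          class = "panelmr_config_error")
  }
  get_col <- function(nm) {
    if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else rep(NA_character_, nrow(raw))
  }
  parsed <- tibble(
    trait_id = trait_id,
    trait_label = trait_label,
    category = category,
    ancestry = ancestry,
    rsid = get_col("rsid"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.numeric(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n = suppressWarnings(as.numeric(get_col("n")))
  )
  out <- validate_summary(parsed)
  if (nrow(out) == 0) {
    abort(sprintf("no valid variant rows in %s", path), class = "panelmr_io_error")
  }
  out
}

TRAIT_CATEGORIES <- c("exposure", "LA", "LV", "RA", "RV", "AAO", "DAO", "other")

# drops rows violating the variant contract; attaches the count as an
# attribute and messages it so parses are auditable
validate_summary <- function(data) {
  ok <- !is.na(data$rsid) & data$rsid != "" &
    data$effect_allele %in% VALID_BASES &
    data$other_allele %in% VALID_BASES &
    data$effect_allele != data$other_allele &
    !is.na(data$beta) & is.finite(data$beta) &
    !is.na(data$se) & data$se > 0 &
    !is.na(data$pvalue) & data$pvalue > 0 & data$pvalue <= 1 &
    (is.na(data$eaf) | (data$eaf > 0 & data$eaf < 1))
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  out <- data[ok, , drop = FALSE]
  dup <- duplicated(out$rsid)
  if (any(dup)) {
    dropped <- dropped + sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  if (dropped > 0) {
    inform(sprintf("dropped %d invalid or duplicate variant row%s",
                   dropped, if (dropped > 1) "s" else ""))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_set()]: writes the variant columns as
#' tab-delimited text so that a write/read round trip reproduces all fields.
#'
#' @param data A summary tibble as produced by [read_summary_set()] or
#'   [simulate_pair()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `data`, invisibly.
#' @export
write_summary_set <- function(data, path, delim = "\t") {
  cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  check_columns(data, cols, "summary set")
  readr::write_delim(dplyr::select(data, dplyr::all_of(cols)), path, delim = delim)
  invisible(data)
}

#' Read a pairwise linkage-disequilibrium table
#'
#' Reads a three-column delimited file (`rsid_a`, `rsid_b`, `r2`) of pairwise
#' squared correlations. Lookups through [ld_lookup()] are symmetric; pairs
#' absent from the table return `NA` ("unknown"), which is distinct from an
#' explicit `r2` of zero.
#'
#' @param path Path to the delimited file. An empty (header-only) file yields
#'   a valid table where every lookup is unknown.
#' @param delim Field delimiter.
#' @return A tibble of class `ld_table` with columns `rsid_a`, `rsid_b`, `r2`.
#' @export
read_ld_table <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("LD table file not found: %s", path), class = "panelmr_io_error")
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(
                             rsid_a = "c", rsid_b = "c", r2 = "d"
                           ),
                           progress = FALSE)
  check_columns(raw, c("rsid_a", "rsid_b", "r2"), "LD table")
  ld_table(raw)
}

#' Construct a linkage-disequilibrium table
#'
#' @param data A data frame with columns `rsid_a`, `rsid_b`, `r2`.
#' @return A validated tibble of class `ld_table`.
#' @export
ld_table <- function(data = tibble(rsid_a = character(), rsid_b = character(),
                                   r2 = double())) {
  check_columns(data, c("rsid_a", "rsid_b", "r2"), "LD table")
  data <- as_tibble(data)
  bad <- which(!is.na(data$r2) & (data$r2 < 0 | data$r2 > 1))
  if (length(bad) > 0) {
    abort(sprintf("r2 outside [0,1] at line %d", bad[1] + 1L),
          class = "panelmr_validation_error")
  }
  self <- which(data$rsid_a == data$rsid_b)
  if (length(self) > 0) {
    abort(sprintf("self-pair (%s, %s) at line %d is not allowed",
                  data$rsid_a[self[1]], data$rsid_b[self[1]], self[1] + 1L),
          class = "panelmr_validation_error")
  }
  structure(data, class = c("ld_table", class(tibble())))
}

#' Symmetric LD lookup
#'
#' @param ld An `ld_table`.
#' @param a,b Character vectors of rsids (recycled to common length).
#' @return Numeric vector of r-squared values; `NA` where the pair is not in
#'   the table (unknown, treated as unlinked by [clump()]).
#' @export
ld_lookup <- function(ld, a, b) {
  if (is.null(ld) || nrow(ld) == 0) {
    return(rep(NA_real_, max(length(a), length(b))))
  }
  key <- function(x, y) ifelse(x < y, paste(x, y), paste(y, x))
  tab <- stats::setNames(ld$r2, key(ld$rsid_a, ld$rsid_b))
  unname(tab[key(a, b)])
}

#' Read a secondary-phenotype association table
#'
#' Offline stand-in for PhenoScanner-style lookups: one row per known
#' association of an instrument SNP with a secondary phenotype, used by
#' [screen_secondary()] to drop potentially pleiotropic instruments.
#'
#' @param path Path to a delimited file with columns `rsid`,
#'   `phenotype_label`, `pvalue`, `category` (one of `outcome_related`,
#'   `confounder`, `other`).
#' @param delim Field delimiter.
#' @return A tibble with the four columns above.
#' @export
read_secondary_table <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(sprintf("secondary-association file not found: %s", path),
          class = "panelmr_io_error")
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(
                             rsid = "c", phenotype_label = "c",
                             pvalue = "d", category = "c"
                           ),
                           progress = FALSE)
  check_columns(raw, c("rsid", "phenotype_label", "pvalue", "category"),
                "secondary-association table")
  bad <- which(is.na(raw$pvalue) | raw$pvalue <= 0 | raw$pvalue > 1)
  if (length(bad) > 0) {
    abort(sprintf("pvalue outside (0,1] at line %d", bad[1] + 1L),
          class = "panelmr_validation_error")
  }
  as_tibble(raw)
}

#' Write a causal-estimate results table
#'
#' Writes panel or single-pair results as tab-delimited text with a fixed
#' column order (`trait_id`, `category`, `method`, `model`, `nsnp`, `beta`,
#' `se`, `ci_low`, `ci_high`, `pvalue`, `flags`). Numbers are serialized at
#' full precision (15 significant digits), so a read-back reproduces values.
#'
#' @param results A data frame of result rows; missing columns among the
#'   fixed set are filled with `NA`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `results`, invisibly.
#' @export
write_results_table <- function(results, path, delim = "\t") {
  cols <- c("trait_id", "category", "method", "model", "nsnp", "beta",
            "se", "ci_low", "ci_high", "pvalue", "flags")
  out <- as_tibble(results)
  for (nm in setdiff(cols, names(out))) out[[nm]] <- NA
  out <- dplyr::select(out, dplyr::all_of(cols))
  readr::write_delim(out, path, delim = delim)
  invisible(results)
}
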
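# internal helpers shared across modules

VALID_BASES <- c("A", "C", "G", "T")

complement_allele <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# two-sided normal p-value from an effect and its SE; floored away from 0 so
# the (0, 1] contract survives extreme z-scores
z_pvalue <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
}

# required-column check with a configuration-style error naming the column
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "panelmr_config_error"
    )
  }
  invisible(data)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a finite number in %s%s, %s%s",
                  name,
                  if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"),
          class = "panelmr_config_error")
  }
  invisible(x)
}

# deterministic seeded evaluation that leaves the caller's RNG stream intact
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
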
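#' Forest plot of panel results
#'
#' One point and 95% interval per outcome trait for a chosen method,
#' grouped by trait category — the summary view conventionally used for
#' many-outcome MR screens.
#'
#' @param object An `mr_panel` tibble.
#' @param method Which method's rows to draw (default the primary IVW).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_panel
#' @export
autoplot.mr_panel <- function(object, method = "IVW", ...) {
  rows <- object[object$method == method & object$status == "ok", , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no rows for method '%s'", method), class = "panelmr_input_error")
  }
  rows$significant_chr <- ifelse(is.na(rows$significant), FALSE, rows$significant)
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$trait_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant_chr)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 name = "significant") +
    ggplot2::labs(x = "causal estimate (95% CI)", y = NULL,
                  title = sprintf("%s estimates across the outcome panel", method))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a harmonized SNP set with fitted slopes
#'
#' Exposure versus outcome effects with per-SNP error bars, overlaid with
#' the IVW slope (through the origin) and, when estimable, the MR-Egger
#' line with its intercept.
#'
#' @param harmonized A harmonized tibble (see [harmonize_pair()]).
#' @param show_egger Overlay the MR-Egger fit (needs at least 3 SNPs).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(harmonized, show_egger = TRUE) {
  o <- orient_positive(harmonized)
  ivw <- mr_ivw(o)
  p <- ggplot2::ggplot(o, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_y - .data$se_y,
                                        ymax = .data$beta_y + .data$se_y),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_x - .data$se_x,
                                         xmax = .data$beta_x + .data$se_x),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta, colour = "steelblue") +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  title = "Harmonized SNP effects",
                  subtitle = sprintf("IVW slope %.4g", ivw$beta))
  if (show_egger && nrow(o) >= 3 && stats::var(o$beta_x) > 0) {
    eg <- mr_egger(o)
    p <- p + ggplot2::geom_abline(intercept = eg$intercept$beta,
                                  slope = eg$slope$beta,
                                  colour = "firebrick", linetype = "dotdash")
  }
  p
}
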
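#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline labs
#'   geom_errorbarh geom_vline scale_x_log10 theme_minimal geom_step
#' @export
ggplot2::autoplot

#' Quantile-quantile plot of burden-test p-values
#'
#' Observed against expected -log10 p-values over the tested genes, with
#' the identity line and the genomic inflation factor in the subtitle.
#'
#' @param object An `rg_burden`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rg_burden <- function(object, ...) {
  d <- tibble(p = sort(object$p)) |>
    mutate(expected = -log10((row_number() - 0.5) / n()),
           observed = -log10(.data$p))
  ggplot(d, aes(.data$expected, .data$observed)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    labs(x = expression(Expected ~ -log[10](p)),
         y = expression(Observed ~ -log[10](p)),
         title = "Gene burden test",
         subtitle = sprintf("%d genes, lambda = %.2f", nrow(object),
                            attr(object, "lambda"))) +
    theme_minimal()
}

#' Forest plot of a gene survival screen
#'
#' Hazard ratios with 95% confidence intervals per tested gene, ordered by
#' p-value.
#'
#' @param object An `rg_cox_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rg_cox_screen <- function(object, ...) {
  d <- as_tibble(unclass_result(object)) |>
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot(d, aes(x = .data$hr, y = .data$gene)) +
    geom_errorbarh(aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
                   height = 0.2, colour = "grey50") +
    geom_point(aes(colour = .data$significant), size = 2) +
    geom_vline(xintercept = 1, linetype = 2) +
    scale_x_log10() +
    labs(x = "Hazard ratio (95% CI)", y = NULL,
         title = sprintf("Carrier survival screen (%s)", object$outcome[1] %||% ""),
         colour = "q < threshold") +
    theme_minimal()
}

#' Kaplan-Meier plot of carriers vs non-carriers
#'
#' @param records Clinical tibble (see [cox_association()]).
#' @param carriers Carrier patient ids or logical indicator.
#' @param outcome `"os"` or `"ttft"`.
#' @return A ggplot of the two survival step curves.
#' @export
plot_survival <- function(records, carriers, outcome = c("os", "ttft")) {
  crv <- survival_curves(records, carriers, outcome)
  ggplot(crv, aes(.data$time, .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "Time (years)", y = "Survival probability", colour = NULL) +
    theme_minimal()
}
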
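#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_ribbon geom_line
#'   geom_histogram geom_abline labs facet_wrap theme_minimal
#'   scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot an enrichment envelope
#'
#' The machine twin of the total-mutations versus splice-site-mutation
#' scatter: per-gene observed counts coloured by category, with the
#' simulated envelope as a grey ribbon over the mutation-count range.
#'
#' @param object An `"ssm_envelope"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_envelope <- function(object, ...) {
  d <- tidy(object)
  ribbon <- d %>%
    group_by(.data$n_muts) %>%
    summarise(lower = min(.data$lower), upper = max(.data$upper), .groups = "drop")
  ggplot(d, aes(x = .data$n_muts, y = .data$observed)) +
    geom_ribbon(data = ribbon,
                aes(x = .data$n_muts, ymin = .data$lower, ymax = .data$upper),
                inherit.aes = FALSE, fill = "grey80", alpha = 0.7) +
    geom_point(aes(colour = .data$category), size = 1) +
    scale_colour_manual(values = c(Lower = "#2ca02c", Expected = "#1f77b4",
                                   Upper = "#d62728"), drop = FALSE) +
    labs(x = "total mutations", y = "splice-site mutations",
         colour = "category") +
    theme_minimal()
}

#' @rdname autoplot.ssm_envelope
#' @export
autoplot.splice_classifier <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#d62728") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("%s holdout ROC (AUC = %.3f)",
                         toupper(object$method), object$auc)) +
    theme_minimal()
}

#' Plot splice-site delta distributions by MAF stratum
#'
#' Histograms of the reference-minus-alternate PWM score difference
#' for rare versus common variants; depletion of large positive
#' deltas (site-abolishing) among common variants is the signature of
#' purifying selection.
#'
#' @param x A `"delta_strata"` result from [delta_strata_compare()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_delta_strata <- function(x, binwidth = 1) {
  stopifnot(inherits(x, "delta_strata"))
  ggplot(x$deltas, aes(x = .data$delta)) +
    geom_histogram(binwidth = binwidth, fill = "#1f77b4") +
    facet_wrap(~stratum, ncol = 1, scales = "free_y") +
    labs(x = "PWM delta (ref - alt; positive = weakening)", y = "variants") +
    theme_minimal()
}
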
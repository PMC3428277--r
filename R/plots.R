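# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a classifier comparison
#'
#' 1-specificity (FPR) against sensitivity (TPR), one labelled point per
#' classifier.
#'
#' @param object An `adir_comparison` from [compare_classifiers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adir_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$source), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$classifier),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "1 - specificity (FPR)", y = "Sensitivity (TPR)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a score-versus-age profile
#'
#' Signed classifier scores against age in years, coloured by the true
#' class; the zero line is the decision boundary and the shaded band the
#' low-confidence region.
#'
#' @param object An `adir_score_profile` from [score_profile()].
#' @param band Low-confidence band half-width drawn around zero.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adir_score_profile <- function(object, band = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age_years, y = .data$score,
                                       colour = .data$truth)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -band,
                      ymax = band, alpha = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Age (years)", y = "ADTree score", colour = "Diagnosis") +
    ggplot2::theme_minimal()
}

#' Plot an ADTree training curve
#'
#' Exponential loss after each boosting iteration.
#'
#' @param object A fitted `adtree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adtree <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iter, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Boosting iteration", y = "Exponential loss") +
    ggplot2::theme_minimal()
}
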
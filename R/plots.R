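# ggplot2 output --------------------------------------------------------------

#' ROC curve of a cross-validation run
#'
#' @param object An `lnc_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lnc_cv
#' @export
autoplot.lnc_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("LOOCV ROC (AUC = %.3f, %d folds)",
                      object$auc, nrow(object$folds))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a phenotype-by-lncRNA score landscape
#'
#' Scores are log10-transformed (with a small offset) so the sparse high
#' scores of seeded modules remain visible next to the background.
#'
#' @param object An `lnc_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lnc_landscape
#' @export
autoplot.lnc_landscape <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lncrna_id,
                                     y = .data$phenotype_id,
                                     fill = log10(.data$score + 1e-12))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 score") +
    ggplot2::labs(x = "lncRNA", y = "Phenotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' AUC profile of a parameter sweep
#'
#' @param sweep A tibble from [parameter_sweep()].
#' @param param Which parameter to place on the x axis (default `"delta"`).
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, param = "delta") {
  stopifnot(param %in% names(sweep))
  ok <- !is.na(sweep$auc)
  ggplot2::ggplot(sweep[ok, ],
                  ggplot2::aes(x = .data[[param]], y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = param, y = "LOOCV AUC") +
    ggplot2::theme_minimal()
}
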
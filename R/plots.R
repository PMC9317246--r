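#' Weight plot of a fitted PLS model
#'
#' The plane of the first two components with one point per parameter:
#' dots for predictors, triangles for responses, dashed lines at
#' +/- `threshold` marking the bound above which a weight is called
#' high.
#'
#' @param object A [fit_pls()] object with at least 2 components.
#' @param threshold Reference bound drawn on both axes, default 0.3.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_fit <- function(object, threshold = 0.3, ...) {
  pts <- weight_coordinates(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                    shape = .data$role)) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$parameter),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(predictor = 16, response = 17)) +
    ggplot2::labs(x = "weight, component 1", y = "weight, component 2",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Pre/post scatter of one biomarker
#'
#' Raw paired values per patient with the identity line; points above
#' the line increased over the study period.
#'
#' @param cohort Cohort tibble.
#' @param parameter Base name of a biomarker present as `<name>_I` and
#'   `<name>_F`.
#' @return A ggplot object.
#' @export
plot_paired <- function(cohort, parameter) {
  ci <- paste0(parameter, "_I")
  cf <- paste0(parameter, "_F")
  if (!all(c(ci, cf) %in% names(cohort))) {
    abort(paste0("no paired columns for '", parameter, "'"))
  }
  df <- tibble(initial = cohort[[ci]], final = cohort[[cf]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$initial, y = .data$final)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(title = parameter, x = "initial", y = "final") +
    ggplot2::theme_minimal()
}
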
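#' Plot PCA scores coloured by group
#'
#' @param object A [fit_pca()] result.
#' @param components Which two components to plot (default PC1 vs PC2).
#' @param groups Optional group labels aligned with the training samples.
#' @param highlight Optional tibble from [project_and_assign()] whose points
#'   (e.g. a projected singleton) are overplotted as crosses.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glycan_pca
#' @export
autoplot.glycan_pca <- function(object, components = c(1, 2), groups = NULL,
                                highlight = NULL, ...) {
  pcx <- paste0("PC", components[1])
  pcy <- paste0("PC", components[2])
  df <- object$scores
  df$group <- if (is.null(groups)) "sample" else as.character(groups)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[pcx]], .data[[pcy]],
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcx, 100 * object$explained[components[1]]),
      y = sprintf("%s (%.1f%%)", pcy, 100 * object$explained[components[2]])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(highlight) && all(c(pcx, pcy) %in% names(highlight))) {
    p <- p + ggplot2::geom_point(
      data = highlight, ggplot2::aes(.data[[pcx]], .data[[pcy]]),
      inherit.aes = FALSE, shape = 4, size = 4, stroke = 1.5, colour = "black")
  }
  p
}

#' Plot per-group age trends of a derived trait
#'
#' Scatter of trait versus age coloured by group with the fitted group
#' regression lines, faceted by cohort when several are present.
#'
#' @param data Data frame with the trait column, `group`, `age` and
#'   optionally `cohort`.
#' @param trait Trait column name.
#' @return A ggplot object.
#' @export
plot_trend_curves <- function(data, trait) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$age, .data[[trait]],
                                          colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "age (years)", y = paste0(trait, " (%)")) +
    ggplot2::theme_minimal()
  if ("cohort" %in% names(data) && length(unique(data$cohort)) > 1) {
    p <- p + ggplot2::facet_wrap(~cohort)
  }
  p
}

#' Plot the glycan-age shift across the age grid
#'
#' @param object An [age_shift()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_shift
#' @export
autoplot.age_shift <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$age, .data$shift)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "age (years)",
                  y = sprintf("%s glycan-age shift (years)", object$trait)) +
    ggplot2::theme_minimal()
}
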
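# ggplot2 visualisations for the main result classes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contact-frequency profile
#' @param object A [contact_frequencies()] or [aggregate_contacts()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pa_contact_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$resno), y = .data$f)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "contact frequency (%)",
                  title = "Enzyme-substrate contact frequencies") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pa_contact_profile
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pa_contact_profile_mean <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$resno),
                                       y = .data$mean_f)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_f - .data$sem_f,
                                        ymax = .data$mean_f + .data$sem_f),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "contact frequency (%)",
                  title = "Replica-mean contact frequencies (+/- SEM)") +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit with its data
#' @param object A [fit_mm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pa_mm_fit <- function(object, ...) {
  d <- object$data
  vmax <- object$coef$estimate[object$coef$term == "Vmax"]
  km <- object$coef$estimate[object$coef$term == "Km"]
  grid <- tibble::tibble(x = seq(0, max(d$x), length.out = 200))
  grid$rate <- vmax * grid$x / (km + grid$x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "loading / concentration", y = "rate",
                  title = sprintf("Michaelis-Menten fit (%s): Vmax = %.3g, Km = %.3g",
                                  object$model, vmax, km)) +
    ggplot2::theme_minimal()
}

#' Plot a melt curve with the fitted melting temperature
#' @param object A [extract_tm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pa_tm_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$temperature_C, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$tm, colour = "firebrick") +
    ggplot2::labs(x = "temperature (deg C)", y = "signal",
                  title = sprintf("Melt curve: Tm = %.1f deg C", object$tm)) +
    ggplot2::theme_minimal()
}

#' Plot a conservation profile with island annotations
#' @param object A [column_profile()] result.
#' @param islands Optional [variable_in_conserved()] result to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.pa_conservation_profile <- function(object, islands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "alignment position", y = "information content (bits)",
                  title = "Per-column conservation") +
    ggplot2::theme_minimal()
  if (!is.null(islands) && nrow(islands) > 0) {
    p <- p + ggplot2::geom_point(data = islands, colour = "firebrick", size = 2)
  }
  p
}

#' Bar chart of variant fold-changes
#' @param folds Tibble with `variant`, `fold`, `sem`.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = stats::reorder(.data$variant,
                                                         .data$fold),
                                      y = .data$fold)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold - .data$sem,
                                        ymax = .data$fold + .data$sem),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "variant", y = "fold-change vs parent",
                  title = "Variant activity fold-changes") +
    ggplot2::theme_minimal()
}
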
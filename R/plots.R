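# Zero concentrations cannot sit on a log axis; they are displayed half a
# decade below the smallest positive tested concentration (display only).
plot_conc <- function(conc) {
  cpos <- conc[conc > 0]
  ifelse(conc > 0, conc, min(cpos) / sqrt(10))
}

dataset_points <- function(dataset) {
  long <- tidy(dataset)
  long$plot_conc <- plot_conc(long$concentration)
  long
}

model_curve_df <- function(model, conc_range, label, n = 300L) {
  lgrid <- seq(log10(conc_range[1]), log10(conc_range[2]), length.out = n)
  tibble::tibble(configuration = label, concentration = 10^lgrid,
                 effect = eval_model(model, 10^lgrid))
}

#' Plot a single fitted configuration over the data
#'
#' @param object A `phase_fit`.
#' @param ... Unused.
#' @return A ggplot: replicate points and the fitted curve on a
#'   log-concentration axis.
#' @export
autoplot.phase_fit <- function(object, ...) {
  pts <- dataset_points(object$dataset)
  rng <- range(pts$plot_conc)
  crv <- model_curve_df(object$model, rng, object$configuration$label)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$plot_conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$effect), alpha = 0.7) +
    ggplot2::geom_line(data = crv,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$effect),
                       linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("concentration (%s)", object$dataset$unit),
      y = "normalized effect",
      title = sprintf("%s — %s", object$dataset$title,
                      object$configuration$label)
    ) +
    ggplot2::theme_minimal()
}

#' Plot all candidates of a selection over the data
#'
#' @param object A `phase_selection`.
#' @param best_only Draw only the winning candidate.
#' @param ... Unused.
#' @return A ggplot with one curve per fitted candidate (best one solid,
#'   others dashed).
#' @export
autoplot.phase_selection <- function(object, best_only = FALSE, ...) {
  pts <- dataset_points(object$dataset)
  rng <- range(pts$plot_conc)
  fitted <- object$candidates[!vapply(object$candidates, is.null, logical(1))]
  if (best_only) fitted <- fitted[object$best]
  crv <- purrr::map_dfr(names(fitted), function(lbl) {
    model_curve_df(fitted[[lbl]]$model, rng, lbl)
  })
  crv$best <- crv$configuration == object$best
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$plot_conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$effect), alpha = 0.6) +
    ggplot2::geom_line(data = crv,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$effect,
                                    colour = .data$configuration,
                                    linetype = .data$best),
                       linewidth = 0.7) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("concentration (%s)", object$dataset$unit),
      y = "normalized effect",
      title = sprintf("%s — best: %s", object$dataset$title,
                      object$best)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of phase classes in a batch
#'
#' @param batch A `phase_batch` from [run_batch()].
#' @return A ggplot bar chart of the class frequencies.
#' @export
plot_class_histogram <- function(batch) {
  stopifnot(inherits(batch, "phase_batch"))
  ggplot2::ggplot(batch$histogram,
                  ggplot2::aes(x = .data$phase_class,
                               y = .data$n_curves)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "phase class", y = "curves") +
    ggplot2::theme_minimal()
}
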
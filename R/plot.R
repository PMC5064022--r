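# ggplot2 quick-look graphics for each result type.

#' Plot a voltage-clamp recording
#'
#' Current traces over time, one colour per sweep (labelled by the test
#' voltage where present).
#'
#' @param object An `iks_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iks_recording <- function(object, ...) {
  vlab <- object |>
    dplyr::group_by(.data$sweep_id) |>
    dplyr::summarise(
      label = if (any(.data$segment == "test"))
        paste0(.data$voltage_mV[.data$segment == "test"][1L], " mV")
      else paste("sweep", .data$sweep_id[[1L]]),
      .groups = "drop")
  df <- dplyr::left_join(tibble::as_tibble(object), vlab, by = "sweep_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$current_uA,
                                   colour = .data$label,
                                   group = .data$sweep_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (uA)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted curve with its data
#'
#' Observed points plus the fitted curve; concentration axes are drawn on
#' a log10 scale.
#'
#' @param object An `iks_fit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iks_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  spec <- switch(object$family,
    hill = list(x = "concentration_M", y = "response", log = TRUE,
                xlab = "concentration (M)", ylab = "I_drug / I_max"),
    boltzmann = list(x = "voltage_mV", y = "response", log = FALSE,
                     xlab = "voltage (mV)", ylab = "normalized activation"),
    exponential = list(x = "time_s", y = "signal", log = FALSE,
                       xlab = "time (s)", ylab = "signal"),
    linear_log = list(x = "concentration_M", y = "tau_s", log = TRUE,
                      xlab = "concentration (M)", ylab = "tau (s)"))
  xs <- d[[spec$x]]
  grid <- if (spec$log) {
    10^seq(log10(min(xs)), log10(max(xs)), length.out = n_curve)
  } else {
    seq(min(xs), max(xs), length.out = n_curve)
  }
  curve_df <- tibble::tibble(x = grid, y = predict(object, grid))
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = tibble::tibble(x = xs, y = d[[spec$y]]),
      ggplot2::aes(.data$x, .data$y), alpha = 0.7) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(.data$x, .data$y),
                       colour = "firebrick") +
    ggplot2::labs(x = spec$xlab, y = spec$ylab,
                  title = paste0(object$family, " fit",
                                 if (!is.null(object$tag))
                                   paste0(" (", object$tag, ")") else "")) +
    ggplot2::theme_minimal()
  if (spec$log) p <- p + ggplot2::scale_x_log10()
  if (object$family == "linear_log") p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot wash-in time courses
#'
#' Normalized end-of-pulse amplitude versus time, one colour per ligand
#' concentration.
#'
#' @param object An `iks_washin`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iks_washin <- function(object, ...) {
  df <- dplyr::mutate(object$amplitudes,
                      conc = factor(format(.data$concentration_M,
                                           scientific = TRUE)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$norm_amplitude,
                                   colour = .data$conc)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time since drug application (s)",
                  y = "normalized end-pulse amplitude",
                  colour = "concentration (M)") +
    ggplot2::theme_minimal()
}

#' Plot the simulated gating-modifier report
#'
#' Normalized tail-current activation curves for the drug-free and
#' drug-bound configurations with their Boltzmann fits.
#'
#' @param object An `iks_fig9_report` from [reproduce_fig9()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iks_fig9_report <- function(object, ...) {
  tails <- object$tails
  grid <- seq(min(tails$voltage_mV), max(tails$voltage_mV),
              length.out = 200)
  curves <- dplyr::bind_rows(
    tibble::tibble(condition = "control", voltage_mV = grid,
                   activation = predict(object$fits$control, grid)),
    tibble::tibble(condition = "drug-bound", voltage_mV = grid,
                   activation = predict(object$fits$bound, grid)))
  ggplot2::ggplot(tails, ggplot2::aes(.data$voltage_mV, .data$activation,
                                      colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_colour_manual(values = c(control = "black",
                                            `drug-bound` = "firebrick")) +
    ggplot2::labs(x = "prepulse potential (mV)",
                  y = "normalized tail current", colour = NULL) +
    ggplot2::theme_minimal()
}
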
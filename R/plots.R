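#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated voltage trace
#'
#' Voltage against time with the spike-registration threshold drawn as
#' a dashed line.
#'
#' @param object a [simulate_neuron()] trajectory.
#' @param from start of the plotted window (defaults to the start).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.da_trajectory <- function(object, from = 0, ...) {
  thr <- attr(object, "params")$v_spike
  unit <- if (attr(object, "model") == "biophysical") "ms" else "s"
  df <- object[object$time >= from, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = sprintf("time (%s)", unit),
                  y = "membrane potential",
                  title = sprintf("%s model", attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' Plot a frequency curve
#'
#' @param object a [frequency_curve()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.da_frequency_curve <- function(object, ...) {
  lab <- if (attr(object, "vary") == "nmda") "NMDAR conductance"
         else "AMPAR conductance"
  ggplot2::ggplot(object[object$regime == "firing", ],
                  ggplot2::aes(.data$conductance, .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = lab, y = "firing frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a frequency map over the conductance plane
#'
#' Heat map of steady firing frequency over the (AMPAR, NMDAR)
#' conductance plane; non-firing regions are left blank.  Optional
#' rays `g_ampa = ratio * g_nmda` can be overlaid.
#'
#' @param object a [frequency_map()] result.
#' @param ratio_lines numeric vector of AMPA/NMDA ratios to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.da_frequency_map <- function(object, ratio_lines = NULL, ...) {
  p <- ggplot2::ggplot(object[object$regime == "firing", ],
                       ggplot2::aes(.data$g_nmda, .data$g_ampa,
                                    fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Hz") +
    ggplot2::labs(x = "NMDAR conductance", y = "AMPAR conductance") +
    ggplot2::theme_minimal()
  for (r in ratio_lines) {
    p <- p + ggplot2::geom_abline(slope = r, intercept = 0,
                                  colour = "white", linewidth = 0.4)
  }
  p
}

#' Phase-plane portrait of the minimal model
#'
#' Draws the v- and w-nullclines for one or more NMDAR conductances at
#' a fixed AMPAR conductance, with the simulated attractor (limit cycle
#' or equilibrium approach) overlaid, in the style used to explain the
#' nullcline-flattening mechanism.
#'
#' @param params a [minimal_params()] object (its `g_n` is ignored).
#' @param g_a fixed AMPAR conductance.
#' @param g_n_values NMDAR conductances, one portrait colour each.
#' @param v_range,w_range phase-plane window.
#' @param duration,transient simulation settings for the attractor.
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(params, g_a = 0, g_n_values = c(0, 0.77),
                             v_range = c(-1.1, 0.3), w_range = c(0, 16),
                             duration = 20, transient = 10) {
  layers <- purrr::map_dfr(g_n_values, function(gn) {
    p <- set_stim(params, g_a, gn)
    nc <- nullclines(p, v_range = v_range, w_range = w_range)
    nc$g_n <- gn
    nc
  })
  cyc <- purrr::map_dfr(g_n_values, function(gn) {
    p <- set_stim(params, g_a, gn)
    traj <- simulate_neuron(p, duration = duration)
    win <- traj[traj$time >= transient, ]
    tibble::tibble(v = win$v, w = win$w, g_n = gn)
  })
  vline <- layers[layers$nullcline == "v", ]
  wline <- layers[layers$nullcline == "w", ]
  ggplot2::ggplot(mapping = ggplot2::aes(.data$v, .data$w,
                                         colour = factor(.data$g_n))) +
    ggplot2::geom_path(data = vline,
                       ggplot2::aes(group = interaction(.data$g_n,
                                                        .data$branch))) +
    ggplot2::geom_path(data = wline, linetype = "dotted",
                       ggplot2::aes(group = interaction(.data$g_n,
                                                        .data$branch))) +
    ggplot2::geom_path(data = cyc, linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(colour = "g_n", x = "v", y = "w") +
    ggplot2::theme_minimal()
}
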
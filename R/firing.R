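#' Detect threshold crossings in a voltage trace
#'
#' Finds the instants at which the voltage crosses a threshold from
#' below (upward), locating each crossing by linear interpolation
#' between the bracketing samples.  Because an upward crossing requires
#' the previous sample to lie strictly below threshold, consecutive
#' detections are necessarily separated by a downward crossing.
#'
#' @param traj a [simulate_neuron()] trajectory (or any data frame with
#'   `time` and `v` columns).
#' @param threshold crossing threshold; defaults to the `v_spike` field
#'   of the trajectory's parameters.
#' @param direction only `"up"` is meaningful for spike registration.
#' @return Ordered numeric vector of crossing times (possibly empty).
#' @examples
#' tr <- tibble::tibble(time = seq(0, 1, 1e-3),
#'                      v = sin(2 * pi * 5 * seq(0, 1, 1e-3)))
#' detect_crossings(tr, threshold = 0)
#' @export
detect_crossings <- function(traj, threshold = NULL, direction = "up") {
  direction <- match.arg(direction, "up")
  if (is.null(threshold)) threshold <- attr(traj, "params")$v_spike
  if (is.null(threshold)) {
    stop("`threshold` is required when `traj` carries no parameters",
         call. = FALSE)
  }
  t <- traj$time
  v <- traj$v
  if (length(t) < 2) return(numeric(0))
  i <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(i)) return(numeric(0))
  frac <- (threshold - v[i]) / (v[i + 1] - v[i])
  t[i] + frac * (t[i + 1] - t[i])
}

# 1% of the spike-threshold-to-trough excursion of the corresponding
# unstimulated model (minimal trough ~ -0.88, biophysical ~ -88 mV);
# regenerated by subthreshold_floor() and checked in the test suite.
FLOOR_MINIMAL <- 0.0048
FLOOR_BIO <- 0.48

#' Amplitude floor separating subthreshold oscillation from rest
#'
#' Computes 1\% of the distance between the spike threshold and the
#' voltage trough of the unstimulated model, the default amplitude
#' criterion used by [firing_summary()] to distinguish attenuated
#' (Hopf) subthreshold oscillations from a genuine equilibrium.
#'
#' @param params a parameter object; the synaptic conductances are
#'   zeroed before simulating.
#' @param duration simulated time used to find the trough.
#' @return A positive scalar in voltage units.
#' @export
subthreshold_floor <- function(params, duration = NULL) {
  p0 <- set_stim(params, 0, 0)
  traj <- simulate_neuron(p0, duration = duration)
  0.01 * (p0$v_spike - min(traj$v))
}

#' Steady-state firing summary of a trajectory
#'
#' Discards an initial transient, detects upward threshold crossings in
#' the remaining analysis window, and classifies the dynamical regime:
#' `"firing"` when at least `min_crossings` crossings occur (the mean
#' crossing rate is then reported as the frequency), otherwise
#' `"subthreshold_oscillation"` when the post-transient peak-to-trough
#' voltage excursion exceeds an amplitude floor, otherwise
#' `"quiescent"` (rest or depolarisation block).
#'
#' The frequency is `(n - 1) / (t_last - t_first)` over the detected
#' crossings, reported in Hz (the minimal model's time unit is seconds;
#' biophysical crossing rates are converted from 1/ms).
#'
#' @param traj a [simulate_neuron()] trajectory.
#' @param threshold crossing threshold (defaults to `v_spike`).
#' @param transient initial time span to discard (default 10 s for the
#'   minimal model, 5000 ms for the biophysical model).
#' @param min_crossings minimum crossings to declare firing (3).
#' @param amplitude_floor override for the subthreshold amplitude
#'   criterion; defaults to the precomputed 1\% excursion constants.
#' @return An object of class `da_firing`: a list with fields
#'   `crossing_times`, `frequency` (Hz, `NA` unless firing), `regime`,
#'   `amplitude`, `n_crossings`, `window`, `threshold` and `model`.
#' @examples
#' fs <- firing_summary(simulate_neuron(minimal_params()))
#' fs$frequency
#' @export
firing_summary <- function(traj, threshold = NULL, transient = NULL,
                           min_crossings = 3, amplitude_floor = NULL) {
  model <- attr(traj, "model")
  params <- attr(traj, "params")
  if (is.null(threshold)) threshold <- params$v_spike
  if (is.null(transient)) {
    if (is.null(model)) {
      stop("`transient` is required for bare traces", call. = FALSE)
    }
    transient <- switch(model, minimal = 10, biophysical = 5000)
  }
  if (is.null(amplitude_floor)) {
    amplitude_floor <- if (is.null(model)) 0 else
      switch(model, minimal = FLOOR_MINIMAL, biophysical = FLOOR_BIO)
  }
  t_end <- max(traj$time)
  if (transient >= t_end) {
    stop("analysis window is empty: `transient` must be shorter than the ",
         "trajectory", call. = FALSE)
  }
  win <- traj[traj$time >= transient, , drop = FALSE]
  crossings <- detect_crossings(win, threshold = threshold)
  amplitude <- diff(range(win$v))
  per_second <- if (identical(model, "biophysical")) 1000 else 1

  if (length(crossings) >= min_crossings) {
    regime <- "firing"
    frequency <- per_second * (length(crossings) - 1) /
      (crossings[length(crossings)] - crossings[1])
  } else {
    frequency <- NA_real_
    regime <- if (amplitude > amplitude_floor) "subthreshold_oscillation"
              else "quiescent"
  }
  structure(
    list(crossing_times = crossings, frequency = frequency, regime = regime,
         amplitude = amplitude, n_crossings = length(crossings),
         window = c(transient, t_end), threshold = threshold, model = model),
    class = "da_firing"
  )
}

#' @export
print.da_firing <- function(x, ...) {
  cat(sprintf("<firing summary (%s model)>\n", x$model))
  cat(sprintf("  regime:    %s\n", x$regime))
  cat(sprintf("  frequency: %s\n",
              if (is.na(x$frequency)) "-" else sprintf("%.3f Hz", x$frequency)))
  cat(sprintf("  crossings: %d in window [%g, %g]\n",
              x$n_crossings, x$window[1], x$window[2]))
  cat(sprintf("  amplitude: %.4g\n", x$amplitude))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname firing_summary
#' @param x a `da_firing` object.
#' @param ... unused.
#' @export
tidy.da_firing <- function(x, ...) {
  tibble::tibble(
    crossing = seq_along(x$crossing_times),
    time = x$crossing_times,
    isi = c(NA_real_, diff(x$crossing_times))
  )
}

#' @rdname firing_summary
#' @export
glance.da_firing <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    regime = x$regime,
    frequency = x$frequency,
    n_crossings = x$n_crossings,
    amplitude = x$amplitude
  )
}

# one-call helper used throughout the sweeps module
steady_state_summary <- function(params, duration = NULL, transient = NULL,
                                 rtol = 1e-8, atol = NULL, init = NULL) {
  traj <- simulate_neuron(params, duration = duration, init = init,
                          rtol = rtol, atol = atol)
  firing_summary(traj, transient = transient)
}
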
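#' Integrate a neuron model
#'
#' Adaptive-step integration (via [deSolve::lsoda()] with the package's
#' compiled right-hand sides) with dense, regularly sampled output so
#' that threshold crossings are not missed.  The model is chosen by the
#' class of `params`.  Time is in seconds for the minimal model and in
#' milliseconds for the biophysical model; the default sampling interval
#' is 1 ms in either unit system.
#'
#' @param params a [minimal_params()] or [bio_params()] object.
#' @param duration total integrated time (s for minimal, ms for
#'   biophysical).  Defaults: 30 s / 15000 ms.
#' @param init initial state, `c(v, w)` or `c(v, ca, n)`.  Defaults:
#'   `(-0.7, 0.1)` for the minimal model; `(-60 mV, 0.1 k_ca,
#'   n_inf(-60))` for the biophysical model.
#' @param sample_by output sampling interval (1e-3 s / 1 ms).
#' @param rtol,atol relative and absolute solver tolerances.
#' @param max_step maximal internal step size.
#'
#' @return A tibble of class `da_trajectory` with a `time` column and
#'   one column per state variable, plus attributes `params`, `model`
#'   and `solver` (the settings used).
#' @examples
#' traj <- simulate_neuron(minimal_params(), duration = 2)
#' head(traj)
#' @export
simulate_neuron <- function(params, duration = NULL, init = NULL,
                            sample_by = NULL, rtol = 1e-8, atol = NULL,
                            max_step = NULL) {
  tag <- model_tag(params)
  if (tag == "minimal") {
    if (is.null(duration)) duration <- 30
    if (is.null(sample_by)) sample_by <- 1e-3
    if (is.null(atol)) atol <- 1e-8
    if (is.null(init)) init <- c(v = -0.7, w = 0.1)
    vars <- c("v", "w")
    func <- "derivs_minimal"
    initfunc <- "initmod_minimal"
  } else {
    if (is.null(duration)) duration <- 15000
    if (is.null(sample_by)) sample_by <- 1
    if (is.null(atol)) atol <- 1e-8
    if (is.null(init)) {
      init <- c(v = -60, ca = 0.1 * params$k_ca,
                n = erg_kinetics(-60, params)$n_inf)
    }
    vars <- c("v", "ca", "n")
    func <- "derivs_bio"
    initfunc <- "initmod_bio"
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a positive scalar", call. = FALSE)
  }
  if (length(init) != length(vars) || !all(is.finite(init))) {
    stop("`init` must be a finite numeric vector of length ", length(vars),
         call. = FALSE)
  }
  init <- stats::setNames(as.numeric(init), vars)
  times <- seq(0, duration, by = sample_by)
  hmax <- if (is.null(max_step)) .Machine$double.xmax else max_step

  out <- deSolve::lsoda(
    y = init, times = times, func = func, parms = pack_parms(params),
    dllname = "dasynergy", initfunc = initfunc,
    rtol = rtol, atol = atol, hmax = hmax
  )
  out <- unclass(out)
  bad <- !stats::complete.cases(out) | !is.finite(rowSums(out))
  if (any(bad) || nrow(out) < length(times)) {
    t_bad <- if (any(bad)) out[which(bad)[1], 1] else times[nrow(out) + 1]
    stop(sprintf("integration failed: non-finite state at t = %g", t_bad),
         call. = FALSE)
  }

  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time", vars)
  structure(
    traj,
    class = c("da_trajectory", class(traj)),
    params = params,
    model = tag,
    init = init,
    solver = list(method = "lsoda", rtol = rtol, atol = atol,
                  sample_by = sample_by, max_step = max_step)
  )
}

#' @export
print.da_trajectory <- function(x, ...) {
  s <- attr(x, "solver")
  cat(sprintf("<%s-model trajectory: %d samples over %g time units (rtol %g)>\n",
              attr(x, "model"), nrow(x), max(x$time), s$rtol))
  NextMethod()
}
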
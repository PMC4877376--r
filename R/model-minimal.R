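#' Component functions of the minimal model
#'
#' The planar model's right-hand side is assembled from four pieces:
#' the cubic instantaneous current `f_cubic()`, the SK-type
#' calcium-activated potassium current `j_kca_min()`, the piecewise
#' recovery function `g_recovery()`, and the synaptic drive
#' `j_stim_min()` (AMPAR plus magnesium-blocked NMDAR).  All are
#' vectorised over their state arguments.
#'
#' `g_recovery()` is piecewise in the sign of `w`: for `w >= 0` it is
#' `v - k_w` (so the w-nullcline is the vertical line `v = k_w`), and
#' for `w < 0` it is `0.01 (v - k_w) - w`, whose `-w` term pushes the
#' slow variable back toward the `v` axis.  The switch prevents the
#' mirror branch of the folded v-nullcline below the axis from hosting
#' stable equilibria that would trap trajectories.  At exactly `w = 0`
#' the upper branch applies.
#'
#' @param v membrane-potential variable (dimensionless).
#' @param w recovery/calcium variable (dimensionless).
#' @param params a [minimal_params()] object.
#' @return A numeric vector (a current for `f_cubic`, `j_kca_min`,
#'   `j_stim_min`; a rate for `g_recovery`).
#' @examples
#' p <- minimal_params()
#' f_cubic(0, p)              # = a1 * a4
#' j_kca_min(0, p$k_ca, p)    # half-activation: g_kca * e_k / 2
#' @name minimal-components
NULL

#' @rdname minimal-components
#' @export
f_cubic <- function(v, params) {
  params$a1 * (v^3 + params$a2 * v^2 + params$a3 * v + params$a4)
}

#' @rdname minimal-components
#' @export
j_kca_min <- function(v, w, params) {
  w4 <- w^4
  params$g_kca * (params$e_k - v) * w4 / (w4 + params$k_ca^4)
}

#' @rdname minimal-components
#' @export
g_recovery <- function(v, w, params) {
  ifelse(w >= 0,
         v - params$k_w,
         0.01 * (v - params$k_w) - w)
}

#' @rdname minimal-components
#' @export
j_stim_min <- function(v, params) {
  nmda_conductance_min(v, params) * (params$e_n - v) +
    params$g_a * (params$e_a - v)
}

#' Voltage-dependent NMDAR conductance of the minimal model
#'
#' The magnesium block makes the NMDAR conductance a rising sigmoid of
#' voltage, `g_n / (1 + m_block * exp(-6 v))`: nearly closed at the
#' oscillation trough, fully open at depolarised voltages.
#'
#' @inheritParams minimal-components
#' @return Conductance values (dimensionless), strictly increasing in `v`.
#' @export
nmda_conductance_min <- function(v, params) {
  params$g_n / (1 + params$m_block * exp(-6 * v))
}

#' Right-hand side of the minimal model
#'
#' Evaluates the time derivatives `(dv/dt, dw/dt)` of the planar model.
#' Division by the time-calibration factor `c` puts rates on a
#' per-second scale, so threshold-crossing rates of simulated
#' trajectories are in Hz.
#'
#' @param state numeric vector `c(v, w)`.
#' @param params a [minimal_params()] object.
#' @return Numeric vector `c(dv, dw)`.
#' @examples
#' minimal_rhs(c(-0.585, 1.76), minimal_params())
#' @export
minimal_rhs <- function(state, params) {
  stopifnot(is.numeric(state), length(state) == 2, all(is.finite(state)))
  v <- state[1]
  w <- state[2]
  dv <- (f_cubic(v, params) + j_kca_min(v, w, params) +
           j_stim_min(v, params)) / params$c
  dw <- params$eps * g_recovery(v, w, params) / params$c
  c(dv, dw)
}
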
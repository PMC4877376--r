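#' Conductance functions of the biophysical model
#'
#' Voltage- and calcium-dependent conductances of the conductance-based
#' model.  All return values in mS/cm2, bounded between 0 and the
#' corresponding maximal conductance, and are vectorised.
#'
#' * `g_ca()` -- L-type calcium conductance
#'   `gbar_ca * alpha^4 / (alpha + beta)^4` with
#'   `alpha(v) = 0.0032 (v + 50) / (1 - exp(-(v + 50)/5))` and
#'   `beta(v) = 0.05 exp(-(v + 55)/40)`; the removable singularity of
#'   `alpha` at `v = -50` is evaluated by its limit `0.016`.
#' * `g_kca_bio()` -- SK conductance, fourth-power Hill function of
#'   calcium with half-activation `k_ca`.
#' * `g_k_inst()` -- instantaneous potassium conductance, a Boltzmann
#'   sigmoid with half-activation -10 mV and slope 7 mV.
#' * `g_nmda_bio()` -- NMDAR conductance under instantaneous magnesium
#'   block, `gbar_nmda / (1 + 0.1 mg exp(-0.062 v))`.
#'
#' @param v membrane potential (mV).
#' @param ca free intracellular calcium concentration (uM).
#' @param params a [bio_params()] object.
#' @return Conductance (mS/cm2).
#' @name bio-conductances
NULL

#' @rdname bio-conductances
#' @export
g_ca <- function(v, params) {
  x <- v + 50
  alpha <- ifelse(abs(x) < 1e-7, 0.0032 * 5, 0.0032 * x / (1 - exp(-x / 5)))
  beta <- 0.05 * exp(-(v + 55) / 40)
  params$gbar_ca * (alpha / (alpha + beta))^4
}

#' @rdname bio-conductances
#' @export
g_kca_bio <- function(ca, params) {
  ca4 <- ca^4
  params$gbar_kca * ca4 / (ca4 + params$k_ca^4)
}

#' @rdname bio-conductances
#' @export
g_k_inst <- function(v, params) {
  params$gbar_k / (1 + exp(-(v + 10) / 7))
}

#' @rdname bio-conductances
#' @export
g_nmda_bio <- function(v, params) {
  params$gbar_nmda / (1 + 0.1 * params$mg * exp(-0.062 * v))
}

#' ERG-current gating kinetics
#'
#' Steady-state activation and voltage-dependent time constant of the
#' ERG potassium current's gating variable `n`.  Activation is a rising
#' sigmoid (half-activation `erg_vhalf` = -47.4 mV, slope 2 mV): ERG is
#' depolarisation-activated.  The time constant is a baseline of 62 ms
#' plus a 300 ms bump between the two midpoints -50.4 and -63.4 mV,
#' written with decreasing sigmoids so that `tau_n >= 62` everywhere
#' and `tau_n -> 62` in both voltage limits.
#'
#' @param v membrane potential (mV).
#' @param params a [bio_params()] object.
#' @return A list with numeric components `n_inf` (dimensionless) and
#'   `tau_n` (ms).
#' @export
erg_kinetics <- function(v, params) {
  n_inf <- 1 / (1 + exp(-(v - params$erg_vhalf) / params$erg_slope))
  tau_n <- params$erg_tau_base + params$erg_tau_amp *
    (1 / (1 + exp((v - params$erg_tau_v1) / params$erg_tau_slope)) -
     1 / (1 + exp((v - params$erg_tau_v2) / params$erg_tau_slope)))
  list(n_inf = n_inf, tau_n = tau_n)
}

#' Right-hand side of the biophysical model
#'
#' Time derivatives of `(v, ca, n)`: the current balance for the
#' voltage (L-type calcium inward; SK, ERG and instantaneous potassium
#' outward through the shared reversal `e_k`; leak; AMPAR; NMDAR), the
#' calcium balance between L-type influx and pump extrusion scaled by
#' the surface-to-volume factor `2 beta_buf / radius`, and first-order
#' relaxation of the ERG gate to its voltage-dependent steady state.
#' With `v` in mV, conductances in mS/cm2, `radius` in cm and time in
#' ms, the calcium rate comes out in uM/ms with no extra conversion
#' factor.
#'
#' @param state numeric vector `c(v, ca, n)`.
#' @param params a [bio_params()] object.
#' @return Numeric vector `c(dv, dca, dn)` (mV/ms, uM/ms, 1/ms).
#' @export
bio_rhs <- function(state, params) {
  stopifnot(is.numeric(state), length(state) == 3, all(is.finite(state)))
  v <- state[1]
  ca <- state[2]
  n <- state[3]
  kin <- erg_kinetics(v, params)
  dv <- (g_ca(v, params) * (params$e_ca - v) +
           (g_kca_bio(ca, params) + params$gbar_erg * n^4 +
              g_k_inst(v, params)) * (params$e_k - v) +
           params$g_l * (params$e_l - v) +
           params$gbar_ampa * (params$e_ampa - v) +
           g_nmda_bio(v, params) * (params$e_nmda - v)) / params$cm
  dca <- (2 * params$beta_buf / params$radius) *
    (g_ca(v, params) * (params$e_ca - v) / (params$z * params$faraday) -
       params$p_ca * ca)
  dn <- (kin$n_inf - n) / kin$tau_n
  c(dv, dca, dn)
}
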
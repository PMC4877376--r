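#' Parameter set of the minimal dopaminergic-neuron model
#'
#' Constructs the complete, validated parameter set of the planar
#' FitzHugh-Nagumo-type model with an SK-current nonlinearity.  The
#' defaults are the published dimensionless calibration; only the two
#' synaptic conductances `g_a` and `g_n` are intended to be varied.
#'
#' The model is
#' \deqn{c\,\dot v = f(v) + j_{KCa}(v,w) + j_{stim}(v), \qquad
#'       c\,\dot w = \epsilon\, g(v,w),}
#' with `f` a cubic, `j_KCa` an SK-type calcium-activated potassium
#' current gated by the fourth power of the slow variable `w`
#' (interpreted as calcium concentration), and `j_stim` the sum of a
#' voltage-independent AMPAR term and an NMDAR term whose conductance is
#' a rising sigmoid of voltage (magnesium block).  Time is in seconds,
#' so threshold-crossing rates are in Hz.
#'
#' @param g_a AMPAR maximal conductance (dimensionless, >= 0).
#' @param g_n NMDAR maximal conductance (dimensionless, >= 0).
#' @param ... overrides for any other field: `c` (time calibration,
#'   1.1e-4), `eps` (slow rate factor, 0.01), `a1,a2,a3,a4` (cubic
#'   coefficients -1, 1.35, 0.54, 0.0539), `g_kca` (0.5), `e_k` (-1),
#'   `k_ca` (SK half-activation, 10), `k_w` (recovery threshold,
#'   -0.585), `m_block` (magnesium-block strength, 0.2), `e_n`, `e_a`
#'   (reversals, 0), `v_spike` (spike threshold, -0.4).
#'
#' @return A list with class `c("minimal_params", "da_params")`.
#' @seealso [bio_params()], [simulate_neuron()]
#' @examples
#' p <- minimal_params(g_a = 0.026, g_n = 0.77)
#' p$k_w
#' @export
minimal_params <- function(g_a = 0, g_n = 0, ...) {
  p <- list(
    c = 1.1e-4, eps = 0.01,
    a1 = -1, a2 = 1.35, a3 = 0.54, a4 = 0.0539,
    g_kca = 0.5, e_k = -1, k_ca = 10, k_w = -0.585,
    m_block = 0.2, e_n = 0, e_a = 0,
    g_a = g_a, g_n = g_n, v_spike = -0.4
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) {
    stop("unknown minimal-model parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  validate_minimal_params(structure(p, class = c("minimal_params", "da_params")))
}

validate_minimal_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!all(vapply(p, num1, logical(1)))) {
    stop("all minimal-model parameters must be finite scalars", call. = FALSE)
  }
  if (p$c <= 0) stop("`c` must be > 0", call. = FALSE)
  if (p$eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  if (p$k_ca <= 0) stop("`k_ca` must be > 0", call. = FALSE)
  for (nm in c("g_kca", "g_a", "g_n")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  p
}

# cached default biophysical calibration (read once per session)
the <- new.env(parent = emptyenv())

bio_calibration_defaults <- function() {
  if (is.null(the$bio_defaults)) {
    path <- system.file("extdata", "bio_calibration.yaml",
                        package = "dasynergy", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    cfg$version <- NULL
    the$bio_defaults <- lapply(cfg, as.numeric)
  }
  the$bio_defaults
}

#' Parameter set of the biophysical dopaminergic-neuron model
#'
#' Constructs the parameter set of the conductance-based model: three
#' state variables (membrane potential `v` in mV, free intracellular
#' calcium `ca` in uM, ERG gating variable `n`), with L-type calcium,
#' SK, ERG and instantaneous potassium currents, a leak, and tonic
#' AMPAR/NMDAR synaptic conductances.  Defaults come from the shipped
#' calibration file `inst/extdata/bio_calibration.yaml`, the single
#' source of truth for this model's calibration (see the methods
#' vignette for how it was fitted); only `gbar_ampa` and `gbar_nmda`
#' are intended to be varied.
#'
#' @param gbar_ampa AMPAR conductance density (mS/cm2, >= 0).
#' @param gbar_nmda NMDAR conductance density (mS/cm2, >= 0).
#' @param ... overrides for any calibration field (see the calibration
#'   file for names, units and meaning).
#'
#' @return A list with class `c("bio_params", "da_params")`.
#' @seealso [minimal_params()], [simulate_neuron()]
#' @examples
#' p <- bio_params(gbar_nmda = 8)
#' p$gbar_erg
#' @export
bio_params <- function(gbar_ampa = 0, gbar_nmda = 0, ...) {
  p <- bio_calibration_defaults()
  p$gbar_ampa <- gbar_ampa
  p$gbar_nmda <- gbar_nmda
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) {
    stop("unknown biophysical parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  validate_bio_params(structure(p, class = c("bio_params", "da_params")))
}

validate_bio_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!all(vapply(p, num1, logical(1)))) {
    stop("all biophysical parameters must be finite scalars", call. = FALSE)
  }
  if (p$cm <= 0) stop("`cm` must be > 0", call. = FALSE)
  if (p$beta_buf <= 0 || p$beta_buf > 1) {
    stop("`beta_buf` must lie in (0, 1]", call. = FALSE)
  }
  if (p$mg < 0) stop("`mg` must be >= 0", call. = FALSE)
  if (p$radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  for (nm in c("gbar_ca", "gbar_kca", "gbar_erg", "gbar_k", "g_l",
               "gbar_ampa", "gbar_nmda")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  p
}

#' @export
print.da_params <- function(x, ...) {
  kind <- if (inherits(x, "minimal_params")) "minimal" else "biophysical"
  cat("<", kind, " dopaminergic-neuron model parameters>\n", sep = "")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-14s %g\n", nm, flat[nm]))
  invisible(x)
}

# model tag used in trajectories, sweeps and exports
model_tag <- function(params) {
  if (inherits(params, "minimal_params")) "minimal"
  else if (inherits(params, "bio_params")) "biophysical"
  else stop("`params` must be created by minimal_params() or bio_params()",
            call. = FALSE)
}

# names of the two synaptic control conductances, in (ampa, nmda) order
stim_fields <- function(params) {
  switch(model_tag(params),
    minimal = c("g_a", "g_n"),
    biophysical = c("gbar_ampa", "gbar_nmda")
  )
}

# return params with the two synaptic conductances replaced (revalidated)
set_stim <- function(params, ampa, nmda) {
  f <- stim_fields(params)
  params[[f[1]]] <- ampa
  params[[f[2]]] <- nmda
  if (inherits(params, "minimal_params")) validate_minimal_params(params)
  else validate_bio_params(params)
}

# flatten params into the numeric vector expected by the compiled RHS
pack_parms <- function(params) {
  if (inherits(params, "minimal_params")) {
    unlist(params[c("c", "eps", "a1", "a2", "a3", "a4", "g_kca", "e_k",
                    "k_ca", "k_w", "m_block", "e_n", "e_a", "g_a", "g_n")])
  } else {
    unlist(params[c("cm", "gbar_ca", "e_ca", "gbar_kca", "k_ca", "gbar_erg",
                    "gbar_k", "e_k", "g_l", "e_l", "gbar_ampa", "e_ampa",
                    "gbar_nmda", "e_nmda", "mg", "radius", "beta_buf", "z",
                    "faraday", "p_ca", "erg_vhalf", "erg_slope",
                    "erg_tau_base", "erg_tau_amp", "erg_tau_v1",
                    "erg_tau_v2", "erg_tau_slope")])
  }
}
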
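#' Nullclines of the minimal model
#'
#' Computes the v- and w-nullclines of the planar model over a phase-
#' plane window.  The v-nullcline is obtained in closed form: setting
#' `dv/dt = 0` gives a saturation level
#' `s(v) = (f(v) + j_stim(v)) / (g_kca (v - e_k))` for the SK gating
#' term `w^4 / (w^4 + k_ca^4)`, which inverts to
#' `w = k_ca (s / (1 - s))^{1/4}` wherever `0 <= s < 1`; because the
#' gating term is even in `w` the mirrored branch `-w` also solves the
#' equation and is reported when it falls inside the window.  The
#' w-nullcline is the vertical line `v = k_w` for `w >= 0` and the line
#' `w = 0.01 (v - k_w)` for `w < 0`.
#'
#' @param params a [minimal_params()] object.
#' @param v_range,w_range window bounds (dimensionless).
#' @param n number of `v` (and `w`) samples.
#' @return A tibble with columns `nullcline` (`"v"` or `"w"`), `branch`
#'   and the point coordinates `v`, `w`.
#' @examples
#' nc <- nullclines(minimal_params(), n = 50)
#' @export
nullclines <- function(params, v_range = c(-1.5, 1), w_range = c(-2, 16),
                       n = 400) {
  if (!inherits(params, "minimal_params")) {
    stop("phase-plane analysis is implemented for the planar minimal model ",
         "only", call. = FALSE)
  }
  if (diff(v_range) <= 0 || diff(w_range) <= 0) {
    stop("phase-plane window is empty", call. = FALSE)
  }
  v <- seq(v_range[1], v_range[2], length.out = n)
  w_pos <- v_nullcline_w(v, params)
  vn <- dplyr::bind_rows(
    tibble::tibble(nullcline = "v", branch = "positive_w", v = v, w = w_pos),
    tibble::tibble(nullcline = "v", branch = "negative_w", v = v, w = -w_pos)
  )
  vn <- vn[is.finite(vn$w) & vn$w >= w_range[1] & vn$w <= w_range[2], ]

  w_up <- seq(max(0, w_range[1]), w_range[2], length.out = n)
  wn_up <- tibble::tibble(nullcline = "w", branch = "vertical",
                          v = params$k_w, w = w_up)
  v_low <- v[0.01 * (v - params$k_w) < 0]
  wn_low <- tibble::tibble(nullcline = "w", branch = "lower",
                           v = v_low, w = 0.01 * (v_low - params$k_w))
  wn_low <- wn_low[wn_low$w >= w_range[1], ]
  out <- dplyr::bind_rows(vn, wn_up, wn_low)
  structure(out, class = c("da_nullclines", class(out)),
            params = params, v_range = v_range, w_range = w_range)
}

# w >= 0 solution of the v-nullcline at each v (NA where none exists)
v_nullcline_w <- function(v, params) {
  s <- (f_cubic(v, params) + j_stim_min(v, params)) /
    (params$g_kca * (v - params$e_k))
  w <- rep(NA_real_, length(v))
  ok <- is.finite(s) & s >= 0 & s < 1
  w[ok] <- params$k_ca * (s[ok] / (1 - s[ok]))^0.25
  w
}

#' Jacobian of the minimal model
#'
#' Analytic Jacobian of the planar right-hand side at a state, using
#' the `w >= 0` branch of the recovery function at exactly `w = 0`
#' (consistent with [g_recovery()]).
#'
#' @param v,w state coordinates.
#' @param params a [minimal_params()] object.
#' @return A 2x2 numeric matrix of partial derivatives.
#' @export
minimal_jacobian <- function(v, w, params) {
  k4 <- params$k_ca^4
  w4 <- w^4
  hill <- w4 / (w4 + k4)
  df <- params$a1 * (3 * v^2 + 2 * params$a2 * v + params$a3)
  # d/dv of NMDA term g_n(v) (e_n - v): g_n'(v) (e_n - v) - g_n(v)
  gn <- nmda_conductance_min(v, params)
  e6 <- params$m_block * exp(-6 * v)
  dgn <- params$g_n * 6 * e6 / (1 + e6)^2
  djstim_dv <- dgn * (params$e_n - v) - gn - params$g_a
  dv_dv <- (df - params$g_kca * hill + djstim_dv) / params$c
  dv_dw <- params$g_kca * (params$e_k - v) *
    4 * w^3 * k4 / (w4 + k4)^2 / params$c
  if (w >= 0) {
    dw_dv <- params$eps / params$c
    dw_dw <- 0
  } else {
    dw_dv <- 0.01 * params$eps / params$c
    dw_dw <- -params$eps / params$c
  }
  matrix(c(dv_dv, dw_dv, dv_dw, dw_dw), 2, 2,
         dimnames = list(c("v", "w"), c("v", "w")))
}

classify_equilibrium <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (max(re) < 0) "stable" else "unstable"
  type <- if (any(Im(ev) != 0)) "focus"
          else if (prod(re) < 0) "saddle"
          else "node"
  list(eigenvalues = ev, stability = stability, type = type)
}

#' Equilibria of the minimal model
#'
#' Locates all isolated equilibria inside a `v` window and attaches
#' linear-stability information.  On the upper branch of the recovery
#' function the w-nullcline is the line `v = k_w`, so the (at most one)
#' equilibrium with `w >= 0` is found in closed form from the
#' v-nullcline inversion; below the axis, equilibria satisfy
#' `w = 0.01 (v - k_w)` and are located by a sign-change scan of the
#' remaining one-dimensional equation polished with [stats::uniroot()].
#'
#' @param params a [minimal_params()] object.
#' @param v_range scan window for `v`.
#' @param n_scan grid resolution of the lower-branch root scan.
#' @return A tibble of class `da_equilibria` with columns `v`, `w`,
#'   `branch`, `stability`, `type`, `lambda1`, `lambda2` (complex
#'   eigenvalues) and a `jacobian` list-column.  Zero rows when the
#'   window contains no equilibrium.
#' @examples
#' find_equilibria(minimal_params())
#' @export
find_equilibria <- function(params, v_range = c(-1.5, 1), n_scan = 600) {
  if (!inherits(params, "minimal_params")) {
    stop("phase-plane analysis is implemented for the planar minimal model ",
         "only", call. = FALSE)
  }
  eq <- list()
  # upper branch: v = k_w, w from the closed-form nullcline inversion
  if (params$k_w >= v_range[1] && params$k_w <= v_range[2]) {
    w_star <- v_nullcline_w(params$k_w, params)
    if (is.finite(w_star)) {
      eq[[length(eq) + 1]] <- c(v = params$k_w, w = w_star)
    }
  }
  # lower branch: w = 0.01 (v - k_w) < 0, scan for roots of dv/dt
  vlo <- seq(v_range[1], min(params$k_w, v_range[2]), length.out = n_scan)
  vlo <- vlo[vlo < params$k_w]
  if (length(vlo) > 1) {
    fv <- vapply(vlo, function(v) {
      w <- 0.01 * (v - params$k_w)
      f_cubic(v, params) + j_kca_min(v, w, params) + j_stim_min(v, params)
    }, numeric(1))
    sw <- which(diff(sign(fv)) != 0)
    for (i in sw) {
      root <- stats::uniroot(function(v) {
        w <- 0.01 * (v - params$k_w)
        f_cubic(v, params) + j_kca_min(v, w, params) + j_stim_min(v, params)
      }, c(vlo[i], vlo[i + 1]), tol = 1e-12)$root
      eq[[length(eq) + 1]] <- c(v = root, w = 0.01 * (root - params$k_w))
    }
  }
  rows <- purrr::map(eq, function(s) {
    J <- minimal_jacobian(s["v"], s["w"], params)
    cls <- classify_equilibrium(J)
    tibble::tibble(
      v = unname(s["v"]), w = unname(s["w"]),
      branch = if (s["w"] >= 0) "upper" else "lower",
      stability = cls$stability, type = cls$type,
      lambda1 = cls$eigenvalues[1], lambda2 = cls$eigenvalues[2],
      jacobian = list(J)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(v = numeric(), w = numeric(), branch = character(),
                   stability = character(), type = character(),
                   lambda1 = complex(), lambda2 = complex(),
                   jacobian = list())
  }
  structure(out, class = c("da_equilibria", class(out)), params = params)
}

# largest eigenvalue real part of the upper-branch equilibrium, or NA
# when no equilibrium with w >= 0 exists at these conductances
upper_eq_relambda <- function(params) {
  w_star <- v_nullcline_w(params$k_w, params)
  if (!is.finite(w_star)) return(NA_real_)
  J <- minimal_jacobian(params$k_w, w_star, params)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Andronov-Hopf boundary in the synaptic-conductance plane
#'
#' For each AMPAR conductance in `ampa_values`, scans the NMDAR
#' conductance range for a sign change of the equilibrium's leading
#' eigenvalue real part (loss of stability of the upper-branch
#' equilibrium) and locates it by bisection.  Conductance pairs whose
#' scan shows no sign change -- for instance deep inside the firing
#' region, where the equilibrium is unstable throughout -- are omitted
#' with a message.
#'
#' @param params a [minimal_params()] object (its own `g_a`, `g_n` are
#'   ignored).
#' @param ampa_values AMPAR conductances at which to trace the boundary.
#' @param nmda_range NMDAR conductance interval scanned for the
#'   stability change.
#' @param n_scan scan resolution along the NMDAR axis.
#' @param tol bisection tolerance in conductance units.
#' @return A tibble with columns `g_a` and `g_n_hopf`.
#' @examples
#' hopf_boundary(minimal_params(), ampa_values = c(0.02, 0.04))
#' @export
hopf_boundary <- function(params, ampa_values, nmda_range = c(0, 1.2),
                          n_scan = 121, tol = 1e-4) {
  if (!inherits(params, "minimal_params")) {
    stop("phase-plane analysis is implemented for the planar minimal model ",
         "only", call. = FALSE)
  }
  if (any(ampa_values < 0) || any(nmda_range < 0)) {
    stop("conductance ranges must be non-negative", call. = FALSE)
  }
  gn_grid <- seq(nmda_range[1], nmda_range[2], length.out = n_scan)
  rows <- purrr::map(ampa_values, function(ga) {
    re <- vapply(gn_grid, function(gn) {
      upper_eq_relambda(set_stim(params, ga, gn))
    }, numeric(1))
    ok <- which(is.finite(re))
    if (length(ok) < 2) {
      message(sprintf("g_a = %g: no equilibrium along the scan; omitted", ga))
      return(NULL)
    }
    sgn <- sign(re[ok])
    flip <- which(diff(sgn) != 0)
    if (!length(flip)) {
      message(sprintf(
        "g_a = %g: no stability change in [%g, %g]; omitted",
        ga, nmda_range[1], nmda_range[2]))
      return(NULL)
    }
    lo <- gn_grid[ok[flip[1]]]
    hi <- gn_grid[ok[flip[1] + 1]]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      re_mid <- upper_eq_relambda(set_stim(params, ga, mid))
      if (sign(re_mid) == sgn[flip[1]]) lo <- mid else hi <- mid
    }
    tibble::tibble(g_a = ga, g_n_hopf = (lo + hi) / 2)
  })
  dplyr::bind_rows(rows)
}

#' One-parameter bifurcation diagram along the NMDAR axis
#'
#' For a fixed AMPAR conductance, sweeps the NMDAR conductance and
#' records the upper-branch equilibrium (location and stability, from
#' the linearisation) together with the voltage extrema of the
#' attractor reached by simulation.  Near a supercritical
#' Andronov-Hopf point the oscillation extrema collapse continuously
#' onto the equilibrium branch.
#'
#' @param params a [minimal_params()] object.
#' @param g_a fixed AMPAR conductance.
#' @param nmda_grid NMDAR conductances to evaluate.
#' @param duration,transient simulation settings per point.
#' @return A tibble with columns `g_n`, `v_eq`, `w_eq`, `stability`,
#'   `v_min`, `v_max` (attractor extrema after the transient).
#' @export
bifurcation_diagram <- function(params, g_a, nmda_grid,
                                duration = 20, transient = 10) {
  purrr::map_dfr(nmda_grid, function(gn) {
    p <- set_stim(params, g_a, gn)
    w_star <- v_nullcline_w(p$k_w, p)
    stab <- NA_character_
    if (is.finite(w_star)) {
      J <- minimal_jacobian(p$k_w, w_star, p)
      stab <- classify_equilibrium(J)$stability
    }
    traj <- simulate_neuron(p, duration = duration)
    win <- traj[traj$time >= transient, ]
    tibble::tibble(g_n = gn, v_eq = p$k_w, w_eq = w_star, stability = stab,
                   v_min = min(win$v), v_max = max(win$v))
  })
}
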
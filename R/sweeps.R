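#' Default sweep grids
#'
#' Conductance grids used by the sweep functions when none are given:
#' minimal model `g_a` in \[0, 0.06\] step 0.002 and `g_n` in \[0, 1.2\]
#' step 0.02; biophysical model `gbar_ampa` in \[0, 0.4\] step 0.02 and
#' `gbar_nmda` in \[0, 12\] step 0.25.  These bracket all operating
#' points of interest with margin.
#'
#' @param params a parameter object.
#' @return A list with components `ampa` and `nmda`.
#' @export
default_grids <- function(params) {
  switch(model_tag(params),
    minimal = list(ampa = seq(0, 0.06, by = 0.002),
                   nmda = seq(0, 1.2, by = 0.02)),
    biophysical = list(ampa = seq(0, 0.4, by = 0.02),
                       nmda = seq(0, 12, by = 0.25))
  )
}

sweep_point <- function(params, ampa, nmda, duration, transient, rtol) {
  fs <- steady_state_summary(set_stim(params, ampa, nmda),
                             duration = duration, transient = transient,
                             rtol = rtol)
  tibble::tibble(frequency = fs$frequency, regime = fs$regime,
                 amplitude = fs$amplitude, n_crossings = fs$n_crossings)
}

#' Steady-state frequency along one synaptic conductance
#'
#' Simulates the model at each grid value of one synaptic conductance
#' (the other held at its value in `params`), each point from a fresh
#' default initial state, and summarises steady-state firing.
#'
#' @param params a [minimal_params()] or [bio_params()] object.
#' @param vary which conductance to sweep: `"nmda"` or `"ampa"`.
#' @param grid increasing vector of conductances; defaults to the
#'   model's [default_grids()] axis.
#' @param duration,transient,rtol simulation settings per point.
#' @return A tibble of class `da_frequency_curve` with columns
#'   `conductance`, `frequency` (NA unless firing), `regime`,
#'   `amplitude`, `n_crossings`.
#' @examples
#' \donttest{
#' frequency_curve(minimal_params(), vary = "nmda",
#'                 grid = seq(0.4, 0.8, 0.2))
#' }
#' @export
frequency_curve <- function(params, vary = c("nmda", "ampa"), grid = NULL,
                            duration = NULL, transient = NULL, rtol = 1e-8) {
  vary <- match.arg(vary)
  if (is.null(grid)) grid <- default_grids(params)[[vary]]
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  fixed <- params[[stim_fields(params)[if (vary == "nmda") 1 else 2]]]
  rows <- purrr::map_dfr(grid, function(g) {
    if (vary == "nmda") {
      sweep_point(params, fixed, g, duration, transient, rtol)
    } else {
      sweep_point(params, g, fixed, duration, transient, rtol)
    }
  })
  out <- dplyr::bind_cols(tibble::tibble(conductance = grid), rows)
  structure(out, class = c("da_frequency_curve", class(out)),
            model = model_tag(params), vary = vary, fixed = fixed)
}

#' Firing-frequency map over the synaptic conductance plane
#'
#' Evaluates steady-state firing on the full grid of
#' (AMPAR, NMDAR) conductance pairs.  Each grid point is simulated
#' independently from the same fresh initial state, matching a
#' steady-response protocol (no continuation in the parameter).
#'
#' @param params a [minimal_params()] or [bio_params()] object.
#' @param ampa_grid,nmda_grid strictly increasing conductance axes;
#'   default to [default_grids()].
#' @param duration,transient,rtol simulation settings per point.
#' @param cache_file optional CSV path: completed grid points are
#'   appended there as they are computed and are skipped (read back)
#'   when the map is re-run, making long sweeps resumable.
#' @return A long-format tibble of class `da_frequency_map` with
#'   columns `g_ampa`, `g_nmda`, `frequency`, `regime`, `amplitude`,
#'   and attributes `ampa_axis`, `nmda_axis`, `model`, `settings`.
#' @examples
#' \donttest{
#' m <- frequency_map(minimal_params(), ampa_grid = c(0, 0.02),
#'                    nmda_grid = c(0.6, 0.8))
#' }
#' @export
frequency_map <- function(params, ampa_grid = NULL, nmda_grid = NULL,
                          duration = NULL, transient = NULL, rtol = 1e-8,
                          cache_file = NULL) {
  grids <- default_grids(params)
  if (is.null(ampa_grid)) ampa_grid <- grids$ampa
  if (is.null(nmda_grid)) nmda_grid <- grids$nmda
  if (!length(ampa_grid) || !length(nmda_grid)) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  if (is.unsorted(ampa_grid, strictly = TRUE) && length(ampa_grid) > 1 ||
      is.unsorted(nmda_grid, strictly = TRUE) && length(nmda_grid) > 1) {
    stop("sweep grids must be strictly increasing", call. = FALSE)
  }
  pts <- tidyr::expand_grid(g_ampa = ampa_grid, g_nmda = nmda_grid)

  done <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    done <- tibble::as_tibble(utils::read.csv(cache_file))
  }
  rows <- purrr::pmap_dfr(pts, function(g_ampa, g_nmda) {
    if (!is.null(done)) {
      hit <- done[abs(done$g_ampa - g_ampa) < 1e-12 &
                  abs(done$g_nmda - g_nmda) < 1e-12, ]
      if (nrow(hit) == 1) return(hit)
    }
    r <- sweep_point(params, g_ampa, g_nmda, duration, transient, rtol)
    row <- dplyr::bind_cols(tibble::tibble(g_ampa = g_ampa,
                                           g_nmda = g_nmda), r)
    if (!is.null(cache_file)) {
      has <- file.exists(cache_file)
      utils::write.table(row, cache_file, sep = ",", row.names = FALSE,
                         col.names = !has, append = has)
    }
    row
  })
  structure(rows, class = c("da_frequency_map", class(rows)),
            model = model_tag(params), params = params,
            ampa_axis = ampa_grid, nmda_axis = nmda_grid,
            settings = list(duration = duration, transient = transient,
                            rtol = rtol))
}

# continuous frequency objective used for within-cell refinement
point_frequency <- function(params, ampa, nmda, settings) {
  fs <- steady_state_summary(set_stim(params, ampa, nmda),
                             duration = settings$duration,
                             transient = settings$transient,
                             rtol = if (is.null(settings$rtol)) 1e-8
                                    else settings$rtol)
  if (is.na(fs$frequency)) 0 else fs$frequency
}

refine_axis <- function(f, lo, hi, tol) {
  if (hi <= lo) return(lo)
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

#' Synergy of AMPAR/NMDAR co-activation
#'
#' Summarises a frequency map by the maximal frequency attainable with
#' NMDAR input alone (the `g_ampa = 0` line) and the global maximum
#' over the plane, and reports the co-activation gain
#' `synergy_percent = 100 (f_joint - f_nmda_only) / f_nmda_only`.
#' With `refine = TRUE` both maxima are polished by golden-section
#' searches within the winning grid cell (two rounds alternating the
#' two axes for the joint maximum), since the grid resolution is
#' coarser than the attainable localisation of the peak.
#'
#' @param map a [frequency_map()] result whose `g_ampa = 0` line
#'   contains firing points.
#' @param refine logical: refine the maxima within their grid cells.
#' @return An object of class `da_synergy`: list with fields
#'   `f_nmda_only`, `f_joint`, `argmax` (named vector `g_ampa`,
#'   `g_nmda`), `synergy_percent`.
#' @export
synergy_report <- function(map, refine = TRUE) {
  params <- attr(map, "params")
  settings <- attr(map, "settings")
  ampa_axis <- attr(map, "ampa_axis")
  nmda_axis <- attr(map, "nmda_axis")

  line0 <- map[map$g_ampa == 0 & map$regime == "firing", ]
  if (!nrow(line0)) {
    stop("no firing on the g_ampa = 0 line: synergy is undefined",
         call. = FALSE)
  }
  firing <- map[map$regime == "firing", ]
  cell <- function(axis, x) {
    i <- which.min(abs(axis - x))
    c(axis[max(1, i - 1)], axis[min(length(axis), i + 1)])
  }

  # NMDAR-only maximum, refined along the NMDAR axis
  i0 <- which.max(line0$frequency)
  gn0 <- line0$g_nmda[i0]
  f_nmda_only <- line0$frequency[i0]
  if (refine) {
    b <- cell(nmda_axis, gn0)
    gn0 <- refine_axis(function(g) point_frequency(params, 0, g, settings),
                       b[1], b[2], tol = diff(b) / 100)
    f_nmda_only <- point_frequency(params, 0, gn0, settings)
  }

  # joint maximum, refined by alternating 1-D searches
  j <- which.max(firing$frequency)
  ga <- firing$g_ampa[j]
  gn <- firing$g_nmda[j]
  f_joint <- firing$frequency[j]
  if (refine) {
    ba <- cell(ampa_axis, ga)
    bn <- cell(nmda_axis, gn)
    for (round in 1:2) {
      gn <- refine_axis(function(g) point_frequency(params, ga, g, settings),
                        bn[1], bn[2], tol = diff(bn) / 100)
      ga <- refine_axis(function(g) point_frequency(params, g, gn, settings),
                        ba[1], ba[2], tol = max(diff(ba) / 100, 1e-6))
    }
    f_joint <- point_frequency(params, ga, gn, settings)
  }
  if (f_joint < f_nmda_only) {
    # the global maximum may sit on the g_ampa = 0 line itself
    f_joint <- f_nmda_only
    ga <- 0
    gn <- gn0
  }
  structure(
    list(f_nmda_only = f_nmda_only, f_joint = f_joint,
         argmax = c(g_ampa = ga, g_nmda = gn),
         synergy_percent = 100 * (f_joint - f_nmda_only) / f_nmda_only,
         model = attr(map, "model")),
    class = "da_synergy"
  )
}

#' @export
print.da_synergy <- function(x, ...) {
  cat(sprintf("<AMPA/NMDA synergy report (%s model)>\n", x$model))
  cat(sprintf("  NMDA-only maximum: %.3f Hz\n", x$f_nmda_only))
  cat(sprintf("  joint maximum:     %.3f Hz at (g_ampa = %.4g, g_nmda = %.4g)\n",
              x$f_joint, x$argmax["g_ampa"], x$argmax["g_nmda"]))
  cat(sprintf("  synergy:           %.1f%%\n", x$synergy_percent))
  invisible(x)
}

#' @rdname synergy_report
#' @param x a `da_synergy` object.
#' @param ... unused.
#' @export
glance.da_synergy <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    f_nmda_only = x$f_nmda_only,
    f_joint = x$f_joint,
    g_ampa_max = unname(x$argmax["g_ampa"]),
    g_nmda_max = unname(x$argmax["g_nmda"]),
    synergy_percent = x$synergy_percent
  )
}

#' Firing profile along a fixed AMPA/NMDA conductance ratio
#'
#' Evaluates steady-state firing along the ray `g_ampa = ratio *
#' g_nmda` through the conductance plane.  Ratios of interest include
#' 1/30 (a ray passing near the frequency maximum) and 1/15 (twice the
#' AMPA weight, which mostly misses the firing region).
#'
#' @param params a parameter object.
#' @param ratio AMPAR/NMDAR conductance ratio (>= 0).
#' @param nmda_grid NMDAR conductances along the ray; defaults to the
#'   model's NMDAR axis.
#' @param duration,transient,rtol simulation settings per point.
#' @return A tibble with columns `g_nmda`, `g_ampa`, `frequency`,
#'   `regime`, `amplitude`, `n_crossings`.
#' @export
ratio_line_profile <- function(params, ratio, nmda_grid = NULL,
                               duration = NULL, transient = NULL,
                               rtol = 1e-8) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 0) {
    stop("`ratio` must be a non-negative scalar", call. = FALSE)
  }
  if (is.null(nmda_grid)) nmda_grid <- default_grids(params)$nmda
  rows <- purrr::map_dfr(nmda_grid, function(gn) {
    sweep_point(params, ratio * gn, gn, duration, transient, rtol)
  })
  dplyr::bind_cols(tibble::tibble(g_nmda = nmda_grid,
                                  g_ampa = ratio * nmda_grid), rows)
}
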
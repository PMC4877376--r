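#' Export helpers
#'
#' Plain-text serialisation of the package's result objects: CSV for
#' tabular data (comma-separated, header row, `.` decimal, UTF-8) and
#' JSON for summaries.  Runs from the same inputs and settings produce
#' byte-identical payloads.
#'
#' @param x object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name da-io
NULL

#' @rdname da-io
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "da_trajectory"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname da-io
#' @export
write_map_csv <- function(x, path) {
  stopifnot(inherits(x, "da_frequency_map"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname da-io
#' @export
read_map_csv <- function(path, model = c("minimal", "biophysical"),
                         params = NULL) {
  model <- match.arg(model)
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("g_ampa", "g_nmda", "frequency", "regime")
  if (!all(need %in% names(df))) {
    stop("map CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(params)) {
    params <- if (model == "minimal") minimal_params() else bio_params()
  }
  structure(df, class = c("da_frequency_map", class(df)),
            model = model, params = params,
            ampa_axis = sort(unique(df$g_ampa)),
            nmda_axis = sort(unique(df$g_nmda)),
            settings = list(duration = NULL, transient = NULL, rtol = 1e-8))
}

#' @rdname da-io
#' @export
write_firing_json <- function(x, path) {
  stopifnot(inherits(x, "da_firing"))
  jsonlite::write_json(
    list(model = x$model, regime = x$regime, frequency = x$frequency,
         n_crossings = x$n_crossings, amplitude = x$amplitude,
         threshold = x$threshold, window = x$window,
         crossing_times = x$crossing_times),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname da-io
#' @export
write_synergy_json <- function(x, path) {
  stopifnot(inherits(x, "da_synergy"))
  jsonlite::write_json(
    list(model = x$model, f_nmda_only = x$f_nmda_only, f_joint = x$f_joint,
         g_ampa_max = unname(x$argmax["g_ampa"]),
         g_nmda_max = unname(x$argmax["g_nmda"]),
         synergy_percent = x$synergy_percent),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read and write run configurations
#'
#' A run configuration is a flat YAML file with a `model` tag
#' (`"minimal"` or `"biophysical"`), optional parameter overrides under
#' `params`, and optional simulation/sweep settings (`duration`,
#' `transient`, `rtol`, `init`, `ampa_grid`, `nmda_grid`, `g_ampa`,
#' `g_nmda`, `seed`, `out_dir`).  `read_run_config()` validates the
#' model tag and override names by constructing the parameter object.
#' Every command-line run writes its fully resolved configuration next
#' to its outputs so that it can be reproduced exactly.
#'
#' @param path YAML file path.
#' @param config a run-configuration list.
#' @return `read_run_config()`: a validated list with a `params`
#'   element replaced by the constructed parameter object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  resolve_run_config(cfg)
}

#' @rdname read_run_config
#' @export
resolve_run_config <- function(config) {
  if (is.null(config$model) ||
      !config$model %in% c("minimal", "biophysical")) {
    stop("config field `model` must be \"minimal\" or \"biophysical\"",
         call. = FALSE)
  }
  overrides <- unclass(config$params %||% list())
  ctor <- if (config$model == "minimal") minimal_params else bio_params
  sf <- if (config$model == "minimal") c("g_a", "g_n")
        else c("gbar_ampa", "gbar_nmda")
  ga <- config$g_ampa %||% overrides[[sf[1]]] %||% 0
  gn <- config$g_nmda %||% overrides[[sf[2]]] %||% 0
  overrides[intersect(sf, names(overrides))] <- NULL
  config$params <- do.call(ctor, c(list(ga, gn), overrides))
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config$params <- unclass(config$params)
  config$package_version <- as.character(utils::packageVersion("dasynergy"))
  yaml::write_yaml(config, path)
  invisible(path)
}
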
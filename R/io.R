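# Configuration, result serialization and fixtures.
#
# One structured text dialect (JSON) is used for configs and manifests;
# tabular outputs are CSV.

rm_config_schema <- list(
  model = c("d", "J_mod", "J_inh", "I0", "eps", "tau", "sigma_noise"),
  protocol = c("kind", "map", "location", "velocity", "eps", "durations",
               "n_trials", "T_morph", "mode", "n_laps"),
  numerics = c("n_phi", "n_theta", "atol", "rtol", "dt_sample"),
  seeds = c("master"),
  output = c("dir", "format"))

#' Load a run configuration
#'
#' Reads a JSON configuration with sections `model`, `protocol`,
#' `numerics`, `seeds`, `output`. Unknown sections or keys are rejected
#' with an error naming them; missing values are filled with defaults.
#'
#' @param path path to a JSON config file.
#' @return an object of class `rm_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a named list with the structure described above.
#' @export
validate_config <- function(config) {
  bad_sections <- setdiff(names(config), names(rm_config_schema))
  if (length(bad_sections) > 0)
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), rm_config_schema[[sec]])
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  model <- config$model
  defaults <- list(I0 = 1, eps = 0, tau = 10, sigma_noise = 0)
  for (k in names(defaults))
    if (is.null(model[[k]])) model[[k]] <- defaults[[k]]
  if (is.null(model$d) || is.null(model$J_mod) || is.null(model$J_inh))
    stop("config section 'model' must provide d, J_mod and J_inh")
  params <- tryCatch(
    model_params(model$d, model$J_mod, model$J_inh, model$I0, model$eps,
                 model$tau, model$sigma_noise),
    error = function(e) stop("invalid 'model' config: ", conditionMessage(e)))
  numerics <- utils::modifyList(
    list(n_phi = 257, n_theta = 256, atol = 1e-8, rtol = 1e-6,
         dt_sample = model$tau / 2), as.list(config$numerics))
  seeds <- utils::modifyList(list(master = 1), as.list(config$seeds))
  structure(list(model = params, protocol = config$protocol,
                 numerics = numerics, seeds = seeds,
                 output = as.list(config$output)),
            class = "rm_config")
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rm_config"))
  out <- list(model = unclass(config$model), protocol = config$protocol,
              numerics = config$numerics, seeds = config$seeds,
              output = config$output)
  out <- Filter(function(x) !is.null(x) && length(x) > 0, out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write run results with a manifest
#'
#' Writes a trajectory / scan data frame as CSV and a JSON manifest
#' carrying the config hash, seed and package version next to it.
#'
#' @param results a data frame (trajectory, scan, trial table, ...).
#' @param path output CSV path.
#' @param config the `rm_config` used (optional).
#' @param seed the master seed used.
#' @param events optional list of runtime events (e.g. amplitude
#'   instability) to record in the manifest.
#' @export
write_results <- function(results, path, config = NULL, seed = NA,
                          events = NULL) {
  utils::write.csv(results, path, row.names = FALSE)
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    write_config(config, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(config_hash = cfg_hash, seed = seed,
                   package_version = as.character(utils::packageVersion("ringmorph")),
                   created = format(Sys.time(), tz = "UTC"),
                   events = events)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Generate seeded desk-scale fixtures
#'
#' Writes one config per phase-diagram regime plus a small map realization,
#' all derived deterministically from one seed. The fixture set covers all
#' four regime labels.
#'
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("ringmorph-fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (w in c("homogeneous", "single_ring", "double_ring", "cylinder")) {
    p <- regime_presets(w)
    cfg <- validate_config(list(model = unclass(p),
                                seeds = list(master = seed)))
    f <- file.path(dir, paste0(w, ".json"))
    write_config(cfg, f)
    paths <- c(paths, f)
  }
  lab <- sample_correlated_maps(200, d = 0.5,
                                seed = split_seed(seed, "maps"))
  f <- file.path(dir, "maps_d0.5.csv")
  write_maps(lab, f, seed = split_seed(seed, "maps"))
  invisible(c(paths, f))
}
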
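#' Run configuration with study defaults
#'
#' Collects every tunable of the downstream modules, the random seed and the
#' output directory into one nested list that serializes losslessly to YAML.
#' Defaults are the study's analysis settings (5th-order 1 Hz Butterworth,
#' 256-sample / 50%-overlap spectrogram windows, 12-18 Hz band, 0.95
#' likelihood cutoff, 0.5 cm/s / 0.5 s immobility rule, 5-20 min analysis
#' window, sex fixed effect + individual random intercept, FDR 0.05).
#'
#' @param ... Named overrides of any top-level section (partial lists are
#'   merged over the defaults).
#' @param seed Integer seed used for every stochastic step of a run.
#' @param output_dir Where CLI subcommands write their tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(..., seed = 1L, output_dir = "motorpheno-out") {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = output_dir,
    spectral = unclass(spectral_params()),
    kinematics = unclass(kinematics_params()),
    rearing = unclass(rearing_params()),
    abundance = unclass(abundance_params()),
    tracing = unclass(tracing_params()),
    sim = list(
      accel = unclass(tremor_sim_params()),
      pose = unclass(bout_sim_params()),
      composition = unclass(composition_sim_params())
    ),
    alignment = "simultaneous_start"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort_config(sprintf("Unknown config section(s): %s.",
                                        paste(bad, collapse = ", ")))
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip `read_config(write_config(cfg))` is lossless.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(yaml_prepare(unclass(cfg)), path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  normalize_config(yaml_restore(yaml::read_yaml(path)))
}

# Rebuild a config read from YAML/JSON through the parameter constructors so
# every field regains its canonical type and validation.
normalize_config <- function(raw) {
  rebuild <- function(ctor, x) unclass(do.call(ctor, as.list(x)))
  cfg <- list(
    seed = as.integer(raw$seed),
    output_dir = raw$output_dir,
    spectral = rebuild(spectral_params, raw$spectral),
    kinematics = rebuild(kinematics_params, raw$kinematics),
    rearing = rebuild(rearing_params, raw$rearing),
    abundance = rebuild(abundance_params, raw$abundance),
    tracing = rebuild(tracing_params, raw$tracing),
    sim = list(accel = rebuild(tremor_sim_params, raw$sim$accel),
               pose = rebuild(bout_sim_params, raw$sim$pose),
               composition = rebuild(composition_sim_params, raw$sim$composition)),
    alignment = raw$alignment
  )
  structure(cfg, class = "run_config")
}

# yaml drops the names of named atomic vectors; store them as maps instead
# and fold maps of scalars back into named vectors on read.
yaml_prepare <- function(x) {
  if (is.list(x)) return(lapply(x, yaml_prepare))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

yaml_restore <- function(x) {
  if (is.integer(x)) return(as.numeric(x))
  if (!is.list(x)) return(x)
  x <- lapply(x, yaml_restore)
  if (length(x) && !is.null(names(x)) && all(names(x) != "") &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1L, logical(1)))) {
    return(unlist(x))
  }
  x
}

#' Write a JSON run manifest
#'
#' The manifest records the full configuration, the seed, the subcommand and
#' package/R versions: it alone suffices to regenerate any simulated dataset
#' bit for bit (see [cli_main()]).
#'
#' @param dir Output directory.
#' @param cfg A [run_config()].
#' @param command CLI subcommand recorded for re-execution.
#' @param extra Named list of additional fields.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg, command, extra = list()) {
  manifest <- c(list(
    command = command,
    config = yaml_prepare(unclass(cfg)),
    versions = list(motorpheno = as.character(packageVersion("motorpheno")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @param path Path to a `manifest.json`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  m$config <- normalize_config(yaml_restore(m$config))
  m
}
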
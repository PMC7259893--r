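# Configuration I/O, fixture emission and result serialization.

#' Serialize a scenario to a plain list (YAML-ready)
#' @param sc A `MicroclimateScenario`.
#' @return A named list round-trippable through [scenario_from_list()].
#' @export
scenario_to_list <- function(sc) {
  out <- unclass(sc)
  out$substrate <- unclass(out$substrate)
  out
}

#' Rebuild a scenario from a plain list
#' @param x A list produced by [scenario_to_list()] (or parsed from YAML).
#' @return A validated `MicroclimateScenario`.
#' @export
scenario_from_list <- function(x) {
  x$substrate <- structure(x$substrate, class = "SoilProperties")
  sc <- structure(x, class = "MicroclimateScenario")
  validate_scenario(sc)
  sc
}

#' Write the shipped scenario and animal parameter sets as files
#'
#' Emits the six microclimate scenarios and the two taxon dimension sets as
#' YAML files; output is deterministic (byte-identical across runs).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in c("hot", "moderate", "cold")) for (h in c("arid", "humid")) {
    nm <- paste(t, h, sep = "_")
    p <- file.path(dir, paste0("scenario_", nm, ".yaml"))
    yaml::write_yaml(scenario_to_list(build_scenario(nm)), p, precision = 15)
    paths <- c(paths, p)
  }
  for (taxon in c("coelophysis", "plateosaurus")) {
    src <- system.file("extdata", paste0(taxon, ".yaml"), package = "dinotherm")
    p <- file.path(dir, paste0(taxon, ".yaml"))
    file.copy(src, p, overwrite = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a day environment as CSV
#' @param day_env A `DayEnvironment`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_environment_csv <- function(day_env, path) {
  sun <- day_env$sun; shade <- day_env$shade
  out <- rbind(sun, shade)
  names(out) <- sub("^t_", "t_C_", names(out))
  utils::write.csv(format(out, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TNZ sweep as CSV
#'
#' Grid columns (t_air_C, q_met_W, t_core_C) followed by a summary row with
#' the critical temperatures.
#'
#' @param tnz A `TNZResult`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tnz_csv <- function(tnz, path) {
  utils::write.csv(format(tnz$grid, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  cat(sprintf("# lower_critical_C,%s\n# upper_critical_C,%s\n# width_C,%s\n",
              format(tnz$lower_critical), format(tnz$upper_critical),
              format(tnz$width)),
      file = path, append = TRUE)
  invisible(path)
}

#' Write a viability matrix summary as CSV
#' @param vm A `ViabilityMatrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(vm, path) {
  utils::write.csv(format(vm$summary, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A small YAML snapshot of the configuration, package version and experiment
#' label alongside the outputs.
#'
#' @param dir Output directory.
#' @param experiment Experiment label.
#' @param config Arbitrary configuration list to snapshot.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, experiment, config = list()) {
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    experiment = experiment,
    package = "dinotherm",
    version = as.character(utils::packageVersion("dinotherm")),
    config = config
  ), p)
  invisible(p)
}
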
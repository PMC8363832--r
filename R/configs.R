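# YAML serialization of scenario configurations. Shipped configs for every
# scenario cell live under inst/extdata/scenarios.

#' Load a scenario configuration from a YAML file
#'
#' @param path Path to a YAML file with a `scenario` mapping (schema
#'   version 1); see the files under
#'   `system.file("extdata", "scenarios", package = "mlmgm")`.
#' @return A [scenario_config()].
#' @export
#' @examples
#' p <- system.file("extdata", "scenarios", "practice_only_accelerated.yaml",
#'                  package = "mlmgm")
#' load_scenario_config(p)
load_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    stop("unsupported scenario config schema: ", raw$schema_version)
  sc <- raw$scenario
  args <- sc[intersect(names(sc),
                       c("scenario_name", "design", "n_waves", "sampling",
                         "variability", "frame", "mcar_rate",
                         "n_replicants", "master_seed"))]
  if (!is.null(sc$fixed)) args$fixed <- unlist(sc$fixed)
  if (!is.null(sc$random)) args$random <- sc$random
  do.call(scenario_config, args)
}

#' Write a scenario configuration to a YAML file
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  sc <- unclass(config)
  sc$fixed <- as.list(sc$fixed)
  yaml::write_yaml(list(schema_version = 1L, scenario = sc), path)
  invisible(path)
}

#' List the scenario configurations shipped with the package
#'
#' @return Named character vector of YAML file paths.
#' @export
list_scenario_configs <- function() {
  dir <- system.file("extdata", "scenarios", package = "mlmgm")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(files, sub("\\.yaml$", "", basename(files)))
}
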
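#' Full run configuration
#'
#' Nested configuration binding the modules into reproducible runs: phantom
#' parameters, tree parameters, transport parameters, trial parameters and
#' an output directory. Used by the command-line interface
#' (`inst/cli/strokesim`); every artifact written by a run is stamped with
#' `config_hash(run_config)` and the master seed.
#'
#' @param phantom Named list of [phantom_config()] overrides.
#' @param tree Named list of [build_vasculature()] overrides (e.g.
#'   `leaves_per_hemisphere`, `generations`, `seed`).
#' @param transport Named list of [transport_config()] overrides.
#' @param trial Named list: `diameters` or `distribution` (`kind`,
#'   `diameter`, `min`, `max`), `n`, `master_seed`.
#' @param output Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = list(), tree = list(), transport = list(),
                       trial = list(), output = "strokesim-out") {
  cfg <- list(phantom = phantom, tree = tree, transport = transport,
              trial = modifyList(list(n = 25, master_seed = 1), trial),
              output = output)
  cfg$hash <- config_hash(cfg[c("phantom", "tree", "transport", "trial")])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `phantom`, `tree`, `transport`, `trial`, `output`;
#' missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading YAML configs requires the yaml package")
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path) %||% list()
  trial <- y$trial %||% list()
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; restore it
  names(trial)[names(trial) == "FALSE"] <- "n"
  run_config(phantom = y$phantom %||% list(), tree = y$tree %||% list(),
             transport = y$transport %||% list(), trial = trial,
             output = y$output %||% "strokesim-out")
}

# materialise the configured objects
build_from_config <- function(cfg) {
  phantom <- build_phantom(do.call(phantom_config, cfg$phantom))
  tree <- do.call(build_vasculature, c(list(phantom = phantom), cfg$tree))
  transport <- do.call(transport_config, cfg$transport)
  list(phantom = phantom, tree = tree, transport = transport)
}
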
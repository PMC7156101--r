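#' Read and validate a scenario configuration
#'
#' A scenario file (YAML or JSON, chosen by extension) describes one ESS
#' analysis: the resource distribution (either `atoms: [[R, w], ...]` or
#' `density: {name: uniform, Rmin, Rmax}`), the trait model (`r`, `a`), the
#' selection `regime`, and optional `solver` settings (`tol`, `bracket`).
#' Malformed configurations fail with a message naming the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `coop_scenario` list with elements `dist` (a
#'   [resource_atoms()]/[resource_density()] object), `model` (a
#'   [trait_model()]), `regime`, `tol`, `bracket`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scenario file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort(sprintf("Unsupported scenario format '.%s' (use yaml or json).", ext))
  )
  validate_scenario(raw)
}

#' @rdname read_scenario
#' @param config A raw scenario list (as parsed from file).
#' @export
validate_scenario <- function(config) {
  if (!is.list(config)) abort("Scenario must be a mapping/object.")
  d <- config$distribution
  if (is.null(d)) abort("Scenario is missing `distribution`.")
  dist <- if (!is.null(d$atoms)) {
    atoms <- d$atoms
    if (is.list(atoms)) atoms <- do.call(rbind, lapply(atoms, unlist))
    atoms <- matrix(as.numeric(atoms), ncol = 2)
    resource_atoms(atoms[, 1], atoms[, 2])
  } else if (!is.null(d$density)) {
    dd <- d$density
    if (is.null(dd$name) || dd$name != "uniform") {
      abort('Only `density: {name: uniform, Rmin, Rmax}` is supported in files;\nbuild other densities with resource_density() in R.')
    }
    resource_uniform(as.numeric(dd$Rmin), as.numeric(dd$Rmax))
  } else {
    abort("`distribution` needs either `atoms` or `density`.")
  }
  if (is.null(config$r)) abort("Scenario is missing `r`.")
  model <- trait_model(as.numeric(config$r), as.numeric(config$a %||% 1))
  regime <- .check_regime(config$regime %||% "soft")
  solver <- config$solver %||% list()
  structure(
    list(dist = dist, model = model, regime = regime,
         tol = as.numeric(solver$tol %||% 1e-10),
         bracket = if (!is.null(solver$bracket)) as.numeric(solver$bracket)),
    class = "coop_scenario"
  )
}

#' Solve the ESS described by a scenario
#'
#' @param scenario A `coop_scenario` from [read_scenario()] /
#'   [validate_scenario()].
#' @return An `ess_fit` (see [ess_solve()]).
#' @export
ess_from_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "coop_scenario"))
  ess_solve(scenario$dist, scenario$model, scenario$regime,
            bracket = scenario$bracket, tol = scenario$tol)
}

#' Run manifest
#'
#' Captures what produced a set of outputs: the command name, a stable hash
#' of the configuration, the seed, the package version and a timestamp.
#' Reruns with an identical manifest input (command, config, seed)
#' reproduce outputs exactly, stochastic stages included.
#'
#' @param command Short command name (e.g. `"ess"`, `"reproduce"`).
#' @param config The configuration object the run used.
#' @param seed Integer seed (or `NULL`).
#' @param outputs Character vector of output paths.
#' @return A `run_manifest` list; write it with [jsonlite::write_json()].
#' @export
run_manifest <- function(command, config, seed = NULL, outputs = character()) {
  structure(
    list(
      command = command,
      config_hash = rlang::hash(config),
      seed = seed,
      package = "coopscape",
      version = as.character(utils::packageVersion("coopscape")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = outputs
    ),
    class = "run_manifest"
  )
}
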
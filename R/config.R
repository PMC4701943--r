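#' Default configuration
#'
#' All tunable parameters in one list, mirroring the YAML layout accepted
#' by [read_spinekit_config()]: `biophysics` (cable, synapse, integrator,
#' coupling convention, parent dendrite), `morphometry` (stations, neck
#' rule, class threshold) and `aliases` (CSV header map).
#'
#' @return Nested list of parameter objects.
#' @export
default_spinekit_config <- function() {
  list(biophysics = list(cable = cable_params(),
                         synapse = synapse_params(),
                         integrator = sim_config(),
                         coupling = "symmetric",
                         parent = c(diameter = 3, length = 20)),
       morphometry = list(n_stations = 32, neck_frac = 0.7,
                          head_min_diameter = 0.43),
       aliases = imaris_alias_map())
}

#' Read a YAML configuration file
#'
#' Any subset of the keys may be present; missing values keep their
#' defaults. Example layout (units as in the parameter constructors):
#'
#' ```yaml
#' biophysics:
#'   cable: {Cm: 1, Ri: 100, Rm: 20000, Em: -70}
#'   synapse: {tau_syn: 2, Esyn: 0, gbar_density: 132, onset: 0}
#'   integrator: {dt: 1, duration: 50}
#'   coupling: symmetric
#'   parent: {diameter: 3, length: 20}
#' morphometry: {n_stations: 32, neck_frac: 0.7, head_min_diameter: 0.43}
#' aliases: {Volume: "^my volume header$"}
#' ```
#'
#' @param path YAML file.
#' @return Nested list as [default_spinekit_config()].
#' @export
read_spinekit_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  d <- default_spinekit_config()
  b <- y$biophysics
  if (!is.null(b$cable)) d$biophysics$cable <-
    do.call(cable_params, utils::modifyList(unclass(d$biophysics$cable), b$cable))
  if (!is.null(b$synapse)) d$biophysics$synapse <-
    do.call(synapse_params, utils::modifyList(unclass(d$biophysics$synapse), b$synapse))
  if (!is.null(b$integrator)) d$biophysics$integrator <-
    do.call(sim_config, utils::modifyList(unclass(d$biophysics$integrator), b$integrator))
  if (!is.null(b$coupling)) {
    d$biophysics$coupling <- match.arg(b$coupling, c("symmetric", "child_ra"))
  }
  if (!is.null(b$parent)) {
    d$biophysics$parent <- c(diameter = b$parent$diameter %||% 3,
                             length = b$parent$length %||% 20)
  }
  if (!is.null(y$morphometry)) {
    d$morphometry <- utils::modifyList(d$morphometry, y$morphometry)
  }
  if (!is.null(y$aliases)) {
    d$aliases[names(y$aliases)] <- unlist(y$aliases)
  }
  d
}
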
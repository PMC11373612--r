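# Experiment configuration: one YAML file = one experiment.
#
# Sections: potential, thermo, simulation, committor, correlators, msm,
# output. Unknown keys anywhere are rejected so a typo in a parameter name
# cannot silently fall back to a default.

.cfg_schema <- list(
  potential   = c("family", "params", "domain"),
  thermo      = c("kBT", "D", "mass"),
  simulation  = c("integrator", "dt", "n_steps", "stride", "seed",
                  "initial_position", "initial_velocity"),
  committor   = c("z1", "z2", "spacing"),
  correlators = c("estimators", "lag_max", "n_lags", "nblocks",
                  "plateau_rel_tol", "plateau_window", "dividing_point"),
  msm         = c("bins", "bin_lo", "bin_hi", "lag"),
  output      = c("dir")
)

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description (or takes an equivalent nested
#' list), checks every section and key against the schema, fills defaults,
#' and requires a seed for the stochastic stages.
#'
#' @param path Path to a YAML file, or `NULL` when `cfg` is given.
#' @param cfg A nested list equivalent to the YAML contents.
#' @return A validated config list of class `experiment_config`.
#' @export
experiment_config <- function(path = NULL, cfg = NULL) {
  if (is.null(cfg)) {
    if (is.null(path)) stop("supply a path or a config list")
    cfg <- yaml::read_yaml(path)
  }
  bad_sections <- setdiff(names(cfg), names(.cfg_schema))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (s in names(cfg)) {
    bad <- setdiff(names(cfg[[s]]), .cfg_schema[[s]])
    if (length(bad))
      stop("unknown key(s) in [", s, "]: ", paste(bad, collapse = ", "))
  }
  need <- c("potential", "simulation")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing section(s): ", paste(miss, collapse = ", "))
  # defaults
  cfg$thermo <- modifyList(list(kBT = 0.5915, D = 1), cfg$thermo %||% list())
  cfg$committor <- modifyList(list(z1 = -7, z2 = 7, spacing = 0.001),
                              cfg$committor %||% list())
  cfg$correlators <- modifyList(
    list(estimators = c("bb", "zz", "qq", "abqq"), lag_max = 50,
         nblocks = 20, plateau_rel_tol = 0.05, plateau_window = 20,
         dividing_point = NULL),
    cfg$correlators %||% list())
  cfg$msm <- modifyList(list(bins = 120, bin_lo = -12, bin_hi = 12, lag = 0.5),
                        cfg$msm %||% list())
  cfg$output <- modifyList(list(dir = "ratepaths-out"), cfg$output %||% list())
  sim <- cfg$simulation
  if (is.null(sim$seed)) stop("simulation.seed is mandatory")
  if (identical(sim$integrator, "langevin") && is.null(cfg$thermo$mass))
    stop("integrator 'langevin' requires thermo.mass")
  structure(cfg, class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_hash <- function(cfg) {
  # content hash of the canonicalized config, for provenance in outputs
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  raw <- utf8ToInt(s)
  h <- 5381
  for (x in raw) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", as.integer(h))
}
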
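# End-to-end experiment runner: potential -> quadrature committor ->
# simulation -> correlators -> Markov model, with every stage logged and
# all outputs written under the configured directory.

.log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  message(msg)
  c(log, msg)
}

#' Run a full rate-estimation experiment
#'
#' Executes the pipeline described by an [experiment_config()]: builds the
#' potential and thermodynamic state, solves the quadrature committor and
#' two-state summary, simulates the configured trajectory, estimates the
#' requested correlators and their limiting slopes, builds a Markov model
#' at the configured lag, and writes committor/correlation CSVs, the
#' spectral model JSON, and a summary JSON collecting every flux estimate.
#' Stage failures propagate with the stage name; outputs of completed
#' stages are retained on disk.
#'
#' @param cfg An [experiment_config()] (or a path to a YAML config).
#' @return Invisibly, a list with `summary` (named list of the headline
#'   numbers), `committor`, `trajectory`, `correlations`, `rates`, `msm`,
#'   `log`, `output_dir`.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- experiment_config(cfg)
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .log_stage(log, "config", "hash %s, unit bridge %g amu*A^2/ps^2 per kcal/mol",
                    .cfg_hash(cfg), KCAL_PER_MOL_TO_AMU_A2_PS2)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  pot <- stage("potential", do.call(potential_1d, c(
    list(family = cfg$potential$family),
    if (!is.null(cfg$potential$params)) list(params = cfg$potential$params),
    if (!is.null(cfg$potential$domain)) list(domain = unlist(cfg$potential$domain)))))
  th <- stage("potential", thermo_state(cfg$thermo$kBT, cfg$thermo$D, cfg$thermo$mass))

  cc <- cfg$committor
  cp <- stage("committor", solve_committor_1d(pot, th, cc$z1, cc$z2, cc$spacing))
  profile <- stage("committor", equilibrium_profile(pot, th, spacing = cc$spacing))
  tss <- stage("committor", two_state_summary(pot, th, cc$z1, cc$z2,
                                              spacing = cc$spacing))
  write_committor_csv(cp, file.path(cfg$output$dir, "committor.csv"))
  log <- .log_stage(log, "committor",
                    "J_quadrature = %.4e ps^-1, tau* = %.1f ps, seed-free",
                    tss$J_AB, tss$tau_star)

  sim <- cfg$simulation
  sp <- stage("simulate", sim_params(sim$integrator, sim$dt, sim$n_steps,
                                     sim$stride %||% 1L, sim$seed,
                                     sim$initial_position %||% cp$z1 / 2,
                                     sim$initial_velocity))
  traj <- stage("simulate", if (sp$integrator == "langevin")
    simulate_langevin(pot, th, sp) else simulate_brownian(pot, th, sp))
  log <- .log_stage(log, "simulate", "%s (%s), %d frames, dt %g ps, seed %d",
                    sp$integrator,
                    if (sp$integrator == "langevin") "BAOAB" else "Euler-Maruyama",
                    length(traj$positions), sp$dt, sp$seed)

  co <- cfg$correlators
  zdag <- co$dividing_point %||% tss$dividing_point
  ds_pos <- dividing_surface("position", zdag)
  dt_out <- sp$dt * sp$stride
  n_lags <- co$n_lags %||% min(floor(co$lag_max / dt_out), 400)
  lag_step <- max(1, floor(co$lag_max / dt_out / n_lags))
  lags <- (0:n_lags) * lag_step * dt_out
  lags <- lags[lags <= co$lag_max]
  ests <- list()
  if ("bb" %in% co$estimators)
    ests$C_BB <- stage("correlate", indicator_correlation(traj, ds_pos,
                                                          lags = lags, nblocks = co$nblocks))
  if ("zz" %in% co$estimators)
    ests$C_zz <- stage("correlate", position_correlation(traj, ds_pos,
                                                         lags = lags, nblocks = co$nblocks))
  if ("qq" %in% co$estimators)
    ests$C_qq <- stage("correlate", committor_correlation(traj, cp,
                                                          lags = lags, nblocks = co$nblocks))
  if ("abqq" %in% co$estimators)
    ests$C_ABqq <- stage("correlate", restricted_committor_correlation(
      traj, cp, lags = lags, nblocks = co$nblocks))
  rates <- lapply(ests, function(cs) {
    tryCatch(extract_flux(cs, rel_tol = co$plateau_rel_tol,
                          window = co$plateau_window, pA = tss$pA),
             error = function(e) e)
  })
  for (nm in names(ests)) {
    write_correlation_csv(ests[[nm]], file.path(cfg$output$dir,
                                                paste0(tolower(nm), ".csv")))
    if (inherits(rates[[nm]], "rate_estimate"))
      log <- .log_stage(log, "correlate", "%s slope J = %.4e +- %.1e ps^-1",
                        nm, rates[[nm]]$J_AB, rates[[nm]]$J_se)
    else
      log <- .log_stage(log, "correlate", "%s: %s", nm,
                        conditionMessage(rates[[nm]]))
  }

  mm <- cfg$msm
  sm <- stage("msm", spectral_decomposition(build_transition_matrix(
    traj, uniform_bins(mm$bin_lo, mm$bin_hi, mm$bins), mm$lag)))
  write_spectral_json(sm, file.path(cfg$output$dir, "msm.json"))
  log <- .log_stage(log, "msm", "mu2 = %.4e ps^-1 at lag %g ps (%d bins)",
                    sm$mus[2], mm$lag, nrow(sm$T))

  summary <- list(
    family = pot$family, seed = sim$seed, config_hash = .cfg_hash(cfg),
    pA = tss$pA, pB = tss$pB,
    J_quadrature = tss$J_AB, tau_star_quadrature = tss$tau_star,
    tau_transit = tss$tau_transit, p_reactive = tss$p_reactive,
    mu2_msm = sm$mus[2], tau_star_msm = 1 / sm$mus[2],
    J_msm_two_state = two_state_flux(sm$mus[2], mm$lag, tss$tau_transit,
                                     tss$pA, tss$pB))
  for (nm in names(rates))
    if (inherits(rates[[nm]], "rate_estimate")) {
      summary[[paste0("J_", tolower(nm))]] <- rates[[nm]]$J_AB
      summary[[paste0("J_", tolower(nm), "_se")]] <- rates[[nm]]$J_se
    }
  write_summary_json(summary, file.path(cfg$output$dir, "summary.json"))
  writeLines(log, file.path(cfg$output$dir, "run.log"))
  invisible(list(summary = summary, committor = cp, trajectory = traj,
                 correlations = ests, rates = rates, msm = sm,
                 two_state = tss, log = log, output_dir = cfg$output$dir))
}
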
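# Shared fixtures: quadrature reference objects and the handful of long
# simulations several test files analyse. Everything is built lazily and
# cached for the session so no trajectory is generated twice.

.rp_cache <- new.env(parent = emptyenv())

rp_cached <- function(key, expr) {
  if (!exists(key, envir = .rp_cache)) assign(key, force(expr), envir = .rp_cache)
  get(key, envir = .rp_cache)
}

rp_th <- function() thermo_state()                 # kBT = 0.5915, D = 1
rp_thm <- function() thermo_state(mass = 20)       # + 20 amu for Langevin

# quadrature reference bundle per family
rp_quad <- function(fam) rp_cached(paste0("quad_", fam), {
  pot <- potential_1d(fam)
  th <- rp_th()
  list(pot = pot,
       cp = solve_committor_1d(pot, th),
       profile = equilibrium_profile(pot, th),
       tss = two_state_summary(pot, th))
})

# 1 microsecond of Brownian dynamics per family (benchmark protocol:
# dt = 0.005 ps), stored every 0.5 ps
rp_bd_1us <- function(fam) rp_cached(paste0("bd1us_", fam), {
  i <- match(fam, c("narrow", "medium", "broad"))
  sp <- sim_params("brownian", dt = 0.005, n_steps = 2e8, stride = 100,
                   seed = 1000 + i, initial_position = -4)
  simulate_brownian(potential_1d(fam), rp_th(), sp)
})

# short fine-stride runs for Markovianity / velocity-relaxation checks
rp_bd_fine <- function() rp_cached("bd_fine", {
  sp <- sim_params("brownian", dt = 0.005, n_steps = 2e6, stride = 1,
                   seed = 11, initial_position = -4)
  simulate_brownian(potential_1d("narrow"), rp_th(), sp)
})

rp_lang_fine <- function() rp_cached("lang_fine", {
  sp <- sim_params("langevin", dt = 0.001, n_steps = 1e7, stride = 1,
                   seed = 12, initial_position = -4)
  simulate_langevin(potential_1d("broad"), rp_thm(), sp)
})

# pooled correlators from 5 x 100 ns of broad-barrier Langevin dynamics
# (aggregate 0.5 us), stored every 0.1 ps, lag grid 0-20 ps
rp_lang_pooled <- function() rp_cached("lang_pooled", {
  pot <- potential_1d("broad")
  th <- rp_thm()
  cp <- rp_quad("broad")$cp
  lags <- seq(0, 20, by = 0.1)
  per <- list(C_qq = list(), C_BB = list(), C_zz = list(), C_ABqq = list())
  for (w in 1:5) {
    sp <- sim_params("langevin", dt = 0.001, n_steps = 1e8, stride = 100,
                     seed = 7000 + w,
                     initial_position = if (w %% 2) -8.5 else 8.5)
    traj <- simulate_langevin(pot, th, sp)
    per$C_qq[[w]] <- committor_correlation(traj, cp, lags = lags, nblocks = 4)
    per$C_BB[[w]] <- indicator_correlation(traj, lags = lags, nblocks = 4)
    per$C_zz[[w]] <- position_correlation(traj, lags = lags, nblocks = 4)
    per$C_ABqq[[w]] <- restricted_committor_correlation(traj, cp, lags = lags,
                                                        nblocks = 4)
    rm(traj)
  }
  lapply(per, pool_correlation_series)
})
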
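# Deterministic fixture generation: short trajectories and synthetic
# Markov chains the test suite analyses instead of simulating at
# benchmark scale.

#' Generate the canned test fixtures
#'
#' Writes, under `dir`: one short Brownian trajectory per benchmark family
#' (1e5 steps at dt = 0.005 ps), the corresponding quadrature committor
#' CSVs, and a synthetic two-state Markov chain (`two_state_chain.csv`,
#' switching probability 0.1 per step). Deterministic for a given seed:
#' regenerating with the same seed produces identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_steps Steps per trajectory (default 1e5).
#' @return Invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(seed, dir, n_steps = 1e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- thermo_state()
  paths <- character(0)
  for (fam in c("narrow", "medium", "broad")) {
    pot <- potential_1d(fam)
    sp <- sim_params("brownian", dt = 0.005, n_steps = n_steps, stride = 10,
                     seed = seed + match(fam, c("narrow", "medium", "broad")),
                     initial_position = -4)
    traj <- simulate_brownian(pot, th, sp)
    p1 <- file.path(dir, paste0("traj_", fam, ".tsv"))
    write_trajectory_txt(traj, p1)
    cp <- solve_committor_1d(pot, th, spacing = 0.01)
    p2 <- file.path(dir, paste0("committor_", fam, ".csv"))
    write_committor_csv(cp, p2)
    paths <- c(paths, p1, p2)
  }
  chain <- simulate_two_state_chain(n = 20000, p_switch = 0.1, seed = seed)
  p3 <- file.path(dir, "two_state_chain.csv")
  write.csv(data.frame(state = chain), p3, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p3)
  invisible(paths)
}

#' Synthetic two-state Markov chain
#'
#' Symmetric chain on states {0, 1} with switching probability `p_switch`
#' per step; the exact transition matrix is
#' \[\[1-p, p\], \[p, 1-p\]\] with second eigenvalue 1 - 2p.
#'
#' @param n Chain length.
#' @param p_switch Per-step switching probability.
#' @param seed Integer seed.
#' @param state0 Initial state (0 or 1).
#' @return Integer vector of states.
#' @export
simulate_two_state_chain <- function(n, p_switch, seed, state0 = 0L) {
  set.seed(as.integer(seed))
  flips <- runif(n - 1) < p_switch
  as.integer(cumsum(c(state0, flips)) %% 2L)
}

#' Wrap a discrete state series as a trajectory-like object
#'
#' Lets the spectral-model machinery run on synthetic chains: states are
#' mapped to positions (state 0 -> -1, state 1 -> +1) sampled at unit
#' intervals of `dt`.
#'
#' @param states Integer state series.
#' @param dt Nominal time per step in ps.
#' @return A `trajectory`.
#' @export
chain_as_trajectory <- function(states, dt = 1) {
  sp <- sim_params("brownian", dt = dt, n_steps = length(states) - 1,
                   stride = 1, seed = 0, initial_position = 0)
  pot <- potential_1d("flat", domain = c(-2, 2))
  structure(list(times = (seq_along(states) - 1) * dt,
                 positions = ifelse(states > 0, 1, -1),
                 velocities = NULL, params = sp, potential = pot,
                 thermo = thermo_state()),
            class = "trajectory")
}
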
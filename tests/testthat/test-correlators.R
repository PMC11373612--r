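# Correlation-function estimators and flux extraction.

# small helper: a trajectory-like wrapper around an arbitrary series
series_traj <- function(x, dt = 1) {
  sp <- sim_params("brownian", dt = dt, n_steps = length(x) - 1, stride = 1,
                   seed = 0, initial_position = x[1])
  structure(list(times = (seq_along(x) - 1) * dt, positions = x,
                 velocities = NULL, params = sp,
                 potential = potential_1d("flat", domain = range(x) + c(-1, 1)),
                 thermo = rp_th()),
            class = "trajectory")
}

test_that("a constant observable correlates to its square at every lag", {
  tr <- series_traj(rnorm(5000))
  cs <- estimate_correlation(tr, function(z) rep(3, length(z)), lags = 0:10)
  expect_equal(cs$values, rep(9, 11), tolerance = 1e-12)
  # lag 0 of the raw correlator is the mean square
  cs2 <- estimate_correlation(tr, identity, lags = 0:2)
  expect_equal(cs2$values[1], mean(tr$positions^2))
})

test_that("an AR(1) series is recovered within its block error bars", {
  set.seed(77)
  a <- exp(-1 / 20)                 # correlation time 20 steps
  n <- 2e5
  x <- stats::filter(rnorm(n, 0, sqrt(1 - a^2)), a, method = "recursive")
  tr <- series_traj(as.numeric(x))
  lags <- c(0, 5, 10, 20, 40)
  cs <- estimate_correlation(tr, identity, lags = lags)
  expect_true(all(abs(cs$values - a^lags) < 3 * pmax(cs$stderr, 1e-3)))
})

test_that("lags beyond the trajectory length are rejected", {
  tr <- series_traj(rnorm(100))
  expect_error(estimate_correlation(tr, identity, lags = c(0, 150)), "length")
  expect_error(estimate_correlation(tr, identity, lags = 0.5), "multiples")
})

test_that("indicator correlator vanishes at zero lag and decorrelates to pApB", {
  chain <- simulate_two_state_chain(5e4, p_switch = 0.2, seed = 8)
  tr <- chain_as_trajectory(chain)
  cs <- indicator_correlation(tr, lags = c(0, 1, 5, 30, 40))
  expect_identical(cs$values[1], 0)
  pApB <- mean(chain) * (1 - mean(chain))
  expect_lt(abs(cs$values[5] - pApB), 3 * cs$stderr[5])
  # normalized population correlator is the exact algebraic complement
  cp_ <- population_correlation(tr, lags = c(0, 1, 5, 30, 40))
  expect_equal(cp_$values, 1 - cs$values / pApB, tolerance = 1e-12)
})

test_that("a one-state trajectory cannot be correlated", {
  tr <- series_traj(abs(rnorm(500)) + 1)   # never below the surface at 0
  expect_error(indicator_correlation(tr, dividing_surface("position", 0)),
               "never visits")
})

test_that("position correlator is pinned to 0 at t = 0 and rejects constants", {
  chain <- simulate_two_state_chain(2e4, p_switch = 0.2, seed = 9)
  tr <- chain_as_trajectory(chain)
  cs <- position_correlation(tr, lags = 0:5)
  expect_identical(cs$values[1], 0)
  expect_error(position_correlation(series_traj(rep(1, 100)), lags = 0:2),
               "variance")
})

test_that("a step-function committor reproduces the indicator correlator exactly", {
  chain <- simulate_two_state_chain(2e4, p_switch = 0.15, seed = 10)
  tr <- chain_as_trajectory(chain)   # positions exactly -1 / +1
  step_cp <- structure(list(grid = c(-2, -1e-12, 0, 2), q = c(0, 0, 1, 1),
                            z1 = -2, z2 = 2, thermo = rp_th(), pot = NULL),
                       class = "committor_profile")
  lags <- 0:20
  expect_identical(committor_correlation(tr, step_cp, lags = lags)$values,
                   indicator_correlation(tr, lags = lags)$values)
})

test_that("restricted committor correlator reduces to <H_A(0) H_B(t)> for a step q", {
  chain <- simulate_two_state_chain(2e4, p_switch = 0.15, seed = 12)
  tr <- chain_as_trajectory(chain)
  step_cp <- structure(list(grid = c(-2, -1e-12, 0, 2), q = c(0, 0, 1, 1),
                            z1 = -2, z2 = 2, thermo = rp_th(), pot = NULL),
                       class = "committor_profile")
  cs <- restricted_committor_correlation(tr, step_cp, lags = 0:10)
  expect_identical(cs$values[1], 0)
  h <- as.numeric(tr$positions >= 0)
  direct <- vapply(0:10, function(l) {
    n <- length(h)
    mean((1 - h[1:(n - l)]) * h[(1 + l):n])
  }, 0)
  expect_equal(cs$values, direct, tolerance = 1e-12)
})

test_that("derivatives are exact for polynomial series", {
  lags <- seq(0, 10, by = 0.5)
  lin <- ratepaths:::.new_corr_series(lags, 3.5 * lags, rep(0.1, length(lags)),
                                      "C_qq", 100)
  d <- correlation_derivative(lin)
  expect_equal(d$values[2:(length(lags) - 1)], rep(3.5, length(lags) - 2))
  quad <- ratepaths:::.new_corr_series(lags, 2 * lags^2, rep(0, length(lags)),
                                       "C_qq", 100)
  dq <- correlation_derivative(quad)
  i <- 2:(length(lags) - 1)
  expect_equal(dq$values[i], 4 * lags[i], tolerance = 1e-10)
  expect_error(correlation_derivative(
    ratepaths:::.new_corr_series(c(0, 1, 3), 1:3, rep(0, 3), "x", 1)),
    "uniform")
})

test_that("flux extraction finds the slope of a linear series immediately", {
  lags <- seq(0, 10, by = 0.1)
  lin <- ratepaths:::.new_corr_series(lags, 2e-4 * lags,
                                      rep(1e-6, length(lags)), "C_qq", 100)
  est <- extract_flux(lin, pA = 0.5)
  expect_equal(est$J_AB, 2e-4, tolerance = 1e-9)
  expect_equal(est$plateau_time, lags[2])
  expect_equal(est$k_AB, 4e-4, tolerance = 1e-9)
})

test_that("a transient relaxes to the plateau; an unrelaxed series fails loudly", {
  lags <- seq(0, 20, by = 0.1)
  s <- 1e-4; tau_c <- 0.5
  relax <- ratepaths:::.new_corr_series(
    lags, 5e-4 * (1 - exp(-lags / tau_c)) + s * lags,
    rep(1e-9, length(lags)), "C_BB", 100)
  est <- extract_flux(relax)
  expect_equal(est$J_AB, s, tolerance = 0.02)
  expect_gt(est$plateau_time, tau_c)
  # derivative still decaying at the longest lag: the broad-barrier
  # indicator pathology must be reported, never silently averaged
  slow <- ratepaths:::.new_corr_series(
    lags, 5e-1 * (1 - exp(-lags / 8)) + s * lags,
    rep(1e-9, length(lags)), "C_BB", 100)
  expect_error(extract_flux(slow), "no plateau")
})

test_that("error-aware plateau onset locates a known transient end", {
  lags <- seq(0, 20, by = 0.1)
  set.seed(3)
  vals <- 5e-3 * (1 - exp(-lags / 2)) + 1e-4 * lags
  cs <- ratepaths:::.new_corr_series(lags, vals + rnorm(length(lags), 0, 2e-6),
                                     rep(2e-5, length(lags)), "C_BB", 100)
  onset <- plateau_onset(cs, tail_window = c(12, 20))
  expect_gt(onset, 2)      # transient time scale
  expect_lt(onset, 12)
  expect_equal(attr(onset, "J_tail"), 1e-4, tolerance = 0.1)
})

test_that("pooled series average values and shrink errors", {
  lags <- 0:5
  mk <- function(off) ratepaths:::.new_corr_series(lags, lags * 1e-3 + off,
                                                   rep(2e-4, 6), "C_qq", 10)
  pooled <- pool_correlation_series(list(mk(1e-4), mk(-1e-4), mk(0), mk(0)))
  expect_equal(pooled$values, lags * 1e-3, tolerance = 1e-12)
  expect_equal(pooled$stderr, rep(1e-4, 6), tolerance = 1e-12)
  bad <- ratepaths:::.new_corr_series(0:4, rep(0, 5), rep(0, 5), "C_qq", 10)
  expect_error(pool_correlation_series(list(mk(0), bad)), "lag grid")
})

test_that("TST rate times the transmission coefficient recovers k_AB", {
  # medium barrier: high-friction regime, so the overdamped quadrature
  # rate is the valid reference for the Langevin correction factor
  pot <- potential_1d("medium"); th <- rp_thm()
  q <- rp_quad("medium")
  k_tst <- tst_rate(q$profile, th, 0)
  shots <- sample_dividing_surface(th, 0, 4000, seed = 61)
  kap <- transmission_coefficient(shots, pot, th, t_max = 20, dt = 0.001,
                                  stride = 20, seed = 62)
  expect_gt(kap$kappa[1], 0.9)          # kappa(0+) = 1 before recrossing
  tail_sel <- kap$t >= 12               # past the ~12 ps transit time
  kappa_plateau <- mean(kap$kappa[tail_sel])
  kappa_se <- sqrt(mean(kap$se[tail_sel]^2))
  expect_gt(kappa_plateau, 0)
  expect_lte(kappa_plateau, 1)
  expect_lt(abs(kappa_plateau * k_tst - q$tss$k_AB), 3 * kappa_se * k_tst)
})

test_that("langevin position statistics match Brownian beyond the memory time", {
  # broad barrier: C_zz from pooled Langevin walkers vs a 1 us BD run at
  # common lags well above the 0.08 ps velocity relaxation time
  lang <- rp_lang_pooled()$C_zz
  bd_traj <- rp_bd_1us("broad")
  lags <- seq(0, 20, by = 0.5)
  bd <- position_correlation(bd_traj, lags = lags)
  idx_lang <- match(lags, round(lang$lags, 10))
  comp <- lags >= 1
  diff_ok <- abs(lang$values[idx_lang][comp] - bd$values[comp]) <
    3 * sqrt(lang$stderr[idx_lang][comp]^2 + bd$stderr[comp]^2)
  expect_gt(mean(diff_ok), 0.9)
})

test_that("correlation CSV round-trips at full precision", {
  cs <- ratepaths:::.new_corr_series(seq(0, 1, 0.1), rnorm(11) * 1e-4,
                                     abs(rnorm(11)) * 1e-6, "C_qq", 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_csv(cs, path)
  back <- read_correlation_csv(path)
  expect_identical(back$values, cs$values)
  expect_identical(back$estimator, "C_qq")
})
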
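# Markov propagator estimation and spectral analysis.

two_state_sm <- function(p = 0.1, lag = 1) {
  # exact symmetric two-state model as a spectral_model
  sm <- structure(list(bin_edges = c(-2, 0, 2), centers = c(-1, 1),
                       lag = lag, counts = matrix(c(1 - p, p, p, 1 - p), 2) * 1e6,
                       T = matrix(c(1 - p, p, p, 1 - p), 2, byrow = TRUE),
                       stationary = c(0.5, 0.5), index_map = 1:2,
                       n_samples = 2e6),
                  class = "spectral_model")
  spectral_decomposition(sm)
}

test_that("a synthetic switching chain recovers its transition matrix", {
  chain <- simulate_two_state_chain(5e4, p_switch = 0.1, seed = 20)
  sm <- build_transition_matrix(chain_as_trajectory(chain), c(-2, 0, 2), lag = 1)
  expect_equal(rowSums(sm$T), c(1, 1), tolerance = 1e-12)
  N <- sum(sm$counts[1, ])
  expect_lt(abs(sm$T[1, 2] - 0.1), 3 * sqrt(0.1 * 0.9 / N))
  sm <- spectral_decomposition(sm)
  expect_equal(sm$lambdas[1], 1, tolerance = 1e-10)
  # closed form: lambda2 = 1 - 2p, mu2 = -log(1 - 2p)/lag
  expect_lt(abs(sm$lambdas[2] - 0.8), 0.02)
})

test_that("the exact two-state model has the closed-form spectrum", {
  sm <- two_state_sm(p = 0.1, lag = 1)
  expect_equal(sm$lambdas, c(1, 0.8), tolerance = 1e-12)
  expect_equal(sm$mus[2], -log(0.8), tolerance = 1e-12)
  expect_equal(sm$left_vectors[, 1], c(1, 1), tolerance = 1e-10)
  expect_equal(sm$right_vectors[, 1], sm$stationary, tolerance = 1e-10)
  # orthonormality (psi_kL . psi_lR) = delta_kl
  G <- t(sm$left_vectors) %*% sm$right_vectors
  expect_lt(max(abs(G - diag(2))), 1e-8)
})

test_that("lag must be commensurate and degenerate binnings are rejected", {
  chain <- simulate_two_state_chain(1000, 0.1, seed = 21)
  tr <- chain_as_trajectory(chain)
  expect_error(build_transition_matrix(tr, c(-2, 0, 2), lag = 0.5),
               "multiple")
  const <- chain_as_trajectory(rep(1L, 1000))
  expect_error(build_transition_matrix(const, c(-2, 0, 2), lag = 1),
               "fewer than 2")
})

test_that("symmetrized counts satisfy detailed balance with a real spectrum", {
  traj <- rp_bd_1us("narrow")
  sm <- spectral_decomposition(
    build_transition_matrix(traj, uniform_bins(-12, 12, 120), lag = 0.5))
  flow <- sm$stationary * sm$T
  expect_lt(max(abs(flow - t(flow))), 1e-12)
  expect_true(all(abs(Im(sm$lambdas)) == 0))
  expect_equal(rowSums(sm$T), rep(1, nrow(sm$T)), tolerance = 1e-12)
  G <- t(sm$left_vectors) %*% sm$right_vectors
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
})

test_that("MSM stationary distribution matches the Boltzmann bin masses", {
  traj <- rp_bd_1us("narrow")
  q <- rp_quad("narrow")
  edges <- uniform_bins(-12, 12, 120)
  sm <- build_transition_matrix(traj, edges, lag = 0.5)
  dens_cum <- ratepaths:::.cumtrapz(q$profile$density, q$profile$grid)
  mass <- approx(q$profile$grid, dens_cum, xout = edges)$y
  ref <- diff(mass)[sm$index_map]
  ref <- ref / sum(ref)
  # segment-based errors absorb the within-well correlation of the counts
  n <- length(traj$positions)
  seg <- lapply(split(seq_len(n), cut(seq_len(n), 10)), function(i) {
    tseg <- traj; tseg$positions <- traj$positions[i]
    bt <- build_transition_matrix(tseg, edges, lag = 0.5)
    pi_full <- numeric(121); pi_full[bt$index_map] <- bt$stationary
    pi_full[sm$index_map]
  })
  segm <- do.call(cbind, seg)
  se <- apply(segm, 1, sd) / sqrt(ncol(segm))
  keep <- ref > 1e-4
  chi2 <- sum(((sm$stationary[keep] - ref[keep]) / se[keep])^2)
  p <- pchisq(chi2, df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("indicator overlaps resolve the t = 0 variance and the slow mode", {
  sm <- two_state_sm(p = 0.2)
  amps <- indicator_overlaps(sm, dividing_surface("position", 0))
  expect_equal(amps[1], 0.5, tolerance = 1e-12)   # (H_B . psi_1R) = pB
  expect_equal(sum(amps[-1]^2), 0.25, tolerance = 1e-12)
  # BD benchmark: mode 2 carries essentially all indicator variance
  traj <- rp_bd_1us("narrow")
  smb <- spectral_decomposition(
    build_transition_matrix(traj, uniform_bins(-12, 12, 120), lag = 0.5))
  a <- indicator_overlaps(smb)
  pApB <- a[1] * (1 - a[1])
  expect_equal(sum(a[-1]^2), pApB, tolerance = 1e-8)
  expect_gt(a[2]^2 / sum(a[-1]^2), 0.95)
})

test_that("the model committor of the two-state model is the indicator", {
  sm <- two_state_sm(p = 0.1)
  mc <- model_committor(sm, core_A_bins = 1, core_B_bins = 2)
  expect_equal(mc$q, c(0, 1), tolerance = 1e-10)
  expect_lt(mc$a, 0); expect_gt(mc$b, 0)
  expect_lt(mc$residual_ab, 1e-10)
  expect_lt(mc$residual_norm, 1e-10)
})

test_that("two-state flux has the stated limits and lag robustness", {
  # small-lag, zero-transit limit: J -> pA pB mu2
  expect_equal(two_state_flux(1e-3, 1e-6, 0, 0.5, 0.5), 0.25 * 1e-3,
               tolerance = 1e-6)
  # frozen direct evaluation of the full formula
  expect_equal(two_state_flux(1e-3, 0.005, 25, 0.5, 0.5), 2.43902e-4,
               tolerance = 1e-5)
  J1 <- two_state_flux(1e-3, 0.005, 25, 0.5, 0.5)
  J10 <- two_state_flux(1e-3, 0.05, 25, 0.5, 0.5)
  expect_lt(abs(J10 - J1) / J1, 10 * 1e-3 * 0.05)
  expect_error(two_state_flux(1e-3, 1, 0, 0.6, 0.6), "equal 1")
})

test_that("rate-matrix flux reproduces the two-state closed form", {
  sm <- two_state_sm(p = 0.1, lag = 1)
  K <- (sm$T - diag(2)) / sm$lag
  expect_equal(rowSums(K), c(0, 0), tolerance = 1e-12)
  expect_equal(rate_matrix_flux(sm, c(0, 1)), 0.1 / 2, tolerance = 1e-12)
})

test_that("rate-matrix flux with the quadrature committor matches quadrature", {
  traj <- rp_bd_1us("narrow")
  q <- rp_quad("narrow")
  sm <- build_transition_matrix(traj, uniform_bins(-12, 12, 120), lag = 0.5)
  J <- rate_matrix_flux(sm, committor_at(q$cp, sm$centers))
  expect_lt(abs(J - q$tss$J_AB) / q$tss$J_AB, 0.1)
})

test_that("Chapman-Kolmogorov holds for data from an exact Markov chain", {
  chain <- simulate_two_state_chain(2e5, p_switch = 0.1, seed = 22)
  ck <- chapman_kolmogorov_test(chain_as_trajectory(chain), c(-2, 0, 2),
                                lag = 1, multiples = c(2, 5, 10))
  expect_true(all(ck$pass))
})

test_that("spectral model JSON round-trips", {
  sm <- two_state_sm(p = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_spectral_json(sm, path)
  back <- read_spectral_json(path)
  expect_equal(back$T, unname(sm$T), tolerance = 1e-15)
  expect_equal(back$lambdas, sm$lambdas, tolerance = 1e-15)
  expect_equal(back$stationary, sm$stationary)
})
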
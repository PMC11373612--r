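# Integrators, shooting committors, and first-passage statistics.

test_that("trajectories are reproducible bit for bit from the seed", {
  pot <- potential_1d("narrow"); th <- rp_th()
  sp <- sim_params("brownian", dt = 0.005, n_steps = 5000, stride = 5,
                   seed = 99, initial_position = -4)
  t1 <- simulate_brownian(pot, th, sp)
  t2 <- simulate_brownian(pot, th, sp)
  expect_identical(t1$positions, t2$positions)
  thm <- rp_thm()
  spl <- sim_params("langevin", dt = 0.001, n_steps = 5000, seed = 99,
                    initial_position = -4)
  expect_identical(simulate_langevin(pot, thm, spl)$velocities,
                   simulate_langevin(pot, thm, spl)$velocities)
})

test_that("compiled and reference integrators draw the same path", {
  # a custom potential reproducing the narrow family routes through the
  # plain-R integrator but consumes the identical RNG stream
  th <- rp_th()
  narrow <- potential_1d("narrow")
  dup <- potential_1d("custom",
                      W = function(z) (z / 9.51)^12 + 3.3 * exp(-(z / 0.6)^2) - 3.2,
                      dWdz = function(z) 12 * z^11 / 9.51^12 +
                        3.3 * exp(-(z / 0.6)^2) * (-2 * z / 0.36))
  sp <- sim_params("brownian", dt = 0.005, n_steps = 2000, seed = 5,
                   initial_position = -4)
  expect_equal(simulate_brownian(narrow, th, sp)$positions,
               simulate_brownian(dup, th, sp)$positions, tolerance = 1e-8)
})

test_that("zero-noise hooks reduce to the deterministic limits", {
  flat <- potential_1d("flat", domain = c(-50, 50))
  th <- rp_th()
  sp0 <- sim_params("brownian", dt = 0.005, n_steps = 100, seed = 1,
                    initial_position = 2, noise = "zero")
  expect_true(all(simulate_brownian(flat, th, sp0)$positions == 2))
  # one step with a prescribed unit deviate: displacement sqrt(2 D dt)
  sp1 <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 1,
                    initial_position = 0, noise = 1)
  expect_equal(simulate_brownian(flat, th, sp1)$positions[2], sqrt(0.01))
  # ballistic hook: free flight at constant velocity
  spb <- sim_params("langevin", dt = 0.01, n_steps = 50, seed = 1,
                    initial_position = 0, initial_velocity = 1.5,
                    noise = "ballistic")
  trb <- simulate_langevin(flat, rp_thm(), spb)
  expect_equal(diff(trb$positions), rep(1.5 * 0.01, 50), tolerance = 1e-12)
})

test_that("escaping the evaluation domain names the step index", {
  steep <- potential_1d("narrow", domain = c(-5, 5))
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1e5, seed = 3,
                   initial_position = -4)
  expect_error(simulate_brownian(steep, rp_th(), sp), "at step")
})

test_that("langevin velocities are Maxwell-distributed with variance kBT/m", {
  traj <- rp_lang_fine()
  expect_equal(var(traj$velocities), 0.5915 * 418.4 / 20, tolerance = 0.02)
  expect_lt(abs(mean(traj$velocities)), 3 * sd(traj$velocities) / sqrt(1e7 / 80))
})

test_that("free diffusion recovers the MSD slope 2D", {
  flat <- potential_1d("flat", domain = c(-1e4, 1e4))
  sp <- sim_params("brownian", dt = 0.005, n_steps = 2e5, seed = 21,
                   initial_position = 0)
  z <- simulate_brownian(flat, rp_th(), sp)$positions
  lags <- seq(20, 200, by = 20)              # 0.1 to 1 ps
  msd <- vapply(lags, function(l) mean(diff(z, lag = l)^2), 0)
  slope <- coef(lm(msd ~ I(lags * 0.005)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
})

test_that("long Brownian runs reproduce the Boltzmann histogram", {
  traj <- rp_bd_1us("narrow")
  q <- rp_quad("narrow")
  # thin to ~2 relaxation times so samples are effectively independent
  thin <- traj$positions[seq(1, length(traj$positions), by = 2000)]  # every 1 ns
  edges <- seq(-11, 11, length.out = 51)
  obs <- tabulate(findInterval(thin, edges, rightmost.closed = TRUE), 50)
  dens <- approx(q$profile$grid, q$profile$density,
                 xout = (head(edges, -1) + tail(edges, -1)) / 2)$y
  expected <- dens * diff(edges) * length(thin)
  keep <- expected >= 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("shooting committors track the quadrature committor", {
  q <- rp_quad("narrow")
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 31,
                   initial_position = 0)
  tab <- shoot_committor(q$pot, rp_th(), sp, c(-2, 0, 2), n_shots = 600)
  expect_equal(tab$n_A + tab$n_B, rep(600, 3))
  q_ref <- committor_at(q$cp, tab$start)
  expect_true(all(abs(tab$q_hat - q_ref) < 3 * pmax(tab$se, 1e-3)))
  # symmetric start is a fair coin
  expect_lt(abs(tab$q_hat[2] - 0.5), 3 * tab$se[2])
})

test_that("shots near a boundary absorb there almost surely", {
  q <- rp_quad("narrow")
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 32,
                   initial_position = 0)
  tab <- shoot_committor(q$pot, rp_th(), sp, -6.99, n_shots = 100)
  expect_lt(tab$q_hat, 0.1)
  expect_error(shoot_committor(q$pot, rp_th(), sp, -8, n_shots = 10),
               "strictly between")
})

test_that("step-capped shots are reported as censored, not dropped", {
  q <- rp_quad("broad")
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 33,
                   initial_position = 0)
  tab <- shoot_committor(q$pot, rp_th(), sp, 0, n_shots = 20, max_steps = 10)
  expect_equal(tab$n_censored, 20)
})

test_that("flat-potential first passage matches the double-quadrature oracle", {
  flat <- potential_1d("flat", domain = c(-50, 50))
  th <- rp_th()
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 41,
                   initial_position = 0)
  # absorbing at both |z| = 7 from a start at the centre; the standard
  # double integral for the interval MFPT gives a^2/(2D) = 24.5 ps
  fpt <- first_passage_times(flat, th, sp, source_region = c(-0.001, 0.001),
                             target_boundary = c(-7, 7), n_samples = 300)
  oracle <- 7^2 / (2 * th$D)
  expect_lt(abs(mean(fpt) - oracle), 3 * attr(fpt, "mean_se"))
  expect_equal(attr(fpt, "censored"), 0L)
})

test_that("well-to-boundary MFPT agrees with 1/k_AB from quadrature", {
  q <- rp_quad("narrow")
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 42,
                   initial_position = 0)
  fpt <- first_passage_times(q$pot, rp_th(), sp, source_region = c(-7, 0),
                             target_boundary = 7, n_samples = 120)
  expect_lt(abs(mean(fpt) - 1 / q$tss$k_AB), 3 * attr(fpt, "mean_se"))
})

test_that("a target boundary inside the source region is rejected", {
  sp <- sim_params("brownian", dt = 0.005, n_steps = 1, seed = 43,
                   initial_position = 0)
  expect_error(first_passage_times(potential_1d("narrow"), rp_th(), sp,
                                   source_region = c(-7, 0),
                                   target_boundary = -2, n_samples = 5),
               "inside the source region")
})

test_that("dividing-surface samples are Maxwellian at the surface", {
  th <- rp_thm()
  s <- sample_dividing_surface(th, 0.3, 4000, seed = 51)
  expect_true(all(s$position == 0.3))
  sd_v <- sqrt(0.5915 * 418.4 / 20)
  expect_lt(abs(mean(s$velocity)), 3 * sd_v / sqrt(4000))
  half_mean <- sqrt(0.5915 * 418.4 / (2 * pi * 20))
  vtheta <- s$velocity * (s$velocity > 0)
  expect_lt(abs(mean(vtheta) - half_mean), 3 * sd(vtheta) / sqrt(4000))
  expect_error(sample_dividing_surface(rp_th(), 0, 10, seed = 1), "mass")
})
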
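# Brownian (overdamped Euler–Maruyama) and Langevin (BAOAB) integrators,
# shooting-based empirical committors, and first-passage sampling.
#
# All stochastic functions consume R's RNG stream after set.seed(seed), so a
# given seed reproduces a trajectory bit for bit. The compiled kernels draw
# from the same stream (norm_rand), so the fast path and the R reference
# path produce identical noise sequences.

#' Simulation parameters
#'
#' @param integrator `"brownian"` (overdamped) or `"langevin"` (inertial,
#'   BAOAB splitting).
#' @param dt Time step in ps (> 0).
#' @param n_steps Number of integration steps (>= 1).
#' @param stride Output interval in steps (>= 1); frames are stored every
#'   `stride` steps, decoupling output size from dt.
#' @param seed Integer RNG seed; mandatory so every trajectory is
#'   reproducible.
#' @param initial_position Starting position in Å.
#' @param initial_velocity Starting velocity in Å/ps (Langevin only;
#'   default: drawn from the Maxwell distribution).
#' @param noise Test hook controlling the random force: `"normal"`
#'   (default, Gaussian), `"zero"` (noise suppressed), `"ballistic"`
#'   (Langevin only: noise and friction suppressed, free flight), or a
#'   numeric vector of prescribed standard-normal deviates (recycled).
#'   Anything but `"normal"` routes through the plain-R reference
#'   integrator.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(integrator = c("brownian", "langevin"), dt, n_steps,
                       stride = 1L, seed, initial_position = 0,
                       initial_velocity = NULL, noise = "normal") {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, n_steps >= 1, stride >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  structure(list(integrator = integrator, dt = dt, n_steps = n_steps,
                 stride = as.integer(stride), seed = as.integer(seed),
                 initial_position = initial_position,
                 initial_velocity = initial_velocity, noise = noise),
            class = "sim_params")
}

.new_trajectory <- function(positions, velocities, sp, pot, th) {
  dt_out <- sp$dt * sp$stride
  structure(list(times = seq(0, by = dt_out, length.out = length(positions)),
                 positions = positions, velocities = velocities,
                 params = sp, potential = pot, thermo = th),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d frames every %g ps (%g ps total), potential '%s'\n",
              x$params$integrator, length(x$positions),
              x$params$dt * x$params$stride,
              x$times[length(x$times)], x$potential$family))
  invisible(x)
}

.noise_fun <- function(noise) {
  if (identical(noise, "normal")) return(NULL)
  if (identical(noise, "zero") || identical(noise, "ballistic"))
    return(function(i) 0)
  if (is.numeric(noise)) {
    nv <- noise
    return(function(i) nv[((i - 1L) %% length(nv)) + 1L])
  }
  stop("invalid noise specification")
}

#' Simulate overdamped Brownian dynamics
#'
#' Euler–Maruyama update z' = z + (D/kBT) F(z) dt + sqrt(2 D dt) G with
#' i.i.d. standard-normal G. Trajectories leaving the potential's
#' evaluation domain abort with an error naming the step index (the
#' symptom of a too-large dt).
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()] (kBT and D used).
#' @param sp A [sim_params()] with `integrator = "brownian"`.
#' @return A `trajectory` (positions only).
#' @export
simulate_brownian <- function(pot, th, sp) {
  stopifnot(inherits(sp, "sim_params"))
  if (sp$integrator != "brownian") stop("sim_params integrator must be 'brownian'")
  set.seed(sp$seed)
  pp <- .pot_param_vec(pot)
  if (!is.null(pp) && identical(sp$noise, "normal")) {
    pos <- .bd_kernel(sp$initial_position, sp$dt, sp$n_steps, sp$stride,
                      th$kBT, th$D, pp, pot$domain[1], pot$domain[2])
  } else {
    g <- .noise_fun(sp$noise)
    mob <- th$D / th$kBT * sp$dt
    sig <- sqrt(2 * th$D * sp$dt)
    z <- sp$initial_position
    .check_domain(pot, z)
    n_out <- sp$n_steps %/% sp$stride + 1L
    pos <- numeric(n_out)
    pos[1] <- z
    k <- 2L
    for (i in seq_len(sp$n_steps)) {
      G <- if (is.null(g)) rnorm(1) else g(i)
      z <- z + mob * eval_force(pot, z) + sig * G
      if (z < pot$domain[1] || z > pot$domain[2])
        stop(sprintf("trajectory escaped the evaluation domain at step %d (z = %g)", i, z))
      if (i %% sp$stride == 0L) { pos[k] <- z; k <- k + 1L }
    }
  }
  .new_trajectory(pos, NULL, sp, pot, th)
}

#' Simulate Langevin dynamics (BAOAB)
#'
#' BAOAB-splitting integrator with friction fixed by the Einstein relation
#' gamma = kBT/(m D) (in ps^-1 after converting kBT to amu Å^2/ps^2).
#' Velocities are stored alongside positions.
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()] with `mass` set.
#' @param sp A [sim_params()] with `integrator = "langevin"`.
#' @return A `trajectory` with positions and velocities.
#' @export
simulate_langevin <- function(pot, th, sp) {
  stopifnot(inherits(sp, "sim_params"))
  if (sp$integrator != "langevin") stop("sim_params integrator must be 'langevin'")
  if (is.null(th$mass)) stop("langevin dynamics requires a mass in the thermo state")
  set.seed(sp$seed)
  kv <- th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2   # kBT in amu Å^2/ps^2
  v0 <- sp$initial_velocity
  if (is.null(v0)) v0 <- rnorm(1, 0, sqrt(kv / th$mass))
  pp <- .pot_param_vec(pot)
  if (!is.null(pp) && identical(sp$noise, "normal")) {
    res <- .baoab_kernel(sp$initial_position, v0, sp$dt, sp$n_steps,
                         sp$stride, th$kBT, th$D, th$mass, pp,
                         pot$domain[1], pot$domain[2])
    pos <- res$positions; vel <- res$velocities
  } else {
    g <- .noise_fun(sp$noise)
    gamma <- kv / (th$mass * th$D)
    c1 <- if (identical(sp$noise, "ballistic")) 1 else exp(-gamma * sp$dt)
    c2 <- sqrt((1 - c1^2) * kv / th$mass)
    fh <- 0.5 * sp$dt * KCAL_PER_MOL_TO_AMU_A2_PS2 / th$mass
    z <- sp$initial_position; v <- v0
    .check_domain(pot, z)
    n_out <- sp$n_steps %/% sp$stride + 1L
    pos <- numeric(n_out); vel <- numeric(n_out)
    pos[1] <- z; vel[1] <- v
    k <- 2L
    for (i in seq_len(sp$n_steps)) {
      G <- if (is.null(g)) rnorm(1) else g(i)
      v <- v + fh * eval_force(pot, z)
      z <- z + 0.5 * sp$dt * v
      v <- c1 * v + c2 * G
      z <- z + 0.5 * sp$dt * v
      if (z < pot$domain[1] || z > pot$domain[2])
        stop(sprintf("trajectory escaped the evaluation domain at step %d (z = %g)", i, z))
      v <- v + fh * eval_force(pot, z)
      if (i %% sp$stride == 0L) { pos[k] <- z; vel[k] <- v; k <- k + 1L }
    }
  }
  .new_trajectory(pos, vel, sp, pot, th)
}

#' Empirical committor by trajectory shooting
#'
#' For each start position, runs `n_shots` independent trajectories until
#' first absorption at z1 (outcome A) or z2 (outcome B). The empirical
#' committor is the fraction reaching B, with the binomial standard error
#' sqrt(q(1-q)/n). Shots exceeding `max_steps` are counted as censored and
#' reported, never silently dropped.
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()].
#' @param sp_template A [sim_params()] providing integrator, dt and seed.
#' @param start_positions Vector of start positions, all strictly inside
#'   (z1, z2).
#' @param n_shots Shots per start position.
#' @param z1,z2 Absorbing boundaries in Å.
#' @param max_steps Step cap per shot (default 1e9).
#' @return Data frame with columns `start`, `n_A`, `n_B`, `n_censored`,
#'   `q_hat`, `se`.
#' @export
shoot_committor <- function(pot, th, sp_template, start_positions, n_shots,
                            z1 = -7, z2 = 7, max_steps = 1e9) {
  stopifnot(inherits(sp_template, "sim_params"))
  if (any(start_positions <= z1 | start_positions >= z2))
    stop("all start positions must lie strictly between z1 and z2")
  pp <- .pot_param_vec(pot)
  if (is.null(pp)) stop("shooting requires a parametric (non-custom) potential")
  lang <- sp_template$integrator == "langevin"
  if (lang && is.null(th$mass)) stop("langevin shooting requires a mass")
  kv <- th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2
  set.seed(sp_template$seed)
  res <- lapply(start_positions, function(s) {
    out <- integer(3)
    for (i in seq_len(n_shots)) {
      v0 <- if (lang) rnorm(1, 0, sqrt(kv / th$mass)) else 0
      r <- .absorb_kernel(s, v0, sp_template$dt, max_steps, th$kBT, th$D,
                          if (lang) th$mass else 1, lang, pp, z1, z2)
      out[r[1] + 1] <- out[r[1] + 1] + 1L
    }
    n_ok <- out[1] + out[2]
    q <- if (n_ok > 0) out[2] / n_ok else NA_real_
    data.frame(start = s, n_A = out[1], n_B = out[2], n_censored = out[3],
               q_hat = q, se = sqrt(q * (1 - q) / n_ok))
  })
  do.call(rbind, res)
}

#' First-passage times to a target boundary
#'
#' Samples starting points from the equilibrium density restricted to the
#' source region (inverse-CDF sampling) and integrates each walker until
#' the target boundary is crossed. The sample mean estimates the mean
#' first passage time, which in the rare-event regime equals 1/k_AB.
#'
#' @param pot,th Potential and thermodynamic state.
#' @param sp_template A [sim_params()] providing integrator, dt and seed.
#' @param source_region Interval `c(lo, hi)` in Å from which starts are
#'   drawn with equilibrium weight.
#' @param target_boundary One absorbing position, or two (both sides
#'   absorbing). Must not intersect the source region.
#' @param n_samples Number of walkers.
#' @param max_steps Step cap per walker; capped walkers are reported as
#'   censored via the `censored` attribute, not dropped silently.
#' @return Numeric vector of passage times in ps (censored walkers
#'   excluded), with attributes `censored` (count) and `mean_se` (standard
#'   error of the mean).
#' @export
first_passage_times <- function(pot, th, sp_template, source_region,
                                target_boundary, n_samples, max_steps = 1e9) {
  stopifnot(length(source_region) == 2, source_region[1] < source_region[2])
  if (any(target_boundary >= source_region[1] & target_boundary <= source_region[2]))
    stop("target boundary lies inside the source region")
  pp <- .pot_param_vec(pot)
  if (is.null(pp)) stop("first-passage sampling requires a parametric potential")
  lang <- sp_template$integrator == "langevin"
  if (lang && is.null(th$mass)) stop("langevin dynamics requires a mass")
  kv <- th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2
  # absorbing interval for the kernel
  tb <- sort(target_boundary)
  if (length(tb) == 2) {
    zlo <- tb[1]; zhi <- tb[2]
  } else if (tb > source_region[2]) {
    zlo <- -1e30; zhi <- tb
  } else {
    zlo <- tb; zhi <- 1e30
  }
  set.seed(sp_template$seed)
  # inverse-CDF equilibrium sampling restricted to the source region
  g <- seq(source_region[1], source_region[2], length.out = 2001)
  w <- exp(-(eval_potential(pot, g) - min(eval_potential(pot, g))) / th$kBT)
  cdf <- .cumtrapz(w, g); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  starts <- approx(cdf[keep], g[keep], xout = runif(n_samples))$y
  times <- numeric(0); censored <- 0L
  for (s in starts) {
    v0 <- if (lang) rnorm(1, 0, sqrt(kv / th$mass)) else 0
    r <- .absorb_kernel(s, v0, sp_template$dt, max_steps, th$kBT, th$D,
                        if (lang) th$mass else 1, lang, pp, zlo, zhi)
    if (r[1] == 2) censored <- censored + 1L
    else times <- c(times, r[2] * sp_template$dt)
  }
  attr(times, "censored") <- censored
  attr(times, "mean_se") <- if (length(times) > 1) sd(times) / sqrt(length(times)) else NA_real_
  times
}

#' Sample initial conditions on a dividing surface
#'
#' Positions all at z-dagger; velocities i.i.d. Maxwell–Boltzmann with
#' variance kBT/m.
#'
#' @param th A [thermo_state()] with `mass` set.
#' @param z_dagger Dividing-surface position in Å.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return Data frame with columns `position` and `velocity` (Å/ps).
#' @export
sample_dividing_surface <- function(th, z_dagger, n, seed) {
  if (is.null(th$mass)) stop("dividing-surface sampling requires a mass")
  set.seed(as.integer(seed))
  sigma_v <- sqrt(th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2 / th$mass)
  data.frame(position = rep(z_dagger, n), velocity = rnorm(n, 0, sigma_v))
}
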
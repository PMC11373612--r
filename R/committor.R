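# Exact 1D committor by quadrature and committor-derived observables.
#
# For overdamped diffusion in a potential W(z) with absorbing boundaries
# z1 (state A) and z2 (state B), the committor solves the 1D backward
# equation d/dz [ exp(-W/kBT) dq/dz ] = 0, giving
#   q(z) = int_{z1}^{z} exp(W/kBT) dz' / int_{z1}^{z2} exp(W/kBT) dz'.
# The steady-state reactive flux then has the closed form
#   J_AB = D / (Z_full * Z_barrier),
# with Z_full = int exp(-W/kBT) dz over the normalization domain and
# Z_barrier = int_{z1}^{z2} exp(W/kBT) dz.

#' Exact committor of 1D overdamped diffusion by quadrature
#'
#' Solves the committor on a uniform grid between the absorbing boundaries
#' as a cumulative-trapezoid ratio of exp(W/kBT). The exponent is shifted by
#' its maximum before exponentiation so deep barriers cannot overflow.
#' Endpoints are exactly 0 and 1 and q is monotone non-decreasing.
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()].
#' @param z1,z2 Absorbing boundaries in Å, `z1 < z2`; q = 0 at z1 (state A)
#'   and q = 1 at z2 (state B). Default -7 and +7 as in the benchmark
#'   systems.
#' @param spacing Grid spacing in Å.
#' @param grid Optional explicit grid spanning `[z1, z2]`.
#' @return An object of class `committor_profile` with fields `grid`, `q`,
#'   `z1`, `z2`, `thermo`, `pot`.
#' @export
solve_committor_1d <- function(pot, th, z1 = -7, z2 = 7, spacing = 0.001,
                               grid = NULL) {
  stopifnot(inherits(pot, "potential_1d"), inherits(th, "thermo_state"))
  if (!(z1 < z2)) stop("z1 must be less than z2")
  .check_domain(pot, c(z1, z2))
  if (is.null(grid)) grid <- seq(z1, z2, by = spacing)
  if (grid[length(grid)] < z2) grid <- c(grid, z2)
  e <- eval_potential(pot, grid) / th$kBT
  shift <- max(e)
  u <- exp(e - shift)
  cum <- .cumtrapz(u, grid)
  q <- cum / cum[length(cum)]
  q[1] <- 0
  q[length(q)] <- 1
  structure(list(grid = grid, q = q, z1 = z1, z2 = z2,
                 thermo = th, pot = pot),
            class = "committor_profile")
}

#' Evaluate a committor profile at arbitrary positions
#'
#' Linear interpolation on the quadrature grid, clamped to 0 below z1 and
#' to 1 above z2 (the committor is constant inside the absorbing basins).
#'
#' @param cp A `committor_profile`.
#' @param z Positions in Å.
#' @return Committor values in \[0, 1\].
#' @export
committor_at <- function(cp, z) {
  q <- approx(cp$grid, cp$q, xout = z, rule = 2)$y
  q[z <= cp$z1] <- 0
  q[z >= cp$z2] <- 1
  q
}

#' Steady-state reactive flux by quadrature (closed form)
#'
#' Evaluates J_AB = D / (Z_full * Z_barrier) for 1D overdamped diffusion,
#' where Z_full is the configurational integral of exp(-W/kBT) over the
#' full normalization domain and Z_barrier the integral of exp(W/kBT)
#' between the absorbing boundaries. This equals the Dirichlet-form flux
#' functional evaluated at the exact committor.
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()].
#' @param cp Optional `committor_profile` (supplies z1, z2 and the grid
#'   spacing); built with defaults when missing.
#' @param profile Optional [equilibrium_profile()] (supplies Z_full); built
#'   with defaults when missing. `cp` and `profile` must come from the same
#'   potential and thermodynamic state.
#' @return Flux J_AB in ps^-1.
#' @export
flux_quadrature <- function(pot, th, cp = NULL, profile = NULL) {
  if (is.null(cp)) cp <- solve_committor_1d(pot, th)
  if (is.null(profile)) profile <- equilibrium_profile(pot, th)
  e <- eval_potential(pot, cp$grid) / th$kBT
  shift <- max(e)
  Zb <- .trapz(exp(e - shift), cp$grid) * exp(shift)
  th$D / (profile$Z * Zb)
}

#' Dirichlet-form flux functional for a trial committor
#'
#' Evaluates J\[q\] = int (dq/dz)^2 D rho_eq(z) dz by trapezoid quadrature.
#' By the variational principle, J\[q\] is minimized by the exact committor,
#' so any trial function satisfying the boundary conditions gives an upper
#' bound on the true flux.
#'
#' @param trial_q A `committor_profile` or any list with fields `grid`,
#'   `q`, `z1`, `z2`. Must equal 0 at z1 and 1 at z2 (tolerance 1e-8).
#' @param th A [thermo_state()].
#' @param profile An [equilibrium_profile()] for the same system.
#' @return Flux upper bound in ps^-1.
#' @export
flux_functional <- function(trial_q, th, profile) {
  q_at_z1 <- approx(trial_q$grid, trial_q$q, xout = trial_q$z1, rule = 2)$y
  q_at_z2 <- approx(trial_q$grid, trial_q$q, xout = trial_q$z2, rule = 2)$y
  if (abs(q_at_z1) > 1e-8 || abs(q_at_z2 - 1) > 1e-8)
    stop("trial committor must equal 0 at z1 and 1 at z2")
  g <- profile$grid
  q <- approx(trial_q$grid, trial_q$q, xout = g, rule = 2)$y
  q[g <= trial_q$z1] <- 0
  q[g >= trial_q$z2] <- 1
  # derivative on interval midpoints; density evaluated exactly at the
  # midpoints when the profile carries its potential (second-order
  # accuracy of the Dirichlet form), averaged otherwise
  dq <- diff(q) / diff(g)
  mid <- (head(g, -1) + tail(g, -1)) / 2
  dmid <- if (!is.null(profile$pot) && !is.null(profile$logZ)) {
    exp(-eval_potential(profile$pot, mid) / profile$thermo$kBT - profile$logZ)
  } else {
    (head(profile$density, -1) + tail(profile$density, -1)) / 2
  }
  sum(dq^2 * dmid * diff(g)) * th$D
}

#' Equilibrium probability of being on a reactive trajectory
#'
#' Computes p_AB = <q(1-q)>, the equilibrium average of q(z)(1-q(z))
#' against rho_eq, with q clamped to 0/1 outside the absorbing boundaries.
#' This is the fraction of time an equilibrium trajectory spends on purely
#' reactive A-to-B (equivalently B-to-A) segments.
#'
#' @param cp A `committor_profile`.
#' @param profile An [equilibrium_profile()] for the same system.
#' @return Dimensionless probability.
#' @export
reactive_probability <- function(cp, profile) {
  q <- committor_at(cp, profile$grid)
  .trapz(q * (1 - q) * profile$density, profile$grid)
}

#' Mean transit time of reactive transitions
#'
#' The average duration of the reactive segment of an A-to-B transition,
#' <tau_r> = <q(1-q)> / J_AB. Independent of direction since
#' q(1-q) is invariant under q -> 1-q.
#'
#' @param cp A `committor_profile`.
#' @param profile An [equilibrium_profile()].
#' @param J Steady-state flux J_AB in ps^-1 (> 0).
#' @return Mean transit time in ps.
#' @export
mean_transit_time <- function(cp, profile, J) {
  if (!is.numeric(J) || J <= 0) stop("flux J must be positive")
  reactive_probability(cp, profile) / J
}

#' Transition state (separatrix position) from the committor
#'
#' Finds the position where q(z) crosses 0.5 by linear interpolation
#' between the bracketing grid points. In 1D the density-weighted average
#' over the separatrix collapses to this single root.
#'
#' @param cp A `committor_profile`.
#' @param profile Unused in 1D (accepted for interface symmetry).
#' @return Position z-dagger in Å.
#' @export
transition_state <- function(cp, profile = NULL) {
  s <- cp$q - 0.5
  idx <- which(s[-length(s)] <= 0 & s[-1] > 0)
  if (!length(idx)) {
    if (any(s == 0)) return(cp$grid[which(s == 0)[1]])
    stop("committor never crosses 0.5; no transition state")
  }
  i <- idx[1]
  f <- -s[i] / (s[i + 1] - s[i])
  cp$grid[i] + f * (cp$grid[i + 1] - cp$grid[i])
}

#' Two-state kinetic summary from quadrature
#'
#' Assembles the full set of two-state observables: equilibrium state
#' probabilities, steady-state flux, forward/backward rates
#' k_AB = J/pA and k_BA = J/pB, the global relaxation rate
#' mu2 = J/(pA pB) and relaxation time tau* = 1/mu2 (valid in the
#' rare-event regime mu2 * tau_r << 1), the reactive probability
#' <q(1-q)>, and the mean transit time.
#'
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()].
#' @param z1,z2 Absorbing boundaries in Å.
#' @param dividing_point Dividing position for the state split (default:
#'   the q = 0.5 separatrix).
#' @param spacing Quadrature grid spacing in Å.
#' @return An object of class `two_state_summary`: a list with fields
#'   `pA`, `pB`, `J_AB`, `k_AB`, `k_BA`, `mu2`, `tau_star`, `p_reactive`,
#'   `tau_transit`, `dividing_point`.
#' @export
two_state_summary <- function(pot, th, z1 = -7, z2 = 7,
                              dividing_point = NULL, spacing = 0.001) {
  cp <- solve_committor_1d(pot, th, z1, z2, spacing = spacing)
  profile <- equilibrium_profile(pot, th, spacing = spacing)
  if (is.null(dividing_point)) dividing_point <- transition_state(cp)
  p <- state_probabilities(profile, dividing_point)
  J <- flux_quadrature(pot, th, cp, profile)
  p_re <- reactive_probability(cp, profile)
  mu2 <- J / (p[["pA"]] * p[["pB"]])
  structure(list(pA = p[["pA"]], pB = p[["pB"]], J_AB = J,
                 k_AB = J / p[["pA"]], k_BA = J / p[["pB"]],
                 mu2 = mu2, tau_star = 1 / mu2,
                 p_reactive = p_re, tau_transit = p_re / J,
                 dividing_point = dividing_point),
            class = "two_state_summary")
}

#' @export
print.two_state_summary <- function(x, ...) {
  cat("<two_state_summary>\n")
  cat(sprintf("  pA = %.4f  pB = %.4f   (dividing point %.3f Å)\n",
              x$pA, x$pB, x$dividing_point))
  cat(sprintf("  J_AB = %.4e ps^-1   k_AB = %.4e   k_BA = %.4e ps^-1\n",
              x$J_AB, x$k_AB, x$k_BA))
  cat(sprintf("  mu2 = %.4e ps^-1    tau* = %.1f ps\n", x$mu2, x$tau_star))
  cat(sprintf("  <q(1-q)> = %.4e     mean transit time = %.2f ps\n",
              x$p_reactive, x$tau_transit))
  invisible(x)
}

#' Read/write a committor profile as CSV
#'
#' The CSV has columns `z`, `q`; boundaries are stored as comment header
#' lines `# z1:` and `# z2:`.
#'
#' @param cp A `committor_profile`.
#' @param path File path.
#' @export
write_committor_csv <- function(cp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# z1: %.17g", cp$z1), sprintf("# z2: %.17g", cp$z2),
               "z,q"), con)
  writeLines(sprintf("%.17g,%.17g", cp$grid, cp$q), con)
  invisible(path)
}

#' @rdname write_committor_csv
#' @export
read_committor_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  z1l <- grep("^# z1:", hdr, value = TRUE)
  z2l <- grep("^# z2:", hdr, value = TRUE)
  if (!length(z1l) || !length(z2l))
    stop("malformed committor CSV: missing '# z1:'/'# z2:' header in ", path)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("z", "q") %in% names(df)))
    stop("malformed committor CSV: need columns z,q in ", path)
  structure(list(grid = df$z, q = df$q,
                 z1 = as.numeric(sub("^# z1:", "", z1l)),
                 z2 = as.numeric(sub("^# z2:", "", z2l)),
                 thermo = NULL, pot = NULL),
            class = "committor_profile")
}
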
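# Benchmark double-well potentials and equilibrium profiles.
#
# The three named families share the functional form
#   W(z) = (z/a_c)^12 + h * exp(-(z/w)^p) + c      [kcal/mol, z in Å]
# i.e. a steep even confinement term plus a Gaussian-like central bump whose
# width controls whether the barrier is narrow, medium, or broad. All three
# are symmetric double wells.

.family_params <- list(
  narrow = list(a_c = 9.51, h = 3.3, w = 0.6, p = 2,  c = -3.2),
  medium = list(a_c = 9.51, h = 3.3, w = 4.0, p = 2,  c = -3.3),
  broad  = list(a_c = 9.51, h = 3.2, w = 7.0, p = 16, c = -3.2),
  flat   = list(a_c = Inf,  h = 0.0, w = 1.0, p = 2,  c = 0.0)
)

#' Construct a 1D potential
#'
#' Builds a potential energy function W(z) with analytic derivative. The
#' named families (`"narrow"`, `"medium"`, `"broad"`) are symmetric double
#' wells differing in barrier width; `"flat"` is identically zero (free
#' diffusion within the domain). A `"custom"` potential supplies its own
#' energy and derivative functions.
#'
#' @param family One of `"narrow"`, `"medium"`, `"broad"`, `"flat"`,
#'   `"custom"`.
#' @param params Named list of overrides for the family constants
#'   (`a_c` confinement scale in Å, `h` bump height in kcal/mol, `w` bump
#'   width in Å, `p` bump exponent, `c` offset in kcal/mol). Ignored for
#'   `"custom"`.
#' @param domain Closed evaluation interval in Å. Default `c(-14, 14)`:
#'   at |z| = 14 the confinement term alone exceeds 16 kcal/mol (> 27 kBT at
#'   the benchmark temperature), so the equilibrium density outside is
#'   negligible.
#' @param W,dWdz For `family = "custom"`: vectorized functions giving the
#'   energy (kcal/mol) and its derivative (kcal/mol/Å).
#' @return An object of class `potential_1d`.
#' @examples
#' pot <- potential_1d("narrow")
#' eval_potential(pot, 0)    # 0.1 kcal/mol
#' eval_force(pot, 0)        # 0 (even function)
#' @export
potential_1d <- function(family = c("narrow", "medium", "broad", "flat", "custom"),
                         params = NULL, domain = c(-14, 14),
                         W = NULL, dWdz = NULL) {
  family <- match.arg(family)
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  if (family == "custom") {
    if (!is.function(W) || !is.function(dWdz))
      stop("custom potentials must supply analytic W and dWdz functions")
    pp <- NULL
  } else {
    pp <- .family_params[[family]]
    if (!is.null(params)) {
      bad <- setdiff(names(params), names(pp))
      if (length(bad)) stop("unknown potential parameters: ", paste(bad, collapse = ", "))
      pp[names(params)] <- params
    }
    W <- NULL; dWdz <- NULL
  }
  structure(list(family = family, params = pp, domain = domain,
                 W_fun = W, dWdz_fun = dWdz),
            class = "potential_1d")
}

#' @export
print.potential_1d <- function(x, ...) {
  cat("<potential_1d> family =", x$family,
      " domain = [", x$domain[1], ",", x$domain[2], "] Å\n")
  if (!is.null(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

.check_domain <- function(pot, z) {
  if (any(!is.finite(z))) stop("non-finite position")
  if (any(z < pot$domain[1] | z > pot$domain[2]))
    stop(sprintf("position outside potential domain [%g, %g]",
                 pot$domain[1], pot$domain[2]))
}

# parameter vector handed to the C++ kernels: (a_c, h, w, p, c);
# a_c = 0 encodes "no confinement term"
.pot_param_vec <- function(pot) {
  if (pot$family == "custom") return(NULL)
  pp <- pot$params
  c(if (is.finite(pp$a_c)) pp$a_c else 0, pp$h, pp$w, pp$p, pp$c)
}

#' Evaluate a potential
#'
#' @param pot A [potential_1d()].
#' @param z Positions in Å (vectorized). Must lie within the potential
#'   domain.
#' @return Energies W(z) in kcal/mol.
#' @export
eval_potential <- function(pot, z) {
  .check_domain(pot, z)
  if (pot$family == "custom") return(pot$W_fun(z))
  pp <- pot$params
  confine <- if (is.finite(pp$a_c)) (z / pp$a_c)^12 else 0
  confine + pp$h * exp(-(z / pp$w)^pp$p) + pp$c
}

#' Evaluate the force -dW/dz
#'
#' Analytic derivative of the family formula (or the user-supplied
#' derivative for custom potentials).
#'
#' @inheritParams eval_potential
#' @return Forces in kcal/mol/Å.
#' @export
eval_force <- function(pot, z) {
  .check_domain(pot, z)
  if (pot$family == "custom") return(-pot$dWdz_fun(z))
  pp <- pot$params
  dconf <- if (is.finite(pp$a_c)) 12 * z^11 / pp$a_c^12 else 0
  dbump <- pp$h * exp(-(z / pp$w)^pp$p) * (-pp$p * z^(pp$p - 1) / pp$w^pp$p)
  -(dconf + dbump)
}

#' Thermodynamic and dynamic state
#'
#' @param kBT Thermal energy in kcal/mol (> 0).
#' @param D Diffusion coefficient in Å^2/ps (> 0).
#' @param mass Particle mass in amu, required only for inertial (Langevin)
#'   dynamics.
#' @return An object of class `thermo_state`.
#' @export
thermo_state <- function(kBT = 0.5915, D = 1, mass = NULL) {
  stopifnot(kBT > 0, D > 0)
  if (!is.null(mass)) stopifnot(mass > 0)
  structure(list(kBT = kBT, D = D, mass = mass), class = "thermo_state")
}

.trapz <- function(y, x) sum((head(y, -1) + tail(y, -1)) / 2 * diff(x))

.cumtrapz <- function(y, x) c(0, cumsum((head(y, -1) + tail(y, -1)) / 2 * diff(x)))

#' Equilibrium (Boltzmann) density profile
#'
#' Computes rho_eq(z) = exp(-W(z)/kBT)/Z on a uniform grid, with Z the
#' trapezoid integral over the grid. Exponentials are evaluated with a
#' subtract-max shift so that deep wells cannot overflow. A built-in
#' coarsening check warns when the grid is too coarse: if evaluating Z on
#' every other grid point shifts the normalization by more than `check_tol`
#' (relative), an accuracy warning is raised.
#'
#' @inheritParams eval_potential
#' @param th A [thermo_state()].
#' @param grid Optional explicit grid of z values (Å); otherwise a uniform
#'   grid over the potential domain with the given `spacing`.
#' @param spacing Grid spacing in Å (default 0.001).
#' @param check_tol Relative normalization-shift threshold for the
#'   coarseness warning.
#' @return An object of class `equilibrium_profile` with fields `grid`,
#'   `W`, `density` (Å^-1, integrates to 1), `Z` (the configurational
#'   integral of exp(-W/kBT) in Å), `pot`, `thermo`.
#' @export
equilibrium_profile <- function(pot, th, grid = NULL, spacing = 0.001,
                                check_tol = 1e-6) {
  stopifnot(inherits(pot, "potential_1d"), inherits(th, "thermo_state"))
  if (is.null(grid))
    grid <- seq(pot$domain[1], pot$domain[2], by = spacing)
  Wv <- eval_potential(pot, grid)
  e <- -Wv / th$kBT
  shift <- max(e)
  u <- exp(e - shift)
  Zs <- .trapz(u, grid)                     # Z * exp(-shift)
  dens <- u / Zs
  Z <- Zs * exp(shift)
  # coarseness check: normalization from the decimated grid
  i2 <- seq(1, length(grid), by = 2)
  Zs2 <- .trapz(u[i2], grid[i2])
  if (abs(Zs2 - Zs) / Zs > check_tol)
    warning(sprintf(
      "equilibrium grid may be too coarse: normalization shifts by %.2e on coarsening",
      abs(Zs2 - Zs) / Zs))
  structure(list(grid = grid, W = Wv, density = dens, Z = Z,
                 logZ = log(Zs) + shift, log_shift = shift,
                 pot = pot, thermo = th),
            class = "equilibrium_profile")
}

#' State probabilities from an equilibrium profile
#'
#' Splits the equilibrium density at a dividing point z-dagger. The
#' half-open convention assigns z >= z-dagger to state B (applied
#' consistently to all indicator functions in the package).
#'
#' @param profile An [equilibrium_profile()].
#' @param dividing_point Dividing position z-dagger in Å, inside the grid.
#' @return Named numeric vector `c(pA =, pB =)` with `pA + pB = 1`.
#' @export
state_probabilities <- function(profile, dividing_point) {
  g <- profile$grid
  if (dividing_point < g[1] || dividing_point > g[length(g)])
    stop("dividing point outside the profile grid")
  d <- profile$density
  below <- g < dividing_point
  if (!any(below)) {
    pA <- 0
  } else {
    k <- max(which(below))
    pA <- if (k >= 2) .trapz(d[1:k], g[1:k]) else 0
    if (k < length(g) && g[k] < dividing_point) {
      # partial trapezoid up to the dividing point
      f <- (dividing_point - g[k]) / (g[k + 1] - g[k])
      dz <- dividing_point - g[k]
      d_at <- d[k] + f * (d[k + 1] - d[k])
      pA <- pA + (d[k] + d_at) / 2 * dz
    }
  }
  total <- .trapz(d, g)
  pA <- pA / total
  c(pA = pA, pB = 1 - pA)
}

#' Export an equilibrium profile as CSV
#'
#' Writes columns `z`, `W`, `rho_eq`.
#'
#' @param profile An [equilibrium_profile()].
#' @param path Output file path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(data.frame(z = profile$grid, W = profile$W,
                       rho_eq = profile$density),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
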
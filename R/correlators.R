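# Time-correlation-function estimators of the reactive flux and the
# transmission coefficient.
#
# Four correlators are supported, all zero at t = 0 by construction and all
# converging to a straight line whose limiting slope is the steady-state
# reactive flux J_AB:
#   C_BB(t)    = <H_B(0) H_B(0)> - <H_B(0) H_B(t)>        (indicator)
#   C_zz(t)    = pA pB [1 - <dz(0) dz(t)>/<dz^2>]          (position)
#   C_qq(t)    = <q(0) q(0)> - <q(0) q(t)>                 (committor)
#   C_ABqq(t)  = <H_A(0) H_B(t) (q(t) - q(0))>             (restricted)
# Standard errors come from block averaging over contiguous blocks of time
# origins (20 blocks by default).

#' Dividing surface
#'
#' @param kind `"position"` (threshold z-dagger in Å) or `"committor"`
#'   (threshold q-dagger in (0,1), default 0.5, the separatrix).
#' @param threshold Threshold value. The half-open convention applies:
#'   values at or above the threshold belong to state B.
#' @return An object of class `dividing_surface`.
#' @export
dividing_surface <- function(kind = c("position", "committor"), threshold = NULL) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- if (kind == "committor") 0.5 else 0
  if (kind == "committor" && (threshold <= 0 || threshold >= 1))
    stop("committor threshold must lie in (0, 1)")
  structure(list(kind = kind, threshold = threshold), class = "dividing_surface")
}

.new_corr_series <- function(lags, values, stderr, estimator, n_origins) {
  structure(list(lags = lags, values = values, stderr = stderr,
                 estimator = estimator, n_origins = n_origins),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %s: %d lags in [%g, %g] ps\n",
              x$estimator, length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

.lags_to_steps <- function(traj, lags) {
  dt_out <- traj$params$dt * traj$params$stride
  steps <- lags / dt_out
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("lags must be multiples of the trajectory sampling interval ", dt_out, " ps")
  steps <- as.integer(round(steps))
  if (any(steps >= length(traj$positions)))
    stop("lag exceeds trajectory length")
  steps
}

.default_lags <- function(traj, t_max = 50) {
  dt_out <- traj$params$dt * traj$params$stride
  n_max <- min(floor(t_max / dt_out), length(traj$positions) - 1)
  (0:n_max) * dt_out
}

# indicator series for a dividing surface, half-open: >= threshold is B
.hB_series <- function(traj, ds, cp = NULL) {
  if (ds$kind == "position") {
    as.numeric(traj$positions >= ds$threshold)
  } else {
    if (is.null(cp)) stop("committor-kind dividing surface needs a committor profile")
    as.numeric(committor_at(cp, traj$positions) >= ds$threshold)
  }
}

#' Equilibrium time-correlation function of an observable
#'
#' Multiple-time-origin estimate of <v(0) v(t)> for an arbitrary function
#' v of position, with block-averaged standard errors.
#'
#' @param traj A `trajectory`.
#' @param observable Vectorized function of position.
#' @param lags Lag times in ps (multiples of the sampling interval).
#' @param nblocks Number of contiguous blocks for error estimation
#'   (default 20).
#' @return A `correlation_series` (estimator `"C_raw"`), containing the
#'   raw product average, not a subtracted correlator.
#' @export
estimate_correlation <- function(traj, observable, lags = NULL, nblocks = 20) {
  if (is.null(lags)) lags <- .default_lags(traj)
  steps <- .lags_to_steps(traj, lags)
  v <- observable(traj$positions)
  r <- .lag_mean_prod(v, v, steps, nblocks)
  .new_corr_series(lags, r$mean, r$se, "C_raw", length(v) - steps)
}

#' Indicator (population) correlation functions
#'
#' `indicator_correlation` computes C_BB(t) = <H_B(0) H_B(0)> -
#' <H_B(0) H_B(t)>; `population_correlation` computes the normalized
#' population correlator C(t) = 1 - C_BB(t)/(pA pB) with the state
#' probabilities estimated from the same trajectory.
#'
#' @param traj A `trajectory`.
#' @param ds A [dividing_surface()].
#' @param cp Committor profile (required for committor-kind surfaces).
#' @inheritParams estimate_correlation
#' @return A `correlation_series`.
#' @export
indicator_correlation <- function(traj, ds = dividing_surface("position", 0),
                                  cp = NULL, lags = NULL, nblocks = 20) {
  if (is.null(lags)) lags <- .default_lags(traj)
  steps <- .lags_to_steps(traj, lags)
  h <- .hB_series(traj, ds, cp)
  pB <- mean(h)
  if (pB == 0 || pB == 1)
    stop("trajectory never visits one of the states; nothing to correlate")
  r <- .lag_mean_cdiff(h, h, steps, nblocks)
  .new_corr_series(lags, r$mean, r$se, "C_BB", length(h) - steps)
}

#' @rdname indicator_correlation
#' @export
population_correlation <- function(traj, ds = dividing_surface("position", 0),
                                   cp = NULL, lags = NULL, nblocks = 20) {
  cbb <- indicator_correlation(traj, ds, cp, lags, nblocks)
  h <- .hB_series(traj, ds, cp)
  pB <- mean(h); pA <- 1 - pB
  .new_corr_series(cbb$lags, 1 - cbb$values / (pA * pB),
                   cbb$stderr / (pA * pB), "C_pop", cbb$n_origins)
}

#' Position correlation function
#'
#' C_zz(t) = pA pB \[1 - <dz(0) dz(t)>/<dz^2>\] with dz = z - <z>; the
#' state probabilities are estimated from the trajectory with the given
#' dividing surface. Shares the limiting slope J_AB with the other
#' correlators.
#'
#' @inheritParams indicator_correlation
#' @return A `correlation_series` (estimator `"C_zz"`).
#' @export
position_correlation <- function(traj, ds = dividing_surface("position", 0),
                                 lags = NULL, nblocks = 20) {
  if (is.null(lags)) lags <- .default_lags(traj)
  steps <- .lags_to_steps(traj, lags)
  dz <- traj$positions - mean(traj$positions)
  vz <- mean(dz^2)
  if (vz == 0) stop("zero position variance")
  h <- .hB_series(traj, ds)
  pApB <- mean(h) * (1 - mean(h))
  r <- .lag_mean_cdiff(dz, dz, steps, nblocks)
  .new_corr_series(lags, pApB * r$mean / vz, pApB * r$se / vz,
                   "C_zz", length(dz) - steps)
}

#' Committor correlation function
#'
#' C_qq(t) = <q(0) q(0)> - <q(0) q(t)> with q evaluated by linear
#' interpolation of the quadrature committor onto the trajectory (clamped
#' to 0/1 outside the absorbing boundaries). Its slope at the Markovian
#' lag time equals the steady-state reactive flux J_AB, with no
#' intermediate molecular time scale: the correlator is linear essentially
#' from the first lag when the projected dynamics is Markovian.
#'
#' @param traj A `trajectory`.
#' @param cp A `committor_profile`.
#' @inheritParams estimate_correlation
#' @return A `correlation_series` (estimator `"C_qq"`).
#' @export
committor_correlation <- function(traj, cp, lags = NULL, nblocks = 20) {
  if (is.null(lags)) lags <- .default_lags(traj)
  steps <- .lags_to_steps(traj, lags)
  q <- committor_at(cp, traj$positions)
  r <- .lag_mean_cdiff(q, q, steps, nblocks)
  .new_corr_series(lags, r$mean, r$se, "C_qq", length(q) - steps)
}

#' Indicator-restricted committor correlation function
#'
#' C_ABqq(t) = <H_A(0) H_B(t) (q(t) - q(0))> with the states defined on
#' the committor: H_A = theta(q-dagger - q(0)), H_B = theta(q(t) -
#' q-dagger) (half-open, B at equality). Restricting to transitions that
#' actually cross the separatrix gives a flux estimator whose derivative
#' plateaus within the Markovian lag even on broad barriers.
#'
#' @param traj A `trajectory`.
#' @param cp A `committor_profile`.
#' @param ds A committor-kind [dividing_surface()] (default q-dagger = 0.5).
#' @inheritParams estimate_correlation
#' @return A `correlation_series` (estimator `"C_ABqq"`).
#' @export
restricted_committor_correlation <- function(traj, cp,
                                             ds = dividing_surface("committor", 0.5),
                                             lags = NULL, nblocks = 20) {
  if (ds$kind != "committor") stop("restricted correlator needs a committor-kind surface")
  if (is.null(lags)) lags <- .default_lags(traj)
  steps <- .lags_to_steps(traj, lags)
  q <- committor_at(cp, traj$positions)
  r <- .lag_mean_abqq(q, ds$threshold, steps, nblocks)
  .new_corr_series(lags, r$mean, r$se, "C_ABqq", length(q) - steps)
}

#' Pool correlation series from independent trajectories
#'
#' Averages same-lag correlation series estimated on independent walkers;
#' pooled standard errors combine the per-walker block errors in
#' quadrature (se = sqrt(sum(se_i^2))/n for equal-length walkers).
#'
#' @param cs_list List of `correlation_series` on identical lag grids.
#' @return A pooled `correlation_series`.
#' @export
pool_correlation_series <- function(cs_list) {
  stopifnot(length(cs_list) >= 1)
  lags <- cs_list[[1]]$lags
  for (cs in cs_list)
    if (length(cs$lags) != length(lags) || max(abs(cs$lags - lags)) > 1e-9)
      stop("all series must share one lag grid")
  n <- length(cs_list)
  vals <- rowMeans(sapply(cs_list, `[[`, "values"))
  ses <- sqrt(rowSums(sapply(cs_list, function(cs) cs$stderr^2))) / n
  .new_corr_series(lags, vals, ses, cs_list[[1]]$estimator,
                   Reduce(`+`, lapply(cs_list, `[[`, "n_origins")))
}

#' Reactive flux from batched independent walkers
#'
#' Simulates `n_walkers` independent trajectories (seeds derived as
#' `seed + walker index`), evaluates the committor correlator C_qq on
#' each, pools them, and extracts the flux as the mean slope over
#' `fit_window`. Walkers start alternately in the A and B wells so the
#' aggregate respects the equilibrium symmetry. Processing is
#' walker-by-walker, so memory stays bounded by one trajectory.
#'
#' @param pot,th Potential and thermodynamic state.
#' @param cp Quadrature `committor_profile` mapped onto the trajectories.
#' @param n_walkers Number of independent walkers.
#' @param t_walker Length of each walker in ps.
#' @param dt Integration step in ps.
#' @param stride Storage stride in steps.
#' @param seed Base RNG seed.
#' @param integrator `"brownian"` or `"langevin"`.
#' @param lags Lag grid in ps (default 0 to 5 ps every 10 stored frames).
#' @param fit_window Slope-averaging window in ps (default `c(0.5, 5)`).
#' @param nblocks_walker Error blocks per walker (default 4; pooled errors
#'   then rest on n_walkers x nblocks_walker blocks).
#' @return A `rate_estimate` with the pooled `correlation_series` attached
#'   as attribute `series`.
#' @export
batched_committor_flux <- function(pot, th, cp, n_walkers, t_walker,
                                   dt = 0.001, stride = 10, seed = 1,
                                   integrator = c("langevin", "brownian"),
                                   lags = NULL, fit_window = c(0.5, 5),
                                   nblocks_walker = 4) {
  integrator <- match.arg(integrator)
  wells <- .well_positions(pot, th)
  if (is.null(lags)) lags <- seq(0, 5, by = 10 * dt * stride)
  series <- vector("list", n_walkers)
  for (w in seq_len(n_walkers)) {
    sp <- sim_params(integrator, dt = dt, n_steps = round(t_walker / dt),
                     stride = stride, seed = seed + w,
                     initial_position = wells[(w %% 2) + 1])
    traj <- if (integrator == "langevin") simulate_langevin(pot, th, sp)
            else simulate_brownian(pot, th, sp)
    series[[w]] <- committor_correlation(traj, cp, lags = lags,
                                         nblocks = nblocks_walker)
    rm(traj)
  }
  pooled <- pool_correlation_series(series)
  est <- extract_flux(pooled, fit_window = fit_window)
  attr(est, "series") <- pooled
  est
}

# positions of the two well minima (force roots bracketing the barrier)
.well_positions <- function(pot, th) {
  g <- seq(pot$domain[1] * 0.98, pot$domain[2] * 0.98, length.out = 4001)
  dens <- exp(-(eval_potential(pot, g) - min(eval_potential(pot, g))) / th$kBT)
  iA <- which.max(dens[g < 0])
  iB <- which(g >= 0)[which.max(dens[g >= 0])]
  c(g[iA], g[iB])
}

#' Numerical derivative of a correlation series
#'
#' Central differences at interior lags, one-sided at the ends, with
#' propagated standard errors. Requires a uniform lag grid.
#'
#' @param cs A `correlation_series` with at least 3 lags.
#' @return A `correlation_series` whose values are d/dt of the input
#'   (units ps^-1), estimator suffixed `"_dot"`.
#' @export
correlation_derivative <- function(cs) {
  n <- length(cs$lags)
  if (n < 3) stop("need at least 3 lags")
  dl <- diff(cs$lags)
  if (max(abs(dl - dl[1])) > 1e-9 * dl[1]) stop("lags must be uniform")
  h <- dl[1]
  v <- cs$values; e <- cs$stderr
  d <- numeric(n); de <- numeric(n)
  d[1] <- (v[2] - v[1]) / h
  de[1] <- sqrt(e[2]^2 + e[1]^2) / h
  d[n] <- (v[n] - v[n - 1]) / h
  de[n] <- sqrt(e[n]^2 + e[n - 1]^2) / h
  i <- 2:(n - 1)
  d[i] <- (v[i + 1] - v[i - 1]) / (2 * h)
  de[i] <- sqrt(e[i + 1]^2 + e[i - 1]^2) / (2 * h)
  .new_corr_series(cs$lags, d, de, paste0(cs$estimator, "_dot"), cs$n_origins)
}

#' Extract the reactive flux from a correlator's limiting slope
#'
#' Differentiates the correlator and finds the plateau of the derivative:
#' the earliest lag where the derivative varies by less than `rel_tol`
#' (relative to its local mean) across a sliding window of `window`
#' points. The flux is the inverse-variance-weighted mean derivative from
#' the plateau time to the last lag. Supplying `fit_window = c(t_lo,
#' t_hi)` bypasses plateau detection and averages the derivative over that
#' window instead.
#'
#' @param cs A `correlation_series`.
#' @param rel_tol Relative stability tolerance for plateau detection
#'   (default 0.05).
#' @param window Sliding-window length in points (default 20).
#' @param fit_window Optional explicit averaging window `c(t_lo, t_hi)` in
#'   ps.
#' @param pA Optional state-A probability; when given, `k_AB = J_AB/pA` is
#'   filled in.
#' @return An object of class `rate_estimate` with fields `J_AB`, `J_se`,
#'   `k_AB`, `plateau_time`, `fit_window`, `method`.
#' @export
extract_flux <- function(cs, rel_tol = 0.05, window = 20, fit_window = NULL,
                         pA = NULL) {
  dcs <- correlation_derivative(cs)
  # the lag-0 one-sided derivative is biased for correlators pinned to 0;
  # start the search at the first interior lag
  d <- dcs$values[-1]; e <- dcs$stderr[-1]; tt <- dcs$lags[-1]
  if (!is.null(fit_window)) {
    sel <- tt >= fit_window[1] & tt <= fit_window[2]
    if (!any(sel)) stop("empty fit window")
    plateau_time <- tt[which(sel)[1]]
    method <- "fixed_window"
  } else {
    n <- length(d)
    if (n < window) stop("fewer derivative points than the plateau window")
    plateau_idx <- NA_integer_
    for (i in seq_len(n - window + 1)) {
      vals <- d[i:(i + window - 1)]
      m <- mean(vals)
      if (m != 0 && (max(vals) - min(vals)) < rel_tol * abs(m)) {
        plateau_idx <- i
        break
      }
    }
    if (is.na(plateau_idx))
      stop("no plateau: the derivative of ", cs$estimator,
           " is still varying by more than ", rel_tol * 100,
           "% at the longest lag")
    plateau_time <- tt[plateau_idx]
    sel <- tt >= plateau_time
    method <- "plateau"
    fit_window <- c(plateau_time, tt[length(tt)])
  }
  w <- 1 / pmax(e[sel], 1e-300)^2
  J <- sum(w * d[sel]) / sum(w)
  J_se <- sqrt(1 / sum(w))
  structure(list(J_AB = J, J_se = J_se,
                 k_AB = if (!is.null(pA)) J / pA else NA_real_,
                 kappa = NA_real_, k_TST = NA_real_,
                 plateau_time = plateau_time, fit_window = fit_window,
                 method = method, estimator = cs$estimator),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s: J_AB = %.4e ± %.1e ps^-1 (plateau at %.3g ps, %s)\n",
              x$estimator, x$J_AB, x$J_se, x$plateau_time, x$method))
  if (!is.na(x$k_AB)) cat(sprintf("  k_AB = %.4e ps^-1\n", x$k_AB))
  if (!is.na(x$kappa)) cat(sprintf("  kappa = %.3f  k_TST = %.4e ps^-1\n", x$kappa, x$k_TST))
  invisible(x)
}

#' Error-aware plateau onset of a correlator derivative
#'
#' For stochastic correlation series the point-wise derivative fluctuates
#' by many standard errors, so the sliding-window relative criterion of
#' [extract_flux()] is unusable; this variant bins the derivative into
#' windows of `bin_width` ps and reports the earliest bin from which the
#' binned derivative stays statistically compatible (within `z` combined
#' standard errors) with the tail value averaged over `tail_window`.
#'
#' @param cs A `correlation_series`.
#' @param tail_window `c(t_lo, t_hi)` in ps defining the limiting-slope
#'   reference region.
#' @param bin_width Width of the averaging bins in ps (default 1).
#' @param z Compatibility threshold in combined standard errors
#'   (default 3).
#' @param band Optional absolute compatibility half-width (ps^-1) that
#'   replaces the per-series error band. When comparing onsets across
#'   estimators of different noise levels, a common band keeps a noisier
#'   estimator from being awarded an earlier onset merely because its
#'   error bars are wider.
#' @param j_tail Optional externally supplied limiting slope; by default
#'   the error-weighted mean over `tail_window`.
#' @param persist Number of consecutive compatible bins required to call
#'   the onset. The default `Inf` demands compatibility of every later
#'   bin (appropriate for clean series); noisy tails that wobble in and
#'   out of the band need a finite horizon (e.g. 3).
#' @return The onset time in ps (left edge of the first compatible bin),
#'   with the binned derivative table as attribute `bins`.
#' @export
plateau_onset <- function(cs, tail_window, bin_width = 1, z = 3,
                          band = NULL, j_tail = NULL, persist = Inf) {
  dcs <- correlation_derivative(cs)
  tt <- dcs$lags[-1]; d <- dcs$values[-1]; e <- dcs$stderr[-1]
  sel <- tt >= tail_window[1] & tt <= tail_window[2]
  if (!any(sel)) stop("empty tail window")
  w <- 1 / pmax(e[sel], 1e-300)^2
  if (is.null(j_tail)) j_tail <- sum(w * d[sel]) / sum(w)
  se_tail <- sqrt(1 / sum(w))
  bins <- floor(tt / bin_width)
  bm <- tapply(d, bins, mean)
  # adjacent central differences share points; halve the nominal gain
  bn <- tapply(d, bins, length)
  bse <- sqrt(tapply(e^2, bins, mean) / pmax(bn / 2, 1))
  bt <- as.numeric(names(bm)) * bin_width
  ok <- if (is.null(band)) abs(bm - j_tail) < z * sqrt(bse^2 + se_tail^2)
        else abs(bm - j_tail) < band
  onset_idx <- if (is.finite(persist)) {
    # earliest run of `persist` consecutive compatible bins
    runs <- vapply(seq_along(ok), function(i)
      all(ok[i:min(i + persist - 1, length(ok))]), TRUE)
    which(runs)[1]
  } else {
    # earliest bin from which every later bin is also compatible
    which(rev(cumprod(rev(ok))) == 1)[1]
  }
  if (is.na(onset_idx)) stop("derivative never becomes compatible with its tail")
  structure(bt[onset_idx],
            bins = data.frame(t = bt, value = as.numeric(bm),
                              se = as.numeric(bse), compatible = ok),
            J_tail = j_tail, J_tail_se = se_tail)
}

#' Transition-state-theory rate
#'
#' k_TST = (rho_eq(z-dagger)/pA) <v theta(v)> with the one-way thermal flux
#' <v theta(v)> = sqrt(kBT/(2 pi m)) (half-Gaussian mean of the Maxwell
#' distribution). This is the no-recrossing rate through the dividing
#' surface.
#'
#' @param profile An [equilibrium_profile()].
#' @param th A [thermo_state()] with `mass`.
#' @param z_dagger Dividing-surface position in Å.
#' @return Rate in ps^-1.
#' @export
tst_rate <- function(profile, th, z_dagger) {
  if (is.null(th$mass)) stop("TST rate requires a mass")
  rho <- approx(profile$grid, profile$density, xout = z_dagger)$y
  pA <- state_probabilities(profile, z_dagger)[["pA"]]
  vflux <- sqrt(th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2 / (2 * pi * th$mass))
  rho / pA * vflux
}

#' Transmission coefficient from dividing-surface shots
#'
#' Launches Langevin trajectories from Maxwell-distributed initial
#' velocities at the dividing surface and computes
#' kappa(t) = <v(0) H_B(t)> / <v(0) theta(v(0))>, normalizing by the
#' analytic half-Gaussian flux sqrt(kBT/(2 pi m)) rather than a numerical
#' difference. kappa(0+) = 1 by construction (every forward-moving shot is
#' in B under the half-open convention); the plateau value times k_TST is
#' the forward rate k_AB.
#'
#' @param shots Data frame from [sample_dividing_surface()].
#' @param pot A [potential_1d()].
#' @param th A [thermo_state()] with `mass`.
#' @param t_max Trajectory length per shot in ps.
#' @param dt Integration time step in ps.
#' @param stride Output interval in steps.
#' @param seed RNG seed for the shot trajectories.
#' @return A data frame with columns `t`, `kappa`, `se` (shot-to-shot
#'   standard error).
#' @export
transmission_coefficient <- function(shots, pot, th, t_max, dt = 0.001,
                                     stride = 10, seed = 1) {
  if (is.null(th$mass)) stop("transmission coefficient requires a mass")
  pp <- .pot_param_vec(pot)
  if (is.null(pp)) stop("requires a parametric potential")
  z_dagger <- shots$position[1]
  n_steps <- ceiling(t_max / dt)
  set.seed(as.integer(seed))
  H <- .kappa_shots_kernel(z_dagger, shots$velocity, dt, n_steps, stride,
                           th$kBT, th$D, th$mass, pp,
                           pot$domain[1], pot$domain[2])
  denom <- sqrt(th$kBT * KCAL_PER_MOL_TO_AMU_A2_PS2 / (2 * pi * th$mass))
  w <- shots$velocity / nrow(H)
  num <- as.numeric(crossprod(w, H))            # <v(0) H_B(t)>
  # shot-to-shot error of the numerator
  se <- apply(H * shots$velocity, 2, sd) / sqrt(nrow(H))
  data.frame(t = seq_len(ncol(H)) * dt * stride,
             kappa = num / denom, se = se / denom)
}

#' Write a correlation series as CSV
#'
#' Columns `lag_ps`, `value`, `stderr`; the estimator identity is kept in
#' a comment header line.
#'
#' @param cs A `correlation_series`.
#' @param path File path.
#' @export
write_correlation_csv <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# estimator: %s", cs$estimator), "lag_ps,value,stderr"), con)
  writeLines(sprintf("%.17g,%.17g,%.17g", cs$lags, cs$values, cs$stderr), con)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
read_correlation_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  est <- if (grepl("^# estimator:", hdr)) sub("^# estimator: *", "", hdr) else "unknown"
  df <- read.csv(path, comment.char = "#")
  if (!all(c("lag_ps", "value", "stderr") %in% names(df)))
    stop("malformed correlation CSV: need columns lag_ps,value,stderr in ", path)
  .new_corr_series(df$lag_ps, df$value, df$stderr, est, NA_integer_)
}
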
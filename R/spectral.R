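# Markov propagator estimation and spectral analysis.
#
# A trajectory is discretized into position bins; transition counts at lag
# tau are symmetrized as (C + C^T)/2 to enforce detailed balance, then row
# normalized into a stochastic matrix T. Because the symmetrized chain is
# reversible, the similarity transform S = diag(sqrt(pi)) T diag(1/sqrt(pi))
# is symmetric and the spectrum is real: eigenvalues lambda_k = exp(-mu_k
# tau) give the implied rates mu_k = -log(lambda_k)/tau, and the
# eigenvectors map to the propagator's left/right eigenfunctions
# (psi_1L = 1, psi_1R = pi).

#' Uniform bin edges
#'
#' @param lo,hi Interval in Å (default \[-12, 12\]).
#' @param n Number of bins (default 120).
#' @return Vector of n + 1 edges.
#' @export
uniform_bins <- function(lo = -12, hi = 12, n = 120) seq(lo, hi, length.out = n + 1)

#' Build a transition matrix from a trajectory
#'
#' Sliding-window transition counts at the given lag, symmetrized and row
#' normalized. Bins never visited are dropped; `index_map` records the
#' original bin index of each retained row. An error is raised if the
#' occupied bins split into disconnected components (no rate information
#' between them).
#'
#' @param traj A `trajectory`.
#' @param bin_edges Bin edges in Å (see [uniform_bins()]).
#' @param lag Lag time in ps, a multiple of the trajectory sampling
#'   interval.
#' @return An object of class `spectral_model` with fields `bin_edges`,
#'   `centers`, `lag`, `counts` (symmetrized), `T`, `stationary`,
#'   `index_map`, `n_samples`. Eigen-quantities are filled by
#'   [spectral_decomposition()].
#' @export
build_transition_matrix <- function(traj, bin_edges, lag) {
  dt_out <- traj$params$dt * traj$params$stride
  lsteps <- lag / dt_out
  if (abs(lsteps - round(lsteps)) > 1e-6)
    stop("lag must be a multiple of the sampling interval ", dt_out, " ps")
  lsteps <- as.integer(round(lsteps))
  nb <- length(bin_edges) - 1
  bins <- findInterval(traj$positions, bin_edges, rightmost.closed = TRUE)
  bins[bins < 1 | bins > nb] <- 0L
  C <- .count_transitions(bins, nb, lsteps)
  Cs <- (C + t(C)) / 2
  occ <- which(rowSums(Cs) > 0)
  if (length(occ) < 2) stop("fewer than 2 occupied bins")
  Cs <- Cs[occ, occ, drop = FALSE]
  # connectivity of the symmetrized count graph
  n <- length(occ)
  comp <- integer(n); comp[1] <- 1L; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(comp == 0L & colSums(Cs[frontier, , drop = FALSE] > 0) > 0)
    comp[nxt] <- 1L
    frontier <- nxt
  }
  if (any(comp == 0L))
    stop("occupied bins are disconnected; components: {",
         paste(occ[comp == 1L], collapse = ","), "} vs {",
         paste(occ[comp == 0L], collapse = ","), "}")
  Tm <- Cs / rowSums(Cs)
  pi_hat <- rowSums(Cs) / sum(Cs)
  structure(list(bin_edges = bin_edges,
                 centers = ((head(bin_edges, -1) + tail(bin_edges, -1)) / 2)[occ],
                 lag = lag, counts = Cs, T = Tm, stationary = pi_hat,
                 index_map = occ, n_samples = sum(C),
                 lambdas = NULL, mus = NULL,
                 left_vectors = NULL, right_vectors = NULL),
            class = "spectral_model")
}

#' Spectral decomposition of a reversible transition matrix
#'
#' Solves the eigenproblem on the pi-symmetrized similarity transform
#' (guaranteeing a real spectrum in floating point), orders eigenvalues
#' descending, and fills implied rates mu_k = -log(lambda_k)/lag and the
#' propagator's left and right eigenfunctions normalized so that
#' (psi_kL . psi_lR) = delta_kl, psi_1L = 1, psi_1R = stationary.
#'
#' @param sm A `spectral_model` from [build_transition_matrix()].
#' @return The model with `lambdas`, `mus`, `left_vectors`,
#'   `right_vectors` filled (vectors as columns, mode k in column k).
#' @export
spectral_decomposition <- function(sm) {
  p <- sm$stationary
  sp <- sqrt(p)
  S <- sweep(sweep(sm$T, 1, sp, `*`), 2, sp, `/`)
  S <- (S + t(S)) / 2   # symmetric up to round-off by construction
  eig <- eigen(S, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  lam <- eig$values[ord]
  U <- eig$vectors[, ord, drop = FALSE]
  # fix sign: psi_1L must be +1; for k = 2 make the B side (larger z) positive
  for (k in seq_len(ncol(U))) {
    ref <- if (k == 1) sum(U[, k] * sp) else U[nrow(U), k] / sp[length(sp)]
    if (ref < 0) U[, k] <- -U[, k]
  }
  psiL <- U / sp          # right eigenvectors of T  (paper's left)
  psiR <- U * sp          # left eigenvectors of T   (paper's right)
  sm$lambdas <- lam
  sm$mus <- -log(pmin(pmax(lam, .Machine$double.eps), 1)) / sm$lag
  sm$left_vectors <- psiL
  sm$right_vectors <- psiR
  sm
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model> %d bins, lag %g ps, %d transition samples\n",
              nrow(x$T), x$lag, as.integer(x$n_samples)))
  if (!is.null(x$mus))
    cat(sprintf("  mu2 = %.4e ps^-1 (tau* = %.1f ps), gap mu3/mu2 = %.1f\n",
                x$mus[2], 1 / x$mus[2], x$mus[3] / x$mus[2]))
  invisible(x)
}

#' Model committor from the second left eigenfunction
#'
#' Builds the two-state model committor q = (psi_2L - a)/(b - a) clipped
#' to \[0, 1\], where a and b are the means of psi_2L over the A- and
#' B-core bins (sign-fixed so a < 0 < b). Also reports the two-state
#' consistency residuals |a + (b - a) pB| and
#' |1 - (b - a)^2 (pA pB - <q(1-q)>)|.
#'
#' @param sm A decomposed `spectral_model`.
#' @param core_A_bins,core_B_bins Row indices (into the retained bins) of
#'   the core sets; alternatively supply `cp` and they default to bins
#'   with quadrature committor < `q_lo` / > `q_hi`.
#' @param cp Optional `committor_profile` used to build default cores.
#' @param q_lo,q_hi Core thresholds (defaults 0.05 and 0.95).
#' @return An object of class `model_committor`: list with `q` (per bin),
#'   `a`, `b`, `residual_ab`, `residual_norm`, `centers`.
#' @export
model_committor <- function(sm, core_A_bins = NULL, core_B_bins = NULL,
                            cp = NULL, q_lo = 0.05, q_hi = 0.95) {
  if (is.null(sm$left_vectors)) stop("run spectral_decomposition() first")
  if (is.null(core_A_bins) || is.null(core_B_bins)) {
    if (is.null(cp)) stop("supply core bins or a committor profile")
    qc <- committor_at(cp, sm$centers)
    core_A_bins <- which(qc < q_lo)
    core_B_bins <- which(qc > q_hi)
  }
  if (!length(core_A_bins) || !length(core_B_bins)) stop("empty core set")
  psi2 <- sm$left_vectors[, 2]
  a <- mean(psi2[core_A_bins])
  b <- mean(psi2[core_B_bins])
  if (a > b) { psi2 <- -psi2; tmp <- a; a <- -b; b <- -tmp }
  if (!(a < 0 && b > 0))
    stop("second eigenfunction does not discriminate the states ",
         "(a and b have the same sign); check the spectral gap")
  q <- pmin(pmax((psi2 - a) / (b - a), 0), 1)
  p <- sm$stationary
  pB <- sum(p * (q >= 0.5))
  pA <- 1 - pB
  pq <- sum(p * q * (1 - q))
  structure(list(q = q, a = a, b = b,
                 residual_ab = abs(a + (b - a) * pB),
                 residual_norm = abs(1 - (b - a)^2 * (pA * pB - pq)),
                 centers = sm$centers),
            class = "model_committor")
}

#' Indicator overlaps with the propagator eigenfunctions
#'
#' Computes the amplitudes (H_B . psi_kR) for every mode; the mode-k
#' contribution to the indicator fluctuation correlator is this amplitude
#' squared times exp(-mu_k t). The k > 1 amplitudes squared sum exactly to
#' the t = 0 variance pA pB.
#'
#' @param sm A decomposed `spectral_model`.
#' @param ds A position-kind [dividing_surface()].
#' @return Numeric vector of amplitudes, one per mode.
#' @export
indicator_overlaps <- function(sm, ds = dividing_surface("position", 0)) {
  if (is.null(sm$right_vectors)) stop("run spectral_decomposition() first")
  hB <- as.numeric(sm$centers >= ds$threshold)
  as.numeric(crossprod(sm$right_vectors, hB))
}

#' Two-state steady-state flux from spectral quantities
#'
#' J_AB = pA pB (1/tau) (1 - exp(-mu2 tau)) /
#'        \[1 + (tau_r/tau)(1 - exp(-mu2 tau))\].
#' In the limit tau_r = 0, mu2 tau -> 0 this reduces to
#' J_AB = pA pB mu2, and the value is independent of the lag as long as
#' mu2 tau << 1.
#'
#' @param mu2 Second implied rate in ps^-1.
#' @param lag Lag time tau in ps.
#' @param tau_transit Mean transit time tau_r in ps.
#' @param pA,pB State probabilities (pA + pB = 1).
#' @return Flux in ps^-1.
#' @export
two_state_flux <- function(mu2, lag, tau_transit, pA, pB) {
  stopifnot(mu2 > 0, lag > 0, tau_transit >= 0, pA > 0, pB > 0)
  if (abs(pA + pB - 1) > 1e-8) stop("pA + pB must equal 1")
  x <- 1 - exp(-mu2 * lag)
  pA * pB * (x / lag) / (1 + tau_transit / lag * x)
}

#' Reactive flux from the estimated rate matrix
#'
#' Estimates the generator K = (T - I)/lag (valid for mu2 lag << 1) and
#' evaluates the continuous-time flux quadratic form
#' J = -sum_{ij} q_j q_i K_ij pi_i.
#'
#' @param sm A `spectral_model`.
#' @param q_bins Committor value per retained bin.
#' @return Flux in ps^-1.
#' @export
rate_matrix_flux <- function(sm, q_bins) {
  if (length(q_bins) != nrow(sm$T)) stop("q_bins length must match the bins")
  K <- (sm$T - diag(nrow(sm$T))) / sm$lag
  -as.numeric(t(sm$stationary * q_bins) %*% K %*% q_bins)
}

#' Chapman–Kolmogorov test
#'
#' Compares the transition matrix estimated directly at n times the lag
#' with the n-th power of the matrix estimated at the lag, for each
#' requested multiple. The discrepancy for each n is the maximum absolute
#' entry difference over well-sampled entries; the reference scale
#' combines the multinomial sampling error of both estimates
#' (propagating the lag-tau error through the n-fold power as sqrt(n)).
#' Because counts come from a sliding window, frames are reused lag/dt
#' times, so the error scales use effective counts N/(lag/dt) rather than
#' raw counts. An entry z-score above `z_crit` (default:
#' Bonferroni-adjusted 1% two-sided normal quantile over the compared
#' entries) fails that multiple.
#'
#' @param traj A `trajectory`.
#' @param bin_edges Bin edges in Å.
#' @param lag Base lag in ps.
#' @param multiples Integer multiples n to test.
#' @param min_counts Entries with fewer expected counts than this are
#'   excluded from the comparison (default 25).
#' @param z_crit Optional fixed z threshold.
#' @return Data frame with columns `n`, `max_discrepancy`, `ref_scale`
#'   (the median entry scale), `max_z`, `pass`.
#' @export
chapman_kolmogorov_test <- function(traj, bin_edges, lag, multiples = c(2, 5),
                                    min_counts = 25, z_crit = NULL) {
  sm1 <- build_transition_matrix(traj, bin_edges, lag)
  rows <- sm1$index_map
  out <- lapply(multiples, function(n) {
    smn <- build_transition_matrix(traj, bin_edges, n * lag)
    common <- intersect(rows, smn$index_map)
    i1 <- match(common, rows)
    i2 <- match(common, smn$index_map)
    Tn_pred <- sm1$T[i1, i1, drop = FALSE]
    # renormalize rows after restriction to the common support
    Tn_pred <- Tn_pred / rowSums(Tn_pred)
    P <- Tn_pred
    if (n > 1) for (k in seq_len(n - 1)) P <- P %*% Tn_pred
    Tn_obs <- smn$T[i2, i2, drop = FALSE]
    Tn_obs <- Tn_obs / rowSums(Tn_obs)
    dt_out <- traj$params$dt * traj$params$stride
    N_obs <- rowSums(smn$counts[i2, i2, drop = FALSE]) / max(1, n * lag / dt_out)
    N_lag <- rowSums(sm1$counts[i1, i1, drop = FALSE]) / max(1, lag / dt_out)
    pbar <- (P + Tn_obs) / 2
    var_obs <- pbar * (1 - pbar) / N_obs
    var_pred <- n * pbar * (1 - pbar) / N_lag   # sqrt(n) error growth through the power
    scale <- sqrt(var_obs + var_pred)
    well <- (pbar * pmin(N_obs, N_lag)) >= min_counts
    if (!any(well)) return(data.frame(n = n, max_discrepancy = NA_real_,
                                      ref_scale = NA_real_, max_z = NA_real_,
                                      pass = NA))
    diffm <- abs(Tn_obs - P)
    z <- diffm[well] / scale[well]
    zc <- if (is.null(z_crit)) qnorm(1 - 0.005 / sum(well)) else z_crit
    data.frame(n = n, max_discrepancy = max(diffm[well]),
               ref_scale = stats::median(scale[well]),
               max_z = max(z), pass = max(z) < zc)
  })
  do.call(rbind, out)
}

#' Save/load a spectral model as JSON
#'
#' Stores edges, lag, transition matrix, stationary distribution,
#' eigenvalues, implied rates and eigenvectors as a JSON document, plus a
#' compact summary (mu2, tau*, gap ratio).
#'
#' @param sm A `spectral_model`.
#' @param path File path.
#' @export
write_spectral_json <- function(sm, path) {
  obj <- list(bin_edges = sm$bin_edges, centers = sm$centers, lag = sm$lag,
              T = sm$T, stationary = sm$stationary, index_map = sm$index_map,
              counts = sm$counts, n_samples = sm$n_samples,
              lambdas = sm$lambdas, mus = sm$mus,
              left_vectors = sm$left_vectors, right_vectors = sm$right_vectors,
              summary = if (!is.null(sm$mus))
                list(mu2 = sm$mus[2], tau_star = 1 / sm$mus[2],
                     gap_ratio = sm$mus[3] / sm$mus[2]) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_spectral_json
#' @export
read_spectral_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("T", "counts", "left_vectors", "right_vectors"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  structure(obj[c("bin_edges", "centers", "lag", "counts", "T", "stationary",
                  "index_map", "n_samples", "lambdas", "mus",
                  "left_vectors", "right_vectors")],
            class = "spectral_model")
}
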
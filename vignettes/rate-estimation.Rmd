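---
title: "Three consistent routes to the transition rate of a two-state system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three consistent routes to the transition rate of a two-state system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratepaths)
```

## The problem

A stochastic system with two long-lived metastable states $A$ and $B$ is
phenomenologically a two-state kinetic model with forward and backward rates
$k_{AB}$, $k_{BA}$, equilibrium probabilities $p_A$, $p_B$, and a global
relaxation time $\tau^* = (k_{AB} + k_{BA})^{-1}$. Three theoretical
frameworks quantify this kinetics:

1. **Committor-based steady-state flux** (transition path theory). The
   committor $q(z)$ is the probability that a trajectory started at $z$
   reaches $B$ before $A$. For 1D overdamped diffusion in a potential
   $W(z)$ with absorbing boundaries $z_1$ and $z_2$,
   $$q(z) = \frac{\int_{z_1}^{z} e^{W/k_BT}\,dz'}{\int_{z_1}^{z_2} e^{W/k_BT}\,dz'},$$
   and the net unidirectional reactive flux has the closed form
   $J_{AB} = D / (Z_\mathrm{full}\, Z_\mathrm{barrier})$ with
   $Z_\mathrm{full} = \int e^{-W/k_BT} dz$ and
   $Z_\mathrm{barrier} = \int_{z_1}^{z_2} e^{W/k_BT} dz$. Equivalently,
   $J_{AB} = \int (\partial_z q)^2 D \rho_\mathrm{eq}\, dz$, a Dirichlet
   form that is *variational*: any trial committor satisfying the boundary
   conditions bounds the true flux from above. Derived observables are the
   reactive probability $p_{AB} = \langle q(1-q)\rangle$ and the mean
   transit time $\langle\tau_r\rangle = \langle q(1-q)\rangle / J_{AB}$.

2. **Spectral analysis of the Markov propagator.** Discretizing the
   dynamics into position bins at lag $\tau$ yields a row-stochastic
   matrix $T$ whose eigenvalues $\lambda_k = e^{-\mu_k \tau}$ carry the
   implied rates. For a two-state system, $\mu_2 = 1/\tau^*$ and
   $J_{AB} \approx p_A p_B \mu_2$ when $\mu_2\tau \ll 1$ and
   $\langle\tau_r\rangle\mu_2 \ll 1$; the package also implements the full
   finite-lag two-state flux formula with the transit-time correction, and
   the second left eigenfunction supplies a *model committor*
   $q \approx (\psi_2^L - a)/(b-a)$ with $a<0<b$ the eigenfunction levels
   in the two basins.

3. **Activated-dynamics correlation functions.** Four correlators, all
   zero at $t=0$, converge to a common limiting slope equal to $J_{AB}$:
   the indicator correlator $C_{BB}$, the position correlator $C_{zz}$,
   the committor correlator $C_{qq}$, and the indicator-restricted
   committor correlator $C_{AB\text{-}qq} = \langle H_A(0) H_B(t)
   [q(t)-q(0)]\rangle$. They differ in *when* they reach that slope: the
   committor-based estimators are linear essentially from the Markovian
   lag, while $C_{BB}$ on a broad flat barrier needs a long molecular time
   $\tau_m$ — the classic weakness of the reactive-flux algorithm that the
   committor weighting repairs. The transmission-coefficient route
   $k_{AB} = \kappa\, k_{AB}^\mathrm{TST}$ is implemented via
   Maxwell-distributed shots from the dividing surface, with
   $k^\mathrm{TST} = (\rho_\mathrm{eq}(z^\dagger)/p_A)\sqrt{k_BT/2\pi m}$.

## Benchmark systems

Three symmetric double wells ship as named families,
$$W(z) = (z/9.51)^{12} + h\, e^{-(z/w)^p} + c \quad [\mathrm{kcal/mol},\ z\ \mathrm{in\ Å}],$$
with $(h, w, p, c)$ equal to $(3.3, 0.6, 2, -3.2)$ ("narrow"),
$(3.3, 4.0, 2, -3.3)$ ("medium") and $(3.2, 7.0, 16, -3.2)$ ("broad"): a
steep even confinement plus a central bump whose width sets the barrier
character. The benchmark thermodynamic state is $k_BT = 0.5915$ kcal/mol,
$D = 1$ Å²/ps, and for inertial runs $m = 20$ amu; committor boundaries sit
at $z_{1,2} = \mp 7$ Å. The benchmark protocols are Brownian dynamics at
$\Delta t = 0.005$ ps and Langevin dynamics at $\Delta t = 0.001$ ps.

```{r quadrature}
th <- thermo_state(kBT = 0.5915, D = 1)
two_state_summary(potential_1d("broad"), th)
```

## Numerical choices

- **Normalization domain.** The committor boundaries are $\pm 7$ Å, but the
  equilibrium density extends beyond them; $\rho_\mathrm{eq}$ is normalized
  on $[-14, 14]$ Å, where the confinement term alone exceeds
  $16$ kcal/mol ($> 27\,k_BT$), so the truncated tail is below $10^{-10}$
  of $Z$. Default grid spacing is $0.001$ Å.
- **Quadrature.** Trapezoid rule throughout; `equilibrium_profile()` warns
  if decimating the grid shifts the normalization by more than $10^{-6}$.
  All $e^{\pm W/k_BT}$ integrals subtract the extreme exponent before
  exponentiating, so deep wells cannot overflow. The Dirichlet-form flux
  evaluates the density exactly at interval midpoints, which makes the
  functional agree with the closed form to better than $10^{-9}$ relative
  on the benchmarks.
- **Indicator convention.** A configuration exactly at a dividing surface
  belongs to state $B$ (half-open convention), applied identically in
  state probabilities, correlators, and shot outcomes.
- **Unit bridge.** 1 kcal/mol = 418.4 amu Å²/ps², stored as the exported
  constant `KCAL_PER_MOL_TO_AMU_A2_PS2`; the Langevin friction is fixed by
  the Einstein relation $\gamma = k_BT/(mD)$ (12.37 ps⁻¹ at benchmark
  parameters, velocity relaxation time $mD/k_BT = 0.08$ ps). This
  relaxation time is sometimes quoted as $k_BT/Dm$; the dimensionally
  consistent expression is $mD/k_BT$, and both evaluate to 0.08 ps at
  these parameters, so the package uses $mD/k_BT$.
- **Integrators.** Brownian dynamics uses Euler–Maruyama; $\Delta t$
  halving leaves the benchmark fluxes statistically unchanged at
  $\Delta t = 0.005$ ps. Langevin dynamics uses BAOAB splitting, chosen
  for accurate configurational sampling at strong friction. Both draw
  noise from R's seeded RNG stream, so trajectories are reproducible bit
  for bit, and the compiled kernels and the plain-R reference integrators
  (used for custom potentials and the deterministic test hooks) consume
  the identical stream.
- **Transition matrices.** Sliding-window counts are symmetrized as
  $(C + C^\top)/2$ before row normalization — the estimator assumes
  detailed balance outright; the maximum-likelihood reversible estimator
  is out of scope. Eigenproblems are solved on the
  $\pi$-symmetrized similarity transform, guaranteeing real spectra in
  floating point. The generator is estimated as $K = (T - I)/\tau$, valid
  for $\mu_2\tau \ll 1$ (true for every benchmark), avoiding matrix-log
  branch issues. Default binning is 120 uniform bins on $[-12, 12]$ Å;
  never-visited bins are dropped with an index map.
- **Model-committor cores.** The eigenfunction levels $a$ and $b$ are
  means of $\psi_2^L$ over core bins, by default bins with quadrature
  committor $< 0.05$ ($A$) or $> 0.95$ ($B$); the two-state consistency
  residuals $|a + (b-a)p_B|$ and $|1-(b-a)^2(p_Ap_B - \langle
  q(1-q)\rangle)|$ are reported.
- **Plateau detection.** The molecular time $\tau_m$ has no agreed
  formal definition. `extract_flux()` uses a sliding-window relative-stability
  criterion (default: variation $< 5\%$ across 20 points), suitable for
  clean or lightly noisy series, and fails loudly with a "no plateau"
  error when the derivative is still decaying — the broad-barrier
  indicator pathology must never be silently averaged over. For
  stochastic series whose point-wise derivative fluctuates by multiples
  of its standard error, `plateau_onset()` instead bins the derivative
  (default 1 ps) and reports the earliest bin from which the binned
  values stay statistically compatible with the limiting slope; see the
  caveat below.
- **Errors.** Block averaging over contiguous time-origin blocks
  (20 by default); independent walkers pool by averaging values and
  combining block errors in quadrature. Cross-estimator comparisons add
  errors in quadrature.
- **Chapman–Kolmogorov test.** Entries of $T(n\tau)$ and $T(\tau)^n$ are
  compared as z-scores against a multinomial scale built from *effective*
  counts $N/(\tau/\Delta t_\mathrm{store})$ — sliding-window counts reuse
  every frame $\tau/\Delta t$ times, and ignoring that overlap makes the
  test reject genuinely Markovian data. The bin width must also resolve
  the per-lag displacement (bins wider than $\sqrt{2D\tau}$ introduce
  projection memory even for Markovian dynamics); 240 bins on
  $[-12, 12]$ Å suit the Brownian benchmark at $\tau = \Delta t$.

## What the simulations show (and at what scale)

Exact references are cheap: the quadrature fluxes, relaxation times and
transit times for all three families take milliseconds. The package's test
suite runs its stochastic checks at these scales, chosen to keep each
claim's statistical power while staying lightweight:

- 1 µs of Brownian dynamics per family (the benchmark protocol length)
  for the common-slope, spectral, and histogram checks, stored every
  0.5 ps;
- an aggregate 0.5 µs of broad-barrier Langevin dynamics across five
  independent walkers for the committor-correlator flux and the
  plateau-ordering checks, stored every 0.1 ps;
- 10–20 ns at full storage resolution for Markovianity (lag scans) and
  velocity-relaxation checks.

Two analysis choices deserve emphasis. First, the *limiting-slope window*
for comparing the four correlators is 25–50 ps: beyond the slowest
molecular transient (the within-well diffusive relaxation of a few ps,
which the position correlator feels longest) yet far below
$\tau^* \geq 560$ ps. Windows starting earlier mix the $C_{zz}$ transient
into its slope. Second, the position correlator's asymptotic slope is
strictly $J_{AB} \cdot (z\cdot\psi_2^R)^2/\langle\delta z^2\rangle$, a few
percent below $J_{AB}$ when within-well fluctuations carry variance; at
benchmark statistics this sits inside the error bars, which is exactly the
sense in which the correlators "share" a slope.

## What the generator does and does not emulate

The built-in systems are genuinely 1D: there is no orthogonal-degree
relaxation, no committor-versus-coordinate mismatch, and the quadrature
committor is exact. Passing tests therefore validate the estimators and
their statistics, not the harder multidimensional questions (choice of
collective variables, hyperplane dividing surfaces, learned committors)
that real molecular data poses. Langevin runs add inertial memory below
0.08 ps — enough to demonstrate the lag-time phenomenology — but no
position-dependent friction or anharmonic thermostat coupling.

## Known limitations

- Custom potentials integrate through the plain-R reference path
  (compiled kernels cover the parametric family), so long custom-potential
  trajectories are slow.
- `plateau_onset()` trades bias for robustness: a noisier estimator has a
  wider compatibility band, which can only *advance* its reported onset.
  The plateau-ordering comparison therefore normalizes all four
  estimators to a common band (see `tests/testthat/test-acceptance.R`).
- The indicator-restricted correlator is evaluated from unconstrained
  equilibrium trajectories restricted by indicators; the
  constrained-ensemble sampler (initiating trajectories exactly on the
  $q = q^\dagger$ interface with $\dot q$ weighting) is future work.
- MSM estimation is by symmetrized counting only; no maximum-likelihood
  reversible estimator, no TICA/Galerkin bases, no coarse-graining.
- File formats are delimited text (trajectories, profiles, correlations)
  and JSON (spectral models, summaries); configs are YAML. These keep the
  toolkit dependency-light and the outputs diffable.
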
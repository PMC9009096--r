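---
title: "Nonperiodic-boundary molecular dynamics with a spherical conductor-like reaction field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{npbc-methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`npbcmd` simulates a finite droplet of rigid molecules inside a spherical
cavity of radius $R$ — nonperiodic boundary conditions (NPBC).  Instead of
periodic images, the environment beyond the droplet is represented by three
boundary terms:

1. **A stochastic "rough wall"**: any molecule whose centre of mass leaves
   the sphere has its COM velocity redrawn uniformly on the sphere (flipped
   inward when pointing outward) with magnitude equal to the Maxwell mean
   speed $\sqrt{8 k_B T/(\pi M)}$, and its angular momentum redrawn the same
   way with the equipartition r.m.s. magnitude
   $\sqrt{\sum_a I_a k_B T}$.  The wall confines and (weakly) thermalizes.
2. **A conductor-like reaction field** ($U_{RF}$): the dielectric response of
   the solvent outside the droplet, in the conductor (C-PCM/COSMO) limit —
   an excellent approximation for high-permittivity solvents such as water
   ($f(\varepsilon) = (\varepsilon-1)/\varepsilon \to 1$).
3. **A boundary mean-field potential** ($U_{vdW}$): a radial polynomial in
   the distance from the wall, tuned so the average solvent density stays
   uniform up to the boundary (it stands in for the missing short-range
   attraction of the absent outer solvent shells).

## The single-sphere COSMO reaction field

For a charge distribution $\{q_k, \mathbf r_k\}$ fully inside the cavity,
the molecular electrostatic potential on the boundary $\Gamma$ and the
apparent surface charge (ASC) $\sigma$ are both expanded in real orthonormal
spherical harmonics up to $L_{max}$.  On a single sphere the COSMO
condition (total potential vanishing on $\Gamma$) diagonalizes per $(l,m)$:

$$\sigma_{lm} = -\,f(\varepsilon)\,\frac{2l+1}{4\pi k_e R}\,\phi_{lm},
\qquad
E = \tfrac12 R^2 \sum_{lm} \sigma_{lm}\,\phi_{lm}
  = -\frac{f}{8\pi k_e} \sum_{lm} (2l+1)\, R\,\phi_{lm}^2 .$$

Two equivalent routes to $\phi_{lm}$ are implemented:

* **Quadrature** (the `ddcosmo` module surface): $\phi_{lm} = 4\pi \sum_n
  w_n \Phi(R s_n) Y_{lm}(s_n)$ on an embedded Lebedev–Laikov grid, with the
  ASC discretized into node charges $Q_n = 4\pi w_n R^2 \sigma(s_n)$.
  Forces are $q_k$ times the field of the $Q_n$, which makes energy, forces
  and $\mathrm{d}E/\mathrm{d}V$ *exactly* consistent under central finite
  differences at fixed grid — the contract the test suite pins down.
* **Spectral** (the dynamics path): $\phi_{lm} = k_e \sum_k q_k
  \frac{4\pi}{2l+1} S_{lm}(\mathbf r_k)/R^{l+1}$ with regular solid
  harmonics $S_{lm}(\mathbf r) = r^l Y_{lm}(\hat{\mathbf r})$, and forces
  from the analytic gradients $\nabla S_{lm}$ (expanded on the degree-$(l-1)$
  basis with coefficient matrices built once by exact polynomial
  differentiation).  This is smooth everywhere inside the cavity — the node
  discretization, in contrast, is singular when an atom approaches a
  quadrature node, which matters during dynamics when molecules graze the
  boundary.  Both routes agree to quadrature-aliasing accuracy for interior
  charges (tested).

The closed-form oracle used throughout is the summed Kirkwood series in the
conductor limit: a charge $q$ at offset $r$ has
$E = -k_e q^2 R / (2(R^2 - r^2))$, which the implementation reproduces to
relative $10^{-4}$ and better at $L_{max} = 16$, with monotone convergence
from above in $L_{max}$.

**Where the dielectric boundary sits.**  Placing the conductor surface at
the confining wall itself makes boundary molecules collapse onto it: each
partial charge near a conductor at contact distance is stabilized by its
image by tens to hundreds of kJ/mol, overwhelming the intermolecular
interactions (we verified this empirically; the droplet wets the shell and
the liquid structure is destroyed).  Physically the continuum stands for
*missing solvent molecules*, whose closest centres lie about one solvent
radius beyond the wall.  The driver therefore builds the reaction field on a
sphere of radius $R + \delta$ with $\delta = 1.4$ Å (a water radius) by
default; `offset` is a configuration field.  With that choice a boundary
water gains a few kJ/mol — the right order for the missing-shell
interaction — and the droplet is stable.  Atoms transiently beyond the wall
(before the rough wall re-injects their molecule) are evaluated at a
radially clamped position ($0.97\,(R+\delta)$) with only the tangential
force component transferred.

## Dynamics

Rigid molecules carry a COM position/velocity, a unit quaternion and a
lab-frame angular momentum.  One step is: half-kick, drift (COM translation
plus an implicit-midpoint quaternion update whose time derivative is
iterated to convergence $\epsilon = 10^{-9}$; the drift is substepped
adaptively so $\Delta t\,\omega \lesssim 0.1$ even for molecules spun up by
a collision), forces, half-kick, wall events, thermostat, and — for NPT —
pressure evaluation and weak-coupling scaling.  Flexible (point-particle)
systems use velocity Verlet with RATTLE projections for holonomic
constraints.

The thermostat is the stochastic velocity-rescaling (canonical sampling)
scheme: one global factor per step built from one Gaussian and one
$\chi^2_{N_f-1}$ variate, applied to velocities and angular momenta alike.
Ideal-gas tests verify the stationary kinetic-energy distribution is
$\Gamma(N_f/2)$.

Pressure uses the Clausius virial in molecular (origin-independent) form,

$$P = \frac{2E_{kin}^{trans} + \sum_{pairs}\mathbf r_{com,ij}\cdot\mathbf
F_{ij} + \sum_m \mathbf r_{com,m}\cdot(\mathbf F^{mf}_m + \mathbf
F^{RF}_m)}{3V},$$

with only the *translational* kinetic energy (rigid rotors do not
contribute ideal pressure) and **all** real forces — pair, mean-field and
reaction-field — in the virial.  This estimator was validated directly
against the mechanical wall pressure measured from rough-wall momentum
flux (logged as `P_wall`): they agree to statistical noise for LJ fluids,
vacuum water droplets and reaction-field droplets alike.  The explicit
cavity-volume derivative of the reaction-field energy,
$\partial E_{RF}/\partial V$ at fixed charges, is a *dielectric-boundary
free-energy* term that the momentum balance does not see; because the
reaction field is Coulomb-homogeneous under uniform scaling, that term is
nearly cancelled by the reaction-field force virial, and subtracting it on
top of the force virial (or instead of it) destroys the equation of state
— the droplet collapses under a modest set point.  It is therefore exposed
behind `in_pressure` as a diagnostic, off by default.  The weak-coupling
barostat
scales molecular COMs — not atoms, which would distort rigid geometry —
and the cavity radius by
$\mu = [1 - \alpha\beta\,(\Delta t/\tau_P)(P_0 - P)]^{1/3}$, clamped to
$[0.95, 1.05]$ per step; $\alpha = 1$ for the spherical box.

## The boundary mean-field potential

$U_{vdW}$ is a polynomial in the boundary distance $x = R - |\mathbf
r_{com}|$, active below `cutoff_start` and anchored to the wall so it
translates rigidly when the cavity breathes.  It is obtained adaptively:
the sphere is divided into constant-width shells (80 in the reference
protocol; fewer at desk scale where inner shells hold almost no molecules);
after each MD chunk, each shell's tabulated correction is nudged by an
increment proportional to the observed relative density deviation (capped,
so fluctuations are damped rather than chased).  The converged profile is
truncated where it first falls below 0.1 kJ/mol walking away from the wall,
split into alternating train/test halves, and fitted by ridge regression on
an orthogonal polynomial basis for each degree 0–12, with the shrinkage
optimized by a (25, 100) comma-selection evolutionary search on
$\log_{10}\lambda$ (population 100, parent/child mutation rates 0.3/0.5,
crossover 0.5, Gaussian mutation annealed by 0.99 per generation).  The
degree with the lowest test RMSE wins (ties: highest test $R^2$, then
lowest degree).  Ridge on the orthogonal basis keeps the penalty
scale-meaningful at high degree and makes $\lambda \to 0$ recover ordinary
least squares exactly.

Two fitted profiles ship with the package: the reference TIP3P-FB
coefficients (degree 10, activation 8 Å), and an SPC profile for the
8.5 Å desk-scale cavity derived with this very pipeline (degree 4,
activation 5.75 Å; repulsive $+4.2$ kJ/mol at the wall, a $-1.2$ kJ/mol
well near 1.9 Å).  A desk-scale droplet of ~86 molecules cannot constrain
the profile in the inner shells — their volume holds at most a molecule or
two — so the derived profile is meaningful only in the boundary region the
truncation keeps, and its purpose (density flattening) rather than any
structural observable was the acceptance criterion during derivation.

## Trajectory analysis

* `rdf_npbc` restricts central atoms to an inner selection sphere so
  neighbor shells never cross the boundary, and normalizes by the droplet's
  global number density; `hwhm_first_peak` refines the peak position
  parabolically and measures the half width at half maximum, by default on
  the falling (outer) flank — the literal reading of "where g first falls
  to half the peak height" — with the rising flank available via
  `side = "left"`.  The baseline is the minimum of $g$ left of the peak
  (zero for a first peak rising from the excluded-volume region).
* `shell_density` uses equal-volume shells $r_i = R\,(i/n)^{1/3}$ and
  molecule-COM membership, so a molecule is never split across shells.
* `f_hb` scores donor–H⋯acceptor pairs by a product of logistic switches in
  the H⋯acceptor distance and the donor–H–acceptor angle, each in $[0,1]$.
  The defaults ($r_0 = 2.5$ Å, $a = 10$ Å$^{-1}$, $\theta_0 = 140^\circ$,
  $b = 0.1\,$deg$^{-1}$) are the package's own choices of a continuous
  hydrogen-bond measure: well-formed bonds score near 1, the continuum
  between integer counts stays populated.  With $b = 0.1$ the angular
  switch at $180^\circ$ reaches 0.982, not 1; sharper switches saturate
  fully.  All four parameters are configurable.

## Snapshot selection

Frame features are the first and second smallest distances from each solute
site to each solvent atom type (12 features for 3 sites × 2 types).
Features share units (Å), so the PCA projection is centered but not scaled;
the retained dimension is the smallest whose cumulative explained-variance
ratio exceeds 0.9.  Clustering is classic PAM (greedy BUILD, then
best-improvement SWAP passes; ties resolve to the lowest index, making the
pipeline deterministic).  The cluster count is chosen by consensus of four
internal criteria over $k = 2..20$: Silhouette, Dunn and Calinski–Harabasz
at their maxima, and the within-sum-of-squares elbow at the largest discrete
second difference; at least three agreeing votes are required, otherwise
the most-voted (smallest on ties) $k$ is returned with a flag.

Representative frames are selected per cluster by GRASP, maximizing the
density-weighted total dissimilarity
$DS(F) = \sum_{i<j\in F} w_i w_j\, d(i,j)$ with
$w_i \propto 1/\sqrt{\hat\rho_i}$ from a 10-NN density proxy (the square
root tempers extreme sparsity), so both dense and sparse regions are
covered.  The construction phase samples from the restricted candidate list;
taken literally, the band
$[DS_{min},\, DS_{min} + \alpha(DS_{max}-DS_{min})]$ collects the *least*
dissimilar candidates, which cannot serve an objective that maximizes
dissimilarity — the implementation therefore uses the top band
$[DS_{max} - \alpha(DS_{max}-DS_{min}),\, DS_{max}]$ by default and keeps
the literal band behind `literal_rcl = TRUE`.  Local search swaps each
member against its nearest neighbors up to 5% of the data set (floored at
five neighbors so small clusters still get a meaningful search); the best
of 100 restarts is kept.  Budgets across clusters follow largest-remainder
proportional allocation, and each cluster's medoid is always included.

## Synthetic data and what passing tests show

`build_water_sphere` places $N = \mathrm{round}(\rho V / m)$ rigid waters
on a jittered lattice clipped to the sphere, with random orientations, and
relaxes them by rigid-body steepest descent; it is a pure function of
(spec, seed).  `synth_feature_trajectory` draws labelled Gaussian-mixture
feature matrices.  These generators emulate the *statistical* structure the
pipeline consumes (liquid-like packing at a target density; well-separated
basins in feature space).  They do not emulate slow collective dynamics,
conformational kinetics, or real solute–solvent chemistry, so passing
clustering tests demonstrates correct algorithmic behaviour on planted
structure, not discovery performance on hard, overlapping basins.

## Problem sizes and numerical choices

Reference-scale simulations (nanoseconds, 20 Å spheres) are out of desk
range; the package works at the 8.5 Å / 86-water scale with 100–220 ps
trajectories, which resolves boundary structure and barostat stationarity
but leaves statistical error of a few hundredths of an Å on peak-shape
observables.  Other fixed choices: Lebedev grids are embedded constants for
sizes 6–302 (verified in-suite by the quadrature-orthonormality Gram
identity up to each rule's precision); $L_{max} = 10$ and the 302-point
grid are defaults, not claims about the reference implementation;
quaternion convergence $10^{-9}$; RATTLE tolerance $10^{-10}$; overlapping
atoms (below $10^{-6}$ Å) are an error; an NaN anywhere aborts the run
with its step index; every stochastic component draws from R's RNG so a
single seed reproduces a whole trajectory bit for bit.

## Known limitations

* The conductor limit overestimates the response of low-permittivity
  solvents; the scaled mode $f(\varepsilon)$ is available but untested
  against solvent-specific data.
* The reaction-field offset $\delta$ is a physically motivated default, not
  a fitted parameter; observables of boundary-layer structure depend on it.
* At desk scale the vacuum-boundary droplet develops a partially depleted
  outer shell; the first-peak height reproduces the overstructuring
  signature of a vacuum boundary, but its width is broadened by surface
  disorder relative to reference-scale simulations.
* No electrostatic cutoff is used (exact all-pairs sums); cost grows
  quadratically with atom count, which is fine for droplets up to a few
  thousand atoms and no further.
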
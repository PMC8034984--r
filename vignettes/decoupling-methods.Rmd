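---
title: "Rigid-body coherent ISFs and the translation-rotation decoupling approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body coherent ISFs and the translation-rotation decoupling approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidISF)
```

## The problem

Neutron Spin Echo (NSE) measures the normalized coherent intermediate
scattering function (ISF) of proteins in solution, $I(Q,t)/I(Q,0)$, over
$Q \approx 0.01\text{--}0.2\ \mathrm{\AA^{-1}}$ and correlation times from
picoseconds to hundreds of nanoseconds. For a single rigid particle the
signal mixes centre-of-mass translation and rotation; for flexible
proteins it additionally contains internal motion, which is usually the
quantity of interest. The standard way to isolate the internal part is to
subtract a *rigid-body reference*, computed under the assumption that
translation and rotation are statistically independent:

$$\frac{I(Q,t)}{I(Q,0)} \approx I_{com}(Q,t)\, I_{rot}(Q,t),
\qquad D_{total}(Q) \approx D_{com} + D_{rot}(Q),$$

or, in the structure-weighted variant,

$$D_{total}(Q) \approx D_{trans}(Q) + D_{rot}(Q), \qquad
D_{trans}(Q) = \frac{\langle |F(Q\hat{Q})|^2\,
(\hat{Q}\cdot D_{tt}\cdot \hat{Q})\rangle_{\hat{Q}}}{P(Q)}.$$

For an anisotropic particle such as a Y-shaped monoclonal antibody (mAb,
~10 nm across) these factorizations are approximations: the body-frame
mobility is anisotropic, so lab-frame translational increments correlate
with the orientation history. Because internal-motion signals are
themselves only ~10% of $D_{eff}(Q)$, a percent-level error in the
rigid-body reference matters. This package simulates rigid coarse-grained
protein models, computes the exact coherent ISFs and their decomposition
from the trajectories, and quantifies the decoupling error.

## Observables

All ISFs are computed from the orientationally averaged pair sum with the
spherical kernel,

$$I(Q,t) = \Big\langle \sum_{m,n} b_m b_n\,
\frac{\sin(Q\,r_{mn}(t_0,t))}{Q\,r_{mn}(t_0,t)} \Big\rangle_{t_0},
\qquad r_{mn}(t_0,t) = |\vec r_m(t_0) - \vec r_n(t_0+t)|,$$

normalized by the lag-0 value. The four components differ only in which
part of the motion enters $r_{mn}$: full motion (`isf_total`), centre of
mass only (`isf_com`), the COM-removed bead cloud (`isf_rot`; for a rigid
body this is the intra-particle ISF), and the frozen-orientation
structure-weighted translation (`isf_trans_weighted`), in which the bead
cloud keeps its orientation at the time origin while the COM moves. A
single time origin gives a very noisy estimate for trajectories of
realistic length, so the sum is averaged over strided origins; the
origin-to-origin spread of a short trajectory is the single-run analogue
of the trajectory-to-trajectory spread discussed below.

Short-time effective diffusion coefficients are extracted per $Q$ as
$D_{eff}(Q) = -\mathrm{slope}\big[\ln I(Q,t)\big]/Q^2$ over a fit window
(`extract_deff`); $D_{trans}(Q)$ is additionally available as a
deterministic spherical quadrature over $\hat Q$ (`dtrans_theoretical`),
Gauss–Legendre in $\cos\theta$ times a uniform azimuthal grid, with a
mandatory order-doubling convergence check (relative tolerance $10^{-3}$,
error if not converged by order 256). The two $D_{trans}$ routes — the
trajectory estimator and the quadrature — are compared against each other
in the test suite; agreement on an anisotropic rod is within the
trajectory's statistical error.

## Engines

**DPD.** The reference engine is a dissipative particle dynamics fluid
with the rigid body embedded as frozen interaction sites of the same type
as the fluid. Pairwise forces are the standard soft conservative
repulsion $a(1-r/r_c)\hat r$, the dissipative force
$-\gamma \omega_R^2(r) (\hat r\cdot \vec v_{ij})\hat r$ and the random
force $\sigma \omega_R(r)\xi \hat r/\sqrt{dt}$, with
$\sigma^2 = 2\gamma k_BT$ and $\omega_R = 1 - r/r_c$ (the
fluctuation–dissipation pairing is enforced by construction, not
configurable). Parameters default to the water-compressibility
convention: $a = 25\,k_BT/r_c$, $\rho = 3$, $\gamma = 4.5$, $dt = 0.01$,
$k_BT = 1$, integrated with the modified velocity-Verlet scheme
($\lambda = 0.5$). The rigid body is advanced as one unit: net force and
torque about the COM drive the COM velocity and the angular momentum;
the orientation quaternion is renormalized each step. The desk-scale
default box is small (a few body diameters); the production-scale
configuration of the study type (box ~6 diameters, ~200 ns-equivalent,
three replicates) uses the identical code path and is simply a matter of
`n_steps` and `box`.

**Brownian surrogate.** Because DPD hydrodynamics is expensive, the
analysis pipeline is exercised with an overdamped rigid-body Brownian
propagator (`run_bd`): each step draws a 6-vector Gaussian displacement
with covariance $2 D\, dt$ in the *body frame* (translation+rotation,
including the coupling block when present), maps the translation to the
lab frame through the current orientation, and composes the rotation via
the quaternion exponential map. Keeping $D$ fixed in the body frame is
exactly the mechanism that makes $D_{com}$, $D_{trans}(Q)$ and
$D_{total}(Q)$ differ. The overdamped limit is appropriate because
centre-of-mass motion is diffusive above the momentum relaxation time,
which is orders of magnitude below the NSE window. The rotational step
RMS must stay below 0.2 rad (enforced) for the exponential-map update to
be accurate.

**Inertial Langevin.** A free point particle with exact
Ornstein–Uhlenbeck velocity updates (`run_langevin_point`) exercises the
ballistic-to-diffusive crossover. Its MSD is

$$\langle r^2(t)\rangle = \tau_B^2\big(1-e^{-t/\tau_B}\big)^2
\Big(\nu_0^2 - \frac{3k_BT}{m}\Big)
+ \frac{6k_BT}{\gamma}\Big[t - \tau_B\big(1-e^{-t/\tau_B}\big)\Big],$$

with $\tau_B = m/\gamma$; we re-derived this 3D form from the velocity
Ornstein-Uhlenbeck process (the per-dimension noise amplitude is
$g = 2\gamma k_BT$) and unit-tested its ballistic ($\nu_0^2 t^2$) and
diffusive ($6 k_BT t/\gamma$) limits against simulation before using it
in `fit_langevin_msd`. On multi-origin MSDs the free three-parameter fit
is weakly identified (the equilibrium curve constrains only $\gamma$ and
$\tau_B$, and correlated MSD points let $\nu_0$ trade against $\tau_B$),
so the fit weights relative residuals, defaults to windows covering the
crossover, and accepts a known mass to pin $\gamma = m/\tau_B$. A purely
diffusive input has no resolvable $\tau_B$: the fit aborts or returns a
flagged degenerate result.

## The diffusion tensor

The Brownian surrogate needs a body-frame 6x6 diffusion tensor. The
default (`estimate_diffusion_tensor(..., method = "rpy")`) is rigid-body
bead-model hydrodynamics: the full $3N \times 3N$ Rotne–Prager–Yamakawa
pair mobility matrix is inverted to a friction matrix and projected onto
rigid translations and rotations, giving consistent `tt`, `rr` and
coupling blocks; a per-bead spin resistance $8\pi\eta a^3$ (equivalently,
the bead-volume correction) keeps degenerate geometries non-singular.
The classic Kirkwood double sum with free-draining rotation is retained
as `method = "kirkwood"`, but we found its rotational block under-predicts
$D_r$ of a compact ~50 Å body by roughly a factor of five relative to the
Stokes–Einstein–Debye scale (checked on a spherical shell against
$k_BT/8\pi\eta R^3$), which suppresses every rotation-related observable;
it is therefore not the default. The bead hydrodynamic radius defaults to
4.5 Å, a typical residue-bead value. The `D0` argument rescales the whole
tensor so that $\mathrm{tr}(tt)/3$ matches a stated free diffusion
coefficient — 3.7 Å²/ns is the accepted value for an antibody in a
D2O-based buffer — which maps the model to physical units without
changing its anisotropy. All analysis is otherwise unit-agnostic in the
reduced variables $D_0 Q^2 t$ and $t/\tau_c$.

## Synthetic models

`make_synthetic_mab()` emulates the coarse structure of an IgG: three
spherical lobes (two Fab, one Fc; default radii 23, 23, 26 Å) whose
centres sit at 30 Å from a hinge, the Fab arms opened 115°, beads placed
quasi-uniformly inside each lobe with a seeded RNG. The defaults give an
overall diameter of ~100 Å (10 nm) and a planar, mildly anisotropic
body — translational eigenvalues spread about ±6% around their mean.
What it reproduces of real data: the size, the Y topology, and
shape-coupled anisotropic mobility. What it does not: the true residue-
level mass distribution, the inter-domain linker geometry, and the
stronger mobility anisotropy a real mAb may have — so passing tests bound
the *mechanism*, not the exact magnitude, of the decoupling error in
experiments. `make_spherical_shell()` (Fibonacci lattice) is the isotropic
null: its coherent rotational ISF must not decay, all its ISFs collapse
onto $\exp(-D_0Q^2t)$, and both decoupling errors must vanish.

`coarse_grain_pdb()` builds the same kind of model from a real structure,
one bead per amino-acid residue (heavy-atom centroid by default, CA
optional), unit scattering lengths and equal masses per residue.

## Study conditions and problem sizes

The packaged study (`run_study`, and the acceptance script) uses: the
synthetic mAb with 50 beads per lobe (150 beads; ISF cost is quadratic in
beads and the decoupling observables were checked stable against the bead
count on small fixtures), the RPY tensor rescaled to $D_0 = 3.7$ Å²/ns,
three independent seeds, $dt = 1$ ns, $5\times 10^4$ steps per seed
(~120 $\tau_c$, so statistical errors on $D_{eff}$ are ~1%), the NSE grid
$Q \in \{0.05, 0.1, 0.15, 0.2\}$ Å⁻¹ plus 0.01 Å⁻¹ as the $D_0$
reference, time origins every 20 frames, and a Deff fit window of
[2, 10] ns — comfortably above any momentum relaxation scale and at
$t/\tau_c \lesssim 0.025$ where replicate curves still agree.

With these conditions the surrogate reproduces the *structure* of the
published comparison: the com+rot sum overestimates the directly measured
$D_{total}(Q)$ where the effect is resolved, with the largest relative
errors at a few percent and the structure-weighted (trans+rot) variant
several times more accurate at small and intermediate $Q$;
$|D_{trans}(Q) - D_0|/D_0$ peaks within a factor ~1.1 of $Q = 2\pi/\sigma$.
The magnitudes are smaller than the ~10% / ~4% maxima reported for the
NISTmAb rigid-body reference — our three-sphere Y is hydrodynamically
milder than the real antibody — so these numbers should be read as
bounds consistent with the published ones, not reproductions of them.
One genuine difference: at $Q \approx 0.15$ Å⁻¹ the surrogate's com+rot
error changes sign (a reproducible property of this shape across seeds),
whereas the published mAb analysis reports an overestimate throughout;
the sign of the coupling correction is shape-dependent and this is
documented rather than suppressed.

## Reproducibility window

A finite trajectory samples Brownian motion incompletely: replicate runs
of the same system agree at small lag and drift apart as the lag becomes
a finite fraction of the run. `reproducibility_onset()` measures, per
$Q$, the earliest lag at which the across-seed spread of the normalized
ISF exceeds a threshold, reported in $t/\tau_c$ with
$\tau_c = \sigma^2/6D_0$ (the time to diffuse one diameter; for a 10 nm
mAb at 3.7 Å²/ns, ~450 ns). For runs of ~0.5 $\tau_c$ — the scale of a
long all-atom or DPD simulation — the onset lands at small $t/\tau_c$
(order $10^{-2}$ at the packaged test scale with a 0.02 band), which is
why the Deff fit window must sit well inside the early-lag region. The
onset is measured and reported, not asserted to match any particular
published value.

## Numerical choices and edge cases

* ISF normalization divides by the lag-0 value of the same origin set;
  lag 0 is therefore exactly 1 by construction.
* Lags beyond the trajectory are dropped with a warning; an empty origin
  set is an error.
* `extract_deff` refuses non-positive ISF values in the window (log
  domain) and windows with fewer than 3 lag points.
* The Debye sum and the pair-sum kernel treat $Qr < 10^{-12}$ as 1
  (the sinc limit), so $Q = 0$ and coincident beads are exact.
* In DPD, exactly coincident pair centres get a deterministic fallback
  direction and are counted and reported; fluid velocities above a cap
  abort the run with the step index.
* Pivoted Cholesky of $2D\,dt$ supports semi-definite tensors (pure
  translation or pure rotation) in the Brownian propagator.
* Ties and non-identifiabilities in the Langevin fit surface as errors or
  a `degenerate` flag, never as silently wrong parameters.

## Limitations

The DPD engine is desk-scaled by default; mapping DPD time to physical
time is metadata (via a measured $D_0$), not asserted. The bead-model
tensor is an approximation (no lubrication, overlapping-bead RPY); the
decoupling magnitudes depend on the model shape, and the synthetic Y is a
conservative stand-in for a real antibody. Incoherent ISFs, instrument
resolution, inter-protein correlations and internal flexibility are out
of scope.

## A minimal session

```{r example, eval = FALSE}
mab <- make_synthetic_mab(beads_per_lobe = 50)
D   <- estimate_diffusion_tensor(mab, D0 = 3.7)
res <- run_study(study_config(
  model = list(type = "synthetic_mab", beads_per_lobe = 50),
  seeds = c(101, 202, 303), n_steps = 50000,
  lags = c(0, 2, 4, 6, 8, 10), origin_stride = 20,
  out_dir = "mab_study"))
res$report
```
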
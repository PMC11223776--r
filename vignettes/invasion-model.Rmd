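---
title: "Modeling breast cancer invasion into adipose tissue with deformable particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling breast cancer invasion into adipose tissue with deformable particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`adipoinvade` simulates a mixture of two cell types with the discrete element
method, in reduced units where the repulsive energy scale $\epsilon_c$, the
mean cancer-cell diameter $\sigma$, and the particle mass $m$ are all 1 (time
is in units of $\sqrt{m\sigma^2/\epsilon_c}$).

**Adipocytes** are three-dimensional deformable particles: closed triangulated
surfaces with $N_v = 42$ vertices and $N_f = 80$ faces (a once-subdivided
icosahedron, the unique standard triangulation with those counts). The shape
energy of adipocyte $i$ is

$$U_i = \frac{\epsilon_v}{2}\Big(1 - \frac{v_i}{v_{i0}}\Big)^2 +
\frac{\epsilon_a}{2}\sum_{k=1}^{N_f}\Big(1 - \frac{a_{ik}}{a_{ik0}}\Big)^2,$$

a harmonic penalty on the enclosed volume $v_i$ and on every triangular face
area $a_{ik}$ about preferred values. Surfaces of this kind without bending
energy are floppy: at a zero-energy reference the dynamical matrix has
$(3N_v - 6) - (N_f + 1) = 39$ non-rigid-body zero modes, so an adipocyte can
change shape at no energy cost while holding its volume and face areas. The
package verifies this spectrally (`shape_hessian()`, `count_zero_modes()`).
Asphericity is measured by the shape parameter
$\mathcal{A} = (\sum_k a_{ik})^{3/2}/(6\sqrt{\pi}\,v_i)$, 1 for a sphere. The
reference shape parameter defaults to $\mathcal{A}_0 = 1.1$, the typical
adipocyte value.

**Cancer cells** are soft spheres, bidisperse (half $0.9\sigma$, half
$1.1\sigma$ to frustrate crystallization), with purely repulsive linear-spring
contacts against adipocyte vertices and a cohesive-repulsive law among
themselves: the repulsive spring continues through contact into an attractive
branch reaching its maximum attractive force $\epsilon_c\beta/\sigma_{qs}$ at
separation $(1+\beta)\sigma_{qs}$ and returning linearly to zero at
$(1+\alpha)\sigma_{qs}$. The attraction range is fixed at $\alpha = 0.2$; the
depth $\beta$ (studied over $10^{-4}$–$10^{-2}$) models cell–cell cohesion.

**Motility.** In the active model each cancer cell carries a self-propulsion
force $f_0\hat{n}_q$ whose direction diffuses rotationally with persistence
time $\tau_p$ (the direction autocorrelation decays as $e^{-t/\tau_p}$). In
the passive model ($\tau_p = 0$ in configurations) the cells instead receive
Langevin noise at a target temperature $T_0$. All species — cancer cells,
adipocyte vertices, and the mobile wall — are damped with the same coefficient
$\gamma$ (default 0.2; 20 for overdamped studies).

**Boundary conditions.** The box is periodic in $y$ and $z$. In $x$ it is
bounded by a static right wall and a mobile left wall with equation of motion
$m\ddot{x}_l = F_{\mathrm{particles}} + P L_y L_z - \gamma v_l$, which imposes
a constant pressure $P$ (default $1.3\times 10^{-3}$). Wall–particle
repulsion activates when a centre comes within one particle diameter of the
wall plane.

# Initialization: the synthetic study conditions

Every study starts from a dilute ($\phi = 0.01$), de-mixed configuration:
cancer cells in a low-$x$ band and randomly oriented adipocytes in a
high-$x$ band (the bands are the fractions $[2,12]/70$ and $[16,68]/70$ of the
box length), with a smooth planar interface between the phases. Athermal
quasistatic compression — repeated 3% relative increases of the packing
fraction, each followed by FIRE energy minimization to a force residual of
$10^{-8}\epsilon_c/\sigma$ — produces a jammed packing at total
$\phi = 0.72$. The last compression step is truncated so the protocol lands on
the target exactly. The packing fraction counts cancer spheres plus adipocyte
volumes $V_i$ (mesh volume plus the protruding halves of the vertex spheres —
an approximation that affects only this bookkeeping, since the vertices sit on
the surface).

This generator *is* the study condition: it emulates a sharp tumor–adipose
interface at tissue-like confluence. It does not emulate polydisperse
adipocytes, pre-existing interstitial collagen geometry, or cell
division/apoptosis, so passing tests say nothing about those features of real
tissue.

ECM constraint is modeled by harmonic tethers between adipocyte centres of
mass, $U = \frac{K_{ecm}}{2}(R_{ij} - l^0_{ij})^2$, shared equally by the
$N_v$ vertices of each tethered adipocyte. The neighbour threshold $d_c$ is
calibrated as the smallest value giving a mean degree of at least 6, and rest
lengths are frozen at the current separations. Spatial heterogeneity with
amplitude $\lambda$ contracts the rest lengths of springs inside the low-$z$
half to $(1-\lambda)R_{ij}$ and dilates the high-$z$ half to
$(1+\lambda)R_{ij}$; springs crossing the two groups keep $R_{ij}$ (a choice —
the symmetric alternative coincides with it for this split).

# Observables

The degree of invasion is the interfacial area $A_t$: a radical (Laguerre)
tessellation is built with cancer centres and adipocyte vertex centres as
seeds, weighted by their radii (the seeds are strongly polydisperse, which is
why the radical flavor is the default; the unweighted tessellation is
available behind a flag). $A_t$ sums the areas of Voronoi faces between a
cancer seed and an adipocyte seed plus, by default, cancer faces on the wall
planes. The normalization

$$A_n = \frac{A_t - A_t^{min}}{A_t^{max} - A_t^{min}} \in [0, 1]$$

takes $A_t^{min}$ from the de-mixed reference frame, rescaled to the
instantaneous transverse cross-section, and $A_t^{max}$ as the instantaneous
total adipocyte Voronoi surface area — both recomputed per frame so that the
dilation of the box at high activity does not masquerade as mixing. Small
numerical excursions outside $[0,1]$ are clamped.

Velocity statistics use the per-origin-normalized autocorrelation
$C_{vv}(t) = \langle v_q(t')\cdot v_q(t'+t)/v_q^2(t')\rangle_{q,t'}$ and the
decorrelation time $\tau_d$ at which it first crosses $e^{-1}$. For free
active particles $C_{vv}$ has the closed form
$(\tau_\gamma e^{-t/\tau_\gamma} - \tau_p e^{-t/\tau_p})/(\tau_\gamma-\tau_p)$
with $\tau_\gamma = m/\gamma$, which the integrator reproduces; this is the
package's main dynamical cross-check.

Steady-state sweeps of $A_n$ against the measured $k_bT/(P\sigma^3)$ are
sigmoidal and are fitted by
$A_n = \frac{1}{2}(\tanh[b\,\log_{10}(k_bT/(aP\sigma^3))] + 1)$. The midpoint
$a$ defines the dimensionless energy scale $E_c = k_bT/(aP\sigma^3)$: curves
from different cohesion/persistence/damping conditions overlay when plotted
against $E_c^b$, with $E_c > 1$ predicting invasion. Across conditions the
midpoint follows $a = c_1(1 + c_2\,\beta\epsilon_c/(P\sigma^3))\,
\tau_\gamma/\tau_d$, fitted linearly after dividing by $\tau_\gamma/\tau_d$.

# Numerical choices

* **Integrator.** Velocity Verlet with a BAOAB splitting: conservative and
  active forces enter the half kicks; damping (and passive thermal noise) is
  applied through the exact Ornstein–Uhlenbeck velocity map mid-step. The
  scheme is symplectic when damping vanishes (energy drift $<10^{-4}$
  relative over $10^4$ steps in tests), reproduces the target temperature of
  the passive thermostat to within a fraction of a percent at the default
  step $\Delta t = 0.05$, and remains stable for $\gamma$ up to 20 because
  the velocity decay is exact rather than discretized.
* **Kinetic temperature** is $k_bT = \frac{m}{3N}\sum_q v_q^2$ (two-thirds of
  the mean kinetic energy per particle), the definition under which the
  passive thermostat and Maxwell-statistics checks close consistently.
* **Activity as the knob.** $f_0$ is the configuration variable; $k_bT$ is
  always a *measured* output. In dense packings the measured temperature sits
  well below the dilute calibration because of caging, so operating points
  are located by measuring, not by the free-particle map
  (`calibrate_activity()` provides the dilute reference).
* **Reference-shape calibration.** $\mathcal{A}_0$ is imposed by scaling all
  preferred face areas by a single factor, preserving the isotropy of the
  reference. The perfectly symmetric icosphere is then a strained *critical
  point* of the energy: radial forces cannot break its symmetry, and at that
  configuration the volume gradient is linearly dependent on the area
  gradients. `relax_shape()` therefore jiggles the vertices (sd
  $10^{-2}\sigma$) before minimizing, which lands on the generic buckled
  zero-energy reference where the 39-mode count is clean (spectral gap
  $\sim 10^{10}$).
* **Minimizer.** FIRE with standard parameters; force tolerance
  $10^{-8}\epsilon_c/\sigma$ for protocols, $10^{-6}$ in scaled-down test
  fixtures.
* **Stiffnesses.** $\epsilon_v = 10^3\epsilon_c$ keeps volume fluctuations
  negligible; $\epsilon_a = 10\epsilon_c$ keeps area fluctuations small while
  leaving the surface floppy. Vertex diameters are $2\sigma$, about twice the
  mean cancer diameter, so vertices tile the surface against
  interpenetration; with mesh radius $2\sigma$ the adipocyte is
  $\approx 6$ cancer diameters wide.
* **Tether image offsets.** Each spring stores its periodic image offset at
  build time, so rest lengths longer than half a (small) box remain well
  defined; re-imaging every step would snap long springs to the wrong image.
* **Degenerate inputs.** Coincident pair centres yield a zero force with a
  warning rather than NaNs; coincident tessellation seeds are jittered by
  $10^{-9}\sigma$ with a warning; a tessellation whose tolerance cannot
  separate the zero-mode spectral gap reports the ambiguity instead of
  guessing.
* **Randomness.** All noise flows from R's global RNG, seeded once per run;
  the compiled loop evaluates in a fixed order, so traces are bit-reproducible
  given the seed.

# Problem sizes and what the tests show

Full-scale campaigns (thousands of cells, $10^7$ steps) are research runs.
The package's own test suite works at sizes chosen to exercise every code
path with stable statistics: jammed packings with $N_a = 4$–$8$ adipocytes
and $N_c = 100$–$300$ cancer cells, invasion horizons of 1500–2500 time
units, and dilute ensembles of a few hundred free cells for velocity
statistics. At these sizes the monotone responses to activity, cohesion,
tethering and packing fraction, and the energy-scale overlay, are robust,
but plateau values carry finite-size noise of a few percent. The
heterogeneity ($\lambda$) response is the exception: with only a handful of
adipocytes per $z$-group in a periodic cross-section about two adipocytes
wide, contracting the tight group's rest lengths opens system-spanning voids
that cancer cells flood, so the degree of invasion *increases* with
$\lambda$ at these sizes — the opposite of the wide-slab behaviour, where
tight regions close interstitial gaps below the cancer-cell diameter. The
local packing spread $\Delta\phi_a$ does grow with $\lambda$ once
$N_a \gtrsim 16$ (from $\approx 0.10$ to $\approx 0.15$ between $\lambda = 0$
and 1). The heterogeneity checks in the test suite document this scale
limitation rather than hide it.

# Known limitations

* **Species temperature ratio.** With damping $-\gamma v$ on every adipocyte
  vertex and activity or noise injected only into cancer cells, the
  stationary adipocyte temperature is set by the balance of collisional
  heating against damping. At the default pressure, contacts are shallow and
  intermittent (collision rates per vertex are well below $\gamma$), so the
  measured cancer/adipocyte temperature ratio is of order 10–40 rather than
  slightly above 1. A near-unity ratio would require either a shared thermal
  bath acting on all species or much weaker vertex damping; neither is part
  of these equations of motion, and the acceptance suite reports the ratio
  as measured.
* The tessellation bounds $A_t^{min}$ and $A_t^{max}$ are geometry dependent;
  at reduced $N$ the de-mixed interface of a dilute box is dominated by
  tessellation roughness, so only the jammed reference frame is meaningful
  for normalization.
* Tethers never break, adipocytes neither shrink nor divide, and cancer
  cells are non-deformable spheres; glassy relaxation-time analysis is out of
  scope.

# A minimal run

```{r example}
library(adipoinvade)
set.seed(1)
st <- place_demixed(init_config(N_a = 8, N_c = 300))
st <- compress_to_phi(st, target_phi = 0.72)
packing_fractions(st)

pp <- sim_params(model = "active", f0 = 0.015, taup = 25, beta = 1e-2)
run <- run_invasion(st, pp, horizon = 2500, cadence = 250)
tail(run$trace[, c("time", "A_t", "A_n", "kT_c", "L_x", "P_wall")])
```
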
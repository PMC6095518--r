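---
title: "Mechanochemical phase-field simulation of phyllotaxis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical phase-field simulation of phyllotaxis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllodome)
```

## The model

phyllodome simulates organ placement (phyllotaxis) on a growing shoot apical
meristem (SAM) as the interplay of two coupled processes on a regular 3D
grid:

**The mechanical part** represents the tissue as a phase field $\phi$,
taking the value $+1$ inside the tissue and $-1$ outside, with a thin
diffuse interface at $\phi = 0$ standing in for the tissue surface. Its
free energy is a spontaneous-curvature (Canham–Helfrich-type) functional

$$F = \int \left( \Phi_{SC}^2[\phi]
  - \tfrac{1}{2}\varrho_\phi |\nabla\phi|^2
  - \tfrac{1}{2}\varrho_u |\nabla u|^2 \right) dV, \qquad
\Phi_{SC} = -\phi + \phi^3 - \epsilon^2\nabla^2\phi
  - \epsilon\, C_0[u]\,(\phi^2 - 1),$$

where the spontaneous curvature $C_0 = \beta u^2$ couples the auxin-like
morphogen $u$ to the preferred curvature of the surface: where auxin
accumulates, the surface prefers to bend, and a primordium can bulge out.
The factor $(\phi^2 - 1)$ confines this coupling to the interface. The
phase field evolves by conserved (Cahn–Hilliard) dynamics driven by
$\delta F/\delta\phi$, plus two growth sources: a mass term $m u^2$
(auxin-promoted growth) and a Gaussian tip source $\kappa m G$ that
produces the SAM's characteristic tip growth. The morphogen is transported
with a *tensorial* mobility $\gamma\sigma_{\alpha\beta}$ — the symmetrized
stress tensor of the phase field — so the stress field orients auxin flux,
the continuum abstraction of stress-aligned microtubules orienting PIN1
carriers.

**The chemical part** is the two-morphogen BVAM reaction–diffusion system

$$\partial_t u = D\nabla^2 u + \eta(u + a v - c\,uv - uv^2), \qquad
  \partial_t v = \nabla^2 v + \eta(b v + h u + c\,uv + uv^2),$$

with kinetic constants $a = 1.1123$, $b = -1.0122$, $h = -1$, diffusivity
ratio $D = 0.516$. It undergoes a Turing instability whose fastest-growing
wavenumber scales as $k_c^2 \propto \eta$, so $\eta$ acts as a domain-size
surrogate and is the pattern-symmetry selector. $c \in [0, 0.57]$
interpolates between stripe-forming ($c = 0$, the ribbed/cactus regime)
and spot-forming kinetics.

The two parts run on separated time scales: chemical steps at
$dt_1 = 5\times 10^{-2}$ and mechanical steps at $dt_2 = 1\times 10^{-5}$,
a factor of 5000, reflecting that shape change is much slower than
reaction–diffusion.

## Where the chemistry lives

The model statement imposes zero-flux boundary conditions on the moving
surface $\phi = 0$. A boundary condition on an implicit moving surface has
no unique grid realization, and the choice matters, so the package makes it
explicit and configurable (`chem_domain`):

* `"box"` — unmasked reaction–diffusion in the whole box. The resulting 3D
  spot lattice fills the volume on both sides of the interface and its
  surface trace has essentially arbitrary symmetry: the azimuthal fold
  counts do not track the $\eta$-based mode selection.
* `"tissue"` — diffuse-domain confinement to the tissue interior
  ($\chi = (1+\phi)/2$ multiplying both fluxes and kinetics, in
  conservative face-flux form). A solid ball/cylinder selects its interior
  (spherical-Bessel) Neumann modes, which again disagree with the
  surface-harmonic mode selection that the linear-stability analysis
  ([predict_sphere_mode()]) predicts and that the reported whorl
  symmetries follow.
* `"shell"` (default) — confinement to a thin shell around the surface of
  the meristematic dome. On a (hemi)spherical shell of radius $R$ the
  Laplace–Beltrami spectrum is $l(l+1)/R^2$, so the fastest-growing degree
  is $l \approx$ the value selected by the spherical-harmonic analysis,
  and the sectoral modes put $l$ maxima around the dome base — which is
  where whorls are observed to emerge. This is the reading consistent with
  the model's own mode-selection machinery, and it is the default.

Two technical details of the shell mask. First, its width is fixed in
*physical* distance (`chem_shell_width`, default 3 grid units): the evolving
free energy favours steep phase-field gradients (the tension terms enter
with negative sign) and slowly compresses the interface profile, so a mask
defined through $\phi$ values alone would starve the chemistry over time.
The mask therefore estimates the signed distance to the surface from the
local profile, $d = \mathrm{atanh}(\phi)(1-\phi^2)/|\nabla\phi|$, and uses
$\mathrm{sech}^2(d/\sqrt{2}w)$. Second, the shell is weighted by a smooth
sigmoid in height that switches off below the cylinder–cap junction
(tracking the summit as the dome grows): the patterning tissue is the
meristematic dome itself, while the supporting stem below it is chemically
inert. Without this, the open cylindrical flank adds perimeter modes with
one extra azimuthal repeat relative to the spherical-cap spectrum and the
fold counts lose their correspondence with $\eta$.

## Numerical scheme

Space: second-order central/7-point finite differences on a uniform grid
($dx = 1$, $40\times40\times60$ voxels by default), homogeneous Neumann
closure by ghost-cell mirroring on the box faces. Anisotropic and masked
fluxes are discretized in conservative face-flux form, which reduces
exactly to the 7-point Laplacian in the isotropic limit and conserves grid
sums to round-off. Fourth- and sixth-order terms (the $\nabla^2$ of the
variational derivative) are nested applications of the 7-point Laplacian.
On the grid the free energy's tension terms are taken in integrated-by-parts
form ($+\tfrac{\varrho}{2} f \nabla^2 f$), making the closed-form
variational derivatives the exact gradients of the implemented $F$ — the
numerical-perturbation oracle in the test-suite reproduces them to
round-off.

Time: explicit Euler throughout. The stress tensor entering the morphogen
mobility is recomputed every `stress_every` (default 10) mechanical steps;
it varies on the slow time scale, and full-cadence recomputation is
available for verification. All heavy kernels are implemented in C++
(Rcpp), and the integrators crop every update to the z-window actually
occupied by the tissue — above it all fields are uniform, so the crop is
exact under the Neumann closure.

The scheduler alternates a chemical "pulse" of `n_chem` steps (default 100)
with `n_mech` mechanical steps (default 250) per outer cycle; the outer
cycle count is the trajectory's time axis $T$. Before the first cycle the
chemistry is equilibrated for `n_chem_init` steps (default 60000,
$t = 3000$ time units): the Turing pattern is the input of the mechanical
model, and on the thin shell the instability growth rate is a few
$10^{-3}$ per time unit, so this is roughly the saturation time at the
slowest $\eta$ used. These pulse lengths are deliberate desk-scale choices;
both are plain configuration knobs.

## Detection and classification

A primordium is operationally a persistent cluster of elevated morphogen on
the extracted surface:

* the $\phi = 0$ isosurface is triangulated by marching tetrahedra
  (watertight, deterministic), restricted to its largest connected
  component, and decorated with trilinearly sampled $u$ and mean curvature
  $H$ (from the projected normal-gradient curvature tensor, $H = \tfrac12
  \mathrm{tr}\,Q$, positive for a sphere enclosing the tissue);
* vertices above an adaptive threshold (mean + 2 SD of surface $u$, never
  below the absolute floor `u_abs_min = 0.25`) are clustered by mesh
  connectivity and reduced to $u$-weighted centroids; clusters within
  `g_width` of the apex are excluded (primordia never appear at the
  summit), as are vertices within `floor_margin` of the box floor (the
  open bottom rim of the computational surface is a box artifact);
* a candidate persisting `tau = 5` consecutive cycles within twice the
  source-ball radius of itself is fixed permanently, joins the current
  generation if born within `gen_window` cycles of its first member, and
  becomes a constant source ball of morphogen and mass ($s_u$, $s_\phi$,
  radius `r_p`) — young primordia are strong auxin sources, and this
  maintains their positions.

Fold counting collapses sites that share an azimuth (one harmonic often
stacks spots along a meridian), then applies the whorl gap-uniformity test,
falling back to the dominant angular Fourier mode (1–12, ties to the lower
mode). `classify_pattern()` labels a trajectory whorled / spiral / ribbed /
aberrant from generation synchrony, angular uniformity, divergence-angle
persistence and cluster aspect ratio; for ribbed (stripe) patterns the fold
is measured on the surface field itself (`field_fold()`), since stripes are
under-described by discrete sites. The absolute threshold, the margins and
the tolerances are artifact definitions — the reference publication counts
folds visually — validated by reproducing the captioned symmetries.

## Parameters

| symbol | code | default | meaning |
|---|---|---|---|
| $N_x,N_y,N_z$ | `nx, ny, nz` | 40, 40, 60 | grid size |
| $dx$ | `dx` | 1 | grid spacing |
| $dt_1, dt_2$ | `dt_chem, dt_mech` | $5\cdot10^{-2}$, $10^{-5}$ | time steps (ratio 5000) |
| $a,b,h,D$ | `a, b, h, D` | 1.1123, −1.0122, −1, 0.516 | BVAM kinetics |
| $c$ | `c` | 0.57 | stripe/spot selector, $[0, 0.57]$ |
| $\eta$ | `eta` | — (required) | domain-size surrogate / symmetry selector |
| $\epsilon$ | `eps` | 1 | interface width (not printed in the reference; one grid spacing is the thinnest resolvable) |
| $\varrho_\phi,\varrho_u$ | `rho_phi, rho_u` | 2.5, 0.5 | surface tensions |
| $\beta$ | `beta` | 0.5 | curvature coupling |
| $\gamma$ | `gamma` | 0.2 | stress–transport coupling |
| $D_\phi, m$ | `D_phi, m` | 1, 15 | mobility, mass-addition rate |
| $\kappa$ | `kappa` | 2 | tip-growth gain |
| $R, H_z$ | `R, Hz` | 10, 6 | dome radius, cylinder height |
| — | `g_width` | $R/2$ | tip-Gaussian standard deviation |
| — | `tip_gain` | 1 | tip-Gaussian amplitude (constant; the Gaussian's *centre* tracks the summit) |
| — | `s_phi, s_u` | 0.5, 0.5 | primordium source strengths |
| — | `r_p` | 2 | source-ball radius |

The tip-Gaussian amplitude deserves a note: the reference describes "a
variable height that changes according to the displacement of the summit".
We read "height" as the Gaussian's centre position $H_z$, which tracks the
summit so the source–apex distance stays constant; an amplitude growing
with summit displacement closes an unstable feedback loop (summit → pump →
summit) that diverges in finite time, so it cannot be the intended reading.
The amplitude is the constant `tip_gain`.

The primordium source strengths are not printed in the reference. They are
chosen small (0.5) so that fixed sources gently maintain their sites
without dominating the pattern field: at the mechanical step size a source
adds $\sim 10^{-3}$ of morphogen per cycle, comparable to the chemistry's
own maintenance of a saturated spot, while values of order 10 visibly
distort the surrounding pattern and eventually destabilize the explicit
scheme.

## What the generator emulates — and what it does not

Synthetic runs emulate the study conditions: the dome geometry, the printed
parameter values, uniform random $(u, v)$ perturbations of amplitude 0.1
seeded per run, and desk-scale horizons (run to first-generation fixation).
Passing tests demonstrate internal consistency of the implementation and
reproduction of the captioned pattern symmetries at those conditions; they
do not validate the model against real SAM geometry, cell-scale mechanics,
or measured auxin fields, and the long-horizon multi-generation behaviour
(four plastochrons and beyond) is outside the desk-scale envelope of the
default configurations.

## Numerical choices and degenerate inputs

* Explicit Euler stability: the stiffest term is $\sim 2\epsilon^4 \nabla^6$,
  giving $dt \lesssim 10^{-3}$ at $dx = 1$; the reference $dt_2 = 10^{-5}$
  has a wide margin, which the nonlinear factors ($3\phi^2 - 1$ at
  overshoots $\phi \approx 1.5$) do not exhaust.
* The raw stress tensor is not symmetric (one term mixes $\nabla\Phi_{SC}$
  with $\nabla\phi$); transport uses the symmetrized tensor, since a
  diffusion mobility must be symmetric for a well-posed flux. The raw
  tensor remains available for diagnostics, and on smooth 1D interfaces
  the asymmetry is at discretization level.
* Curvature is only defined on the interface band $|\phi| < 0.9$ and where
  $|\nabla\phi| > 10^{-10}$; elsewhere it is `NA`, and mesh vertices whose
  interpolation stencil touches masked voxels are masked in turn.
* Isosurface extraction treats voxels exactly at the level as inside
  (after an infinitesimal shift), so degenerate flat patches cannot create
  zero-area triangles.
* Energy decay is *not* asserted anywhere: the negative signs of the
  tension terms make monotone decay unguaranteed (they are implemented
  exactly as the model prints them), and the morphogen transport mobility
  $\gamma\sigma$ is not positive definite.
* `turing_band()` scans 2000 points over $k^2 \in [0,\,4\eta(1+|b|)/\min(D,1)]$
  and bisects the endpoints to $10^{-8}$; an unstable homogeneous state is
  flagged, with the band still returned.

## Desk-scale problem sizes

The default grid is the reference $40\times40\times60$; captioned-symmetry
runs use `n_chem_init = 60000`, then cycles of 100 chemical + 250
mechanical steps to first-generation fixation (typically $T \lesssim 25$
cycles, about one to two minutes each on one core). The conservation and
perturbation oracles in the test-suite run on $10^3$–$24^3$ grids.

## Known limitations

* Whorl folds are reproduced as first-generation symmetries at desk scale;
  multi-generation plastochron sequences require horizons beyond the
  default configurations.
* The chemistry-domain reading (shell of the meristematic cap) is a
  modelling decision among realizable interpretations of a boundary
  condition stated on an implicit surface; the alternatives remain
  selectable and their mode selection differs as described above.
* The interface slowly sharpens below its nominal width under the printed
  free energy; [reinit_interface()] offers level-set-style re-profiling,
  off by default because it erases the interior mass accumulation that
  feeds tip growth.
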
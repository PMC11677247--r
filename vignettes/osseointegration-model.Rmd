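---
title: "A poroelastic discrete-element model of peri-implant tissue mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A poroelastic discrete-element model of peri-implant tissue mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

After a dental implant is placed, the ~0.5 mm gap between the titanium
surface and the bone heals in three phases: a fibrin-rich blood clot
("primary matrix"), then vascularized granulation tissue with a thin fibrous
film on the metal, then immature woven bone that remodels into mature bone.
Whether the gap ossifies directly (osseointegration) or is walled off by
fibrous tissue depends on the local mechanical environment: moderate
hydrostatic stress with low shear favors osteoblasts (intramembranous
ossification), larger compressive stress favors chondrocytes (the
endochondral route), tensile stress beyond a few tenths of a megapascal
favors fibroblasts, and interstitial fluid pressure in a specific band is
needed to move progenitor cells at all. Extracorporeal shock wave therapy
(ESWT) is a candidate way to create those conditions along the whole implant
at once, rather than waiting for bone to creep up from the implant apex
under ordinary chewing loads.

`osseowave` implements a desk-scale in-silico version of this question: a
movable-cellular-automaton-style (bonded discrete-element) model of a
layered bone/implant block with Biot pore-fluid coupling, driven either by
an ESWT pulse train through a copper applicator plate or by a
displacement-controlled occlusal ramp, whose per-element mean stress, shear
strain and pore pressure fields are classified into tissue-differentiation
fates and reported as peri-implant volume fractions.

## Model geometry

The synthetic geometry emulates a mandibular segment at configurable scale.
The default desk benchmark is a 6 x 6 x 8 mm block: a 400 um gingiva layer
over a 600 um cortical layer over cancellous bone; a cylindrical Ti-6Al-4V
implant (radius 2 mm, length 4 mm from the top surface) inside a healing
shell of outer radius 2.5 mm whose material follows the osseointegration
phase (primary matrix; granulation plus a 0.25 mm fibrous interface; woven
bone); a fixed lowest element layer; and a copper applicator plate (7 x 7 x
0.3 mm at full scale, shrunk proportionally on small blocks) beside the +X
face. The gingiva has no dedicated row in the property table and is assigned
the fibrous soft-tissue parameters.

Elements are spheres of diameter `d` (default 400 um; the benchmark range is
333-500 um) on an FCC lattice, bonded to their 12 lattice contacts. Two
geometric choices matter at desk scale and are deliberate:

* **Pitched lattice.** The lattice plane spacing is stretched per axis by at
  most ~2% so each block dimension is an exact integer number of plane
  slabs (`lattice_pitches()`). Otherwise the realized top surface and
  cross-section quantize by half a spacing as `d` changes, which alone moves
  the benchmark stiffness by several percent between discretizations.
* **Interface smoothing.** Element properties are volume-fraction blends
  over a 27-point sub-cell sample (compliance-weighted moduli, harmonic
  permeability) across *tissue* interfaces, and bonds crossing the analytic
  implant surface carry a series-spring stiffness split at the true surface
  position. Both remove staircase artifacts: the realized soft-layer
  thicknesses and the implant radius then vary continuously with `d`.
  Metal elements stay pure metal and region labels (used for reporting and
  zone masks) remain nearest-region. `smooth_interfaces = FALSE` disables
  the blending.

The applicator occupies lattice sites continuing the tissue lattice beyond
the +X face, so plate-tissue bonds exist at exactly their reference length:
no initial contact force, but waves transmit through ordinary pair forces.

## Mechanics

Each element follows Newton-Euler translation and rotation, integrated by
velocity Verlet (two-half-kick updates for both velocity and spin; the pair
shear strain, the rotational "position" coordinate, advances with midpoint
velocities so the scheme stays non-dissipative). The pair response is:

* normal strain `eps_n = (r - r0)/r0` (tension positive) and a tangential
  shear strain vector accumulated from the relative slip of the contact
  points, element rotations included, so rigid-body motion produces no
  strain;
* a many-body closure: each element's local strain tensor is least-squares
  fitted from its pair normal strains through a precomputed 6x6
  pseudo-inverse of its bond-direction moment matrix (eigenmodes below 1% of
  the largest are truncated, so rank-deficient edge elements get a
  minimum-norm fit that never amplifies unresolved modes). The pair normal
  stress is `sigma_n = H eps_n + (many-body term) - alpha P`, where `H` is
  the harmonic combination of the two sides' `2G`, and the many-body term
  injects each element's `(1 - 2G/3K) K eps_v` through that bond's own fit
  weight. In the uniform limit this reproduces isotropic linear
  poroelasticity exactly (`sigma = K eps_v I + 2G eps_dev - alpha P I`),
  and because the force is the exact gradient of the fitted strain energy it
  is conservative: total energy drifts by ~2e-4 over 10^4 undamped steps;
* element stress tensors come from the fitted strain through the material
  law; the shear strain intensity reported to the classifier is
  `von Mises / 2G`;
* radial-return plasticity for the metals (Ti yield 800 MPa, Cu 80 MPa):
  deviatoric pair stresses scale by `sigma_y / von Mises`, mean stress
  unchanged. Tissues never yield; bonds never break (reported stresses stay
  far below tissue strength in all studied protocols).

Bond facet areas are the FCC Voronoi facets `V/(2d)`, scaled per pair by
`(12/deg_i + 12/deg_j)/2` so an under-coordinated surface element's bonds
represent its full surface share (removing an O(d) soft-skin bias).

The explicit timestep is `dt = C d / max(cp)` with `C = 0.2`, where `cp` is
the *undrained* P-wave speed `sqrt((K + 4G/3 + alpha^2 M)/rho)` — the Biot
stiffening, not the drained skeleton speed, limits stability of saturated
soft tissues. Element mass uses the tabulated matrix density.

## Pore fluid

Pore pressure (positive in compression) evolves per element as

```
dP/dt = M (-alpha deps_v/dt + sum_j T_ij (P_j - P_i))
```

with `alpha = 1 - K/Ks`, `1/M = theta/Kf + (alpha - theta)/Ks`, and
two-point Darcy transmissibilities `T = (k_harm/eta) A/(L V)` (harmonic-mean
permeability; zero across metal). The volumetric strain rate comes from the
same per-element strain fit as the mechanics, which makes the undrained
response `dP = -alpha M deps_v` exact at full coordination. Diffusion is
integrated on the mechanical clock with automatic sub-cycling when the
explicit diffusion limit is tighter; with the tabulated tissue
permeabilities it never is at these timesteps. All outer tissue surfaces
are sealed by default; any element set can be declared drained (`P = 0`).

A note on the published soft-tissue rows: the fibrous-type tissues have
`alpha` (0.79) marginally below their porosity (0.8) under the standard
closures. The storage modulus stays positive, so the package warns rather
than errors on those rows.

## Loading protocols

**ESWT.** The applicator plate moves rigidly along +X. Within each 1 us
period the prescribed velocity rises as a half-sine over 0.01 us to the peak
`V`, holds 0.1 us, mirrors down, and — by default — returns with a slow
recovery half-sine spanning the rest of the interval so the head carries no
net displacement (`retract = FALSE` restores a one-sided stroke, which at
desk scale buries the plate ~0.4 um into the block over five pulses and
leaves a dominating static indentation field). The plate follows the exact
displacement integral of the waveform, since the 10 ns rise is below the
timestep. The peak velocity comes from the plane-wave energy balance
`V = sqrt(EFD/(Z tau_eff))` with `Z` the copper impedance and `tau_eff`
defaulting to the pulse period (1 us); both are configuration-exposed so
alternative calibrations can be swapped in. A delivered-energy estimator
integrates `Z v^2` over the forward stroke with the shape correction
`tau_eff/(t_rise + t_hold)`. ESWT runs use zero bulk damping; the lateral
block faces — cuts through the surrounding mandible — carry
impedance-matched absorbing dashpots so outgoing waves radiate instead of
reverberating in the small box, while the gingival top surface stays free.

**Physiological.** The whole top element layer moves down at 0.1 m/s (with
a 5 us half-sine start-up) until the reaction force on it reaches the
target (100 N rest, 200 N mastication), then is held. Physiological runs
use local non-viscous damping 0.05. The reaction is smoothed by a short
running mean before target detection and the secant displacement is
corrected for the window lag exactly (the ramp rate is constant there);
windows between 5 and 25 us move the reported stiffness by well under a
percent.

## Mechanobiological classification

Per element and time sample, with tension-positive mean stress and shear
strain as a fraction:

| state | rule (defaults) |
|---|---|
| quiescent | magnitude below 3 kPa |
| fibrogenic | tension above 0.15 MPa, or small stress with shear > 5% on the tensile side |
| chondrogenic | compression between 0.15 and 2 MPa, or small compression with shear > 5% |
| osteogenic | magnitude in [3 kPa, 0.15 MPa] with shear <= 5% |
| overload | compression beyond 2 MPa |

Band boundaries are closed on the osteogenic side, fixed for testability.
The osteogenic ceiling is configurable (0.2 MPa is a common applied
reading); 0.15 MPa is the default. Cell transport is sufficient for pore
pressure between 20 kPa and 2 MPa and flagged optimal within a factor two
of 68 kPa. The distortional-strain band (0.05-1.1%, optimum 0.5%) is
computed as an auxiliary fibrous/cartilage-favoring flag rather than a
primary fate; under the studied protocols shear strains stay near or below
its lower edge, so it is inert by default. The classifier consumes the
total mean stress (the quantity mapped in the field figures); a switch
selects effective stress instead. Zone volume fractions are counts over the
peri-implant zone (shell plus fibrous interface) per time sample, averaged
over the sampling window; fractions below a 5% reporting floor are
displayed as "<5%" — our reading of the reported "5% mean value", with the
time-averaging and the floor both explicit and separable.

## Verification

Every closure has an analytic oracle, run by `verify_suite()` and the test
suite:

* **Modulus recovery**: quasi-static uniaxial-strain compression of a
  homogeneous block under affine boundary conditions; the measured interior
  stress against the least-squares-fitted interior strain recovers E and nu
  of the drained skeleton to ~0.2% (tolerance 3%).
* **Wave speed**: a velocity step down a laterally confined bar arrives at
  the two interior gauge planes at the bulk P-wave speed within ~3.5%
  (tolerance 5%). The detection threshold (0.2 of the step) sits above the
  surface-skin precursor; an unconfined thin bar would instead measure the
  rod speed `sqrt(E/rho)`, ~21% below bulk — a geometry effect, not an
  engine error.
* **Undrained response**: an affine isotropic compression with sealed pores
  reproduces `dP = -alpha M deps_v` to ~1e-9 at full coordination.
* **Terzaghi consolidation**: a laterally confined, top-drained column under
  constant load matches the analytic series to ~0.8% RMS of the initial
  pressure (tolerance 5%). The column is a 1-D chain discretization
  (axial bonds, `V = d^3`, `A = d^2`, its own closure constant): a narrow
  3-D column is all surface skin, which softens its realized confined
  modulus by ~20% — again geometry, not coupling. The chain reproduces the
  confined modulus and the continuum diffusion operator exactly. The test
  material is a synthetic fast-draining stand-in: tabulated tissue
  permeabilities put consolidation at 10^5-10^8 mechanical steps, and the
  series is permeability-invariant in dimensionless time.
* **Conservation**: total energy (kinetic plus pair-level elastic) drifts
  <0.1% over 10^4 undamped steps at half the stable timestep; momentum is
  conserved to machine precision; sealed fluid mass is conserved exactly.

## The scaled study and what it does and does not show

The full-scale analysis behind the headline volume-fraction maps used
~10^6 elements and tens of hours per run. The package reproduces the
analysis *workflow* on the 6 x 6 x 8 mm benchmark (3-12 k elements,
seconds to minutes per run), with two quantitative caveats that the scaled
geometry imposes and that we report rather than hide:

* **Stiffness convergence.** The three-level benchmark (d = 500/400/333 um)
  converges like the full-scale study — the two finest levels differ by
  ~1.3% — but the coarsest level resolves the 0.5 mm healing gap with a
  single element and sits ~6-7% stiff, so the three-level spread is ~7%
  rather than the <=4% achievable when the element is 4-10x smaller than
  every feature.
* **Peri-implant shear under ESWT.** At desk scale the applicator stands
  0.5 mm from the shell (several mm of bone at full scale) and the soft
  shell between the rigid implant and bone is a quarter-wave resonator at
  ~0.9 MHz that the 1 us pulse interval pumps almost coherently. The first
  pulse produces peak pair shear strains of 0.02-0.04%, consistent with the
  full-scale observation that therapeutic shear stays below 0.05%; over the
  five-pulse train the scaled maximum stacks to 0.09-0.14% depending on the
  discretization. Fate
  classifications, which key on hydrostatic and fluid pressure, are far
  less scale-sensitive.

Neither caveat affects the qualitative workflow results: under
physiological load the osteogenic/transport conditions concentrate near the
implant apex, while the shock-wave train creates transport-sufficient
pressure over a much larger fraction of the healing shell — the pattern the
method exists to study.

## Known limitations

Elastic isotropy (tissue anisotropy is deliberately out of scope);
no damage or bond breakage; no mechanoregulatory time evolution (the model
classifies instantaneous conditions; it cannot predict how long
osseointegration takes); simplified teeth (optional homogeneous dentin
cylinders with a PDL annulus, off by default); the gingiva shares the
fibrous tissue parameters; rigid prescribed applicator motion (no unilateral
contact); desk-scale geometry as discussed above.
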
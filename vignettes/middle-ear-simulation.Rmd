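---
title: "Simulating middle-ear microsurgery with otosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating middle-ear microsurgery with otosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

otosim is a scriptable, desk-scale simulator of two middle-ear
microsurgical procedures: **stapedotomy** (drilling a 0.6 mm hole through
the stapes footplate with a spherical burr) and **stapedioplasty**
(placing and crimping a 0.4 mm x 4.5 mm piston prosthesis onto the incus
long process). Both procedures exist because of otosclerosis: when the
stapes footplate fixes to the inner ear, the conductive chain is bypassed
with a piston through a fresh footplate perforation. The package replaces
interactive tele-operation with scripted, timestamped tool trajectories so
that every run is deterministic and testable, and it generates its own
synthetic anatomy so no imaging data is required.

This vignette explains the mechanical model, the drilling model, the
contact model, what the synthetic scene does and does not capture, the
numerical choices and their rationale, and the known limitations.

## The finite-element model

The ossicular chain (malleus, incus, stapes) is meshed with 4-node linear
tetrahedra; the tympanic membrane is a thin shell of constant-strain
triangles (CST) carrying in-plane plane-stress stiffness scaled by the
membrane thickness; the piston prosthesis is built from hexahedra, which
are decomposed into six tetrahedra at assembly time so that a single
element formulation serves all solids. Ligaments, tendons and joints are
spring sets:

* **axial springs** (`kind = "axial"`) are the textbook two-node spring,
  with stiffness `k d d'` along the rest direction;
* **cartesian springs** (`kind = "cartesian"`) penalize the full relative
  displacement of a node pair (block `k I`). Bundles of these model the
  incudomalleolar and incudostapedial joints and the weld between the
  prosthesis shaft and its loop, where a joint must resist all relative
  translations; the annular ligament suspending the footplate uses one per
  rim node.

Dynamics use a lumped (diagonal) mass matrix, Rayleigh damping
`C = alpha M + beta K` with `alpha = 0 /s` and `beta = 1e-4 s`, and an
implicit backward-Euler step of 0.04 s:

```
(M + dt C + dt^2 K) dv = dt (f_ext + f_el(x) - C v - dt K v)
v <- v + dv ;  x <- x + dt v
```

which is unconditionally stable and dissipative for the linear system (the
suite checks a 1-dof step against the closed form to 1e-12 and monotone
energy decay over 100 free-vibration steps). Tetrahedra optionally carry a
**corotational** frame: the rotation is extracted from the deformation
gradient by polar decomposition (SVD) and the element force becomes
`-R Ke (R' x - x0)`. This is the standard choice for large-displacement
interactive surgical FEM; the default is corotational for the ossicles and
linear for the membrane. Elements whose deformation gradient is within
1e-7 of the identity take the exact linear fast path, so the corotational
model reduces to the linear one at rest. The damping matrix is built once
from the rest-configuration stiffness and kept constant in corotational
mode.

Material defaults (all configurable in `scene_config()`): ossicle bone
E = 14.1 GPa, rho = 2200 kg/m^3; membrane E = 32 MPa, thickness 74 um;
prosthesis rho = 4500 kg/m^3 and E = 344 MPa (the published value for the
modelled grade-2 titanium piston), Poisson 0.3 throughout. Ligament
stiffness defaults to 100 N/m per rim spring and joints to 5000 N/m per
bundle spring; these are order-of-magnitude choices from the middle-ear
FEM literature, and every acceptance-style check in the package is defined
relative to this synthetic scene, not to patient data. Gravity is off by
default: ossicle weight (~1e-5 N) is negligible against the 0.1-1 N
surgical loads.

## The synthetic anatomy

`build_scene()` constructs, deterministically from a configuration in mm:

* an **elliptic stapes footplate**, 2.8 x 1.52 mm laterally and 0.25 mm
  thick (thickness is not anatomically standardized; 0.25 mm is a
  plausible default and configurable), as a voxelized tetrahedral mesh
  plus an exact elliptic-plate signed-distance field;
* a **stapes superstructure** arch (two crura and a head) welded to the
  footplate;
* an **incus** with a 0.3 mm-square long process descending to a tip
  marker group of nodes — the incus displacement metric of the procedures
  is measured at the mean of these tip nodes;
* a **malleus** bar joined to the incus body and to
* a **conical tympanic membrane** (8 mm diameter, 0.8 mm apex height)
  whose annulus ring is fixed. The cone matters: a perfectly flat pure
  membrane has no transverse stiffness at all (singular static problem),
  while the shallow cone resists normal pressure through its geometry,
  which is also anatomically correct;
* the **piston prosthesis**: a 0.4 mm square-section shaft, 4.5 mm long,
  welded to a C-shaped wire loop that starts seated on the incus long
  process with a 0.01 mm interference fit. The elastic squeeze of the
  undersized loop is the crimp grip; the loop opening (30 degrees
  half-angle) faces the push direction so the process enters the aperture
  and bottoms against the solid back of the loop;
* the tools: a 0.6 mm spherical **burr**, a 0.6 mm **blocking rod**
  (suction-cannula dimensions) laid parallel to the long process on the
  side opposite the prosthesis approach, and the **microforceps** whose
  grasp is a generalized spring distributed along the whole shaft — the
  distribution supplies the angular stiffness of a rigid grip, without
  which the loop could spin freely in its own plane under frictionless
  contact.

Coordinates: X anterior-posterior, Y superior-inferior, Z lateral-medial
with +Z toward the inner ear; the microscope looks along +Z through a 6 mm
speculum.

What the generator does **not** emulate: real ossicle geometry (the bodies
are boxes and plates, not micro-MRI surfaces), bony fixation patterns of
otosclerosis beyond a stiffness switch, mucosa, tendon pretension, fluid
coupling to the cochlea, and bleeding. Tests that pass on this scene
demonstrate the correctness of the algorithms and the qualitative
mechanics (force paths, contact behaviour, metric definitions), not
patient-specific accuracy.

## Drilling

Bone removal is constructive-solid-geometry subtraction on a signed
distance field (negative inside material): for every voxel in the tool's
padded bounding box,

```
surface <- max(surface, -tool)
```

so material is only ever removed, carving twice with the same pose is a
no-op, voxels outside the padded box are untouched, and disjoint carves
commute — all asserted exactly in the suite. The footplate SDF uses a
0.02 mm voxel spacing (about 30 voxels across the burr); removed volume is
integrated with a clamped-linear sub-voxel occupancy (binary counting is
kept as the brute-force reference mode), which puts a straight-plunge
drill-through within 5% of the analytic swept volume. Surfaces are
extracted by marching tetrahedra (Freudenthal six-tetrahedra cube
decomposition with linear edge interpolation, coincident vertices merged),
a watertight member of the marching-cubes family; the extracted sphere
volume converges within 3% at spacing r/20.

Drilling feeds back into mechanics by **element deactivation**: a
tetrahedron whose centroid the carved SDF reports as void loses its
stiffness and mass at the next assembly. How drilled bone should alter a
FEM is not standardized; centroid deactivation is the minimal mechanically
consistent coupling, and it also implements the scripted "total drilling"
ablation of the stapes superstructure before stapedioplasty (fracture of
the crura is not modelled). Contact with the burr is likewise restricted
to nodes still backed by material.

## Contact

Tools are analytic signed distance fields; deformable meshes collide
point-wise (nodes, or points sampled on edges/triangles with the deepest
kept per feature). A contact supplies an outward normal (the SDF
gradient), a depth, and optionally a set of carrier nodes on a deformable
obstacle over which the reaction is distributed — the loop-process contact
uses a continuous hat-function weight over the process surface nodes near
the contact point, because any discontinuous support switching injects
impulse noise.

The unilateral problem (impulse >= 0, non-penetration, complementarity) is
solved on the compliance matrix `W = J A^-1 J'` by projected Gauss-Seidel
warm start plus an active-set direct polish, which reaches machine-level
complementarity even when `W` is ill-conditioned (stiff bone clusters,
conforming grip contacts). Stabilization is **split-impulse**: the
velocity pass only stops approach velocity (contacts found within a
0.02 mm detection slop may still approach until they touch), while a
second position pass pushes existing penetrations out by an error
reduction fraction (`erp = 0.2`) per step *without* entering the stored
velocities. The two design decisions worth recording: a naive combined
ERP bias pumped energy into the permanently engaged interference-fit grip
(visible as +-z chatter of the incus), and without the detection slop a
quasistatic push crept through the blocking rod at one correction-rate
penetration per step. Both passes report a normalized complementarity
residual that the procedures carry into their reports; the suite requires
it below the solver tolerance on every step. Contacts are frictionless by
default (no friction model is assumed anywhere in the scene design).

Snap-in engagement is detected geometrically: the loop is engaged when the
in-plane distance from the loop centre to the process axis falls below the
configured detent threshold (0.12 mm default).

## Procedures and metrics

`run_stapedotomy()` steps carving + FEM + contact along a burr trajectory
and reports: drilled volume (mm^3), drilled fraction of the initial
footplate volume, minimal burr-centre distance to the expert target,
effective hole diameter (largest disc inscribed in the through-hole
region, by a 2-D distance transform over grid columns), the force trace on
the footplate, damage flags and the maximal contact residual. "Execution
time" is always the simulated trajectory span, never wall clock.

`run_stapedioplasty()` requires a prepared scene
(`prepare_stapedioplasty_scene()` performs the scripted stapedotomy and
superstructure ablation), pushes the grasped prosthesis along a scripted
ramp-and-hold trajectory (default amplitude 0.25 mm over 6 s) with seeded
band-limited jitter (5 um standard deviation, a tremor surrogate), and
records the incus-tip displacement trace and per-axis peaks, contact
forces on the incus, damage flags against the 0.9 N anterior-posterior /
0.7 N lateral-medial safety limits, and the engagement flag. A second-arm
trajectory adds the rigid blocking rod; `displacement_reduction()`
compares paired runs. A run in which the loop never engages returns
`engaged = FALSE` rather than an error.

The default push amplitude was chosen once so that the single-tool peak
incus displacement (~0.1 mm) sits in the range reported for this
manipulation and the contact forces stay well below the damage limits;
none of the scripted defaults were adjusted afterwards.

## Evaluation

`transfer_function()` solves the steady-state harmonic problem
`(K + i w C - w^2 M) u = p a_n` under an area-weighted acoustic pressure
on the membrane and reads the stapes-footplate response per unit pressure
— the in-silico analogue of an audiometric transfer function.
`static_pressure_test()` applies a static pressure (nominal, or
"otosclerotic" with the annular ligament stiffened 1000-fold) and solves
`K u = f` directly or by Jacobi-preconditioned conjugate gradients.

Procedure quality is scored as

```
E = alpha / S + beta / F + gamma / VF + delta * (TF_after / TF_before)
```

with `S` the distance to the expert-defined target (mm), `F` the force
functional `F(t) = mu df/dt + lambda integral f dt` (central differences +
trapezoid; the scalar summary is the peak |F(t)|, with the full trace
exported so any other reduction can be applied), `VF` the visual
obstruction time (simulated time a tool spends inside the speculum viewing
cone), and the transfer-function ratio averaged over the frequency grid.
Higher E is better; the reciprocal reading of the first three terms makes
E decrease with distance, force and obstruction, which is the only
monotonicity consistent with "smaller is better" for those inputs. No
published values exist for the six constants, so all default to 1 and the
three reciprocal inputs are normalized by configurable reference scales to
keep the terms commensurable; a zero S, F or VF leaves its term out with a
message because the limit is undefined.

## Problem sizes and determinism

The default scene has ~690 nodes (~2100 dofs) and ~1500 corotational
tetrahedra; a 150-step crimp run takes well under a minute on one core and
the full test suite a few minutes. These sizes were chosen as the smallest
scene on which every force path of the procedures is still present. All
randomness (trajectory jitter) is seeded; re-running any procedure with
the same configuration and seed is bit-identical, which the suite asserts.

## Known limitations

* Linear/corotational elasticity only; no plasticity, so the "crimp" is an
  elastic interference grip, not a permanent deformation of the loop.
* Frictionless contact; a real crimp also holds by friction.
* The blocking rod is rigid and scripted; arm compliance is not modelled.
* CST membranes have no bending stiffness; the membrane's transverse
  support comes from its conical geometry and the annulus.
* Drilling does not model heat, burr vibration, or footplate fracture
  (the floating-footplate complication cannot occur in this model).
* The quality-score constants are placeholders (all 1); scores are
  comparable between runs of this simulator, not across instruments.
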
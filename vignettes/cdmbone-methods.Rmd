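---
title: "Continuum-damage simulation of cortical bone compression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum-damage simulation of cortical bone compression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmbone)
```

## The problem

Cortical bone — the dense shell of long bones — fails quasi-brittlely under
axial compression: the load–displacement curve rises almost linearly and then
drops abruptly, with no plastic plateau.  Finite-element fracture simulations
of this process usually degrade element stiffness through a scalar damage
variable once a *strain criterion* exceeds a tissue failure threshold.  Two
criteria are in common use and they are not equivalent: the **minimum
principal strain** (the magnitude of the most compressive principal strain)
and the **von Mises equivalent strain** (a deviatoric norm that mixes axial,
transverse and shear components).  `cdmbone` implements both within one
pipeline so their structural predictions can be compared on identical
specimens.

## Constitutive model

The tissue is transversely isotropic linear elastic, stiff axis along the
osteons (the shaft axis, which is also the loading axis `k` of the voxel
grid).  Default engineering constants, in MPa:

| constant | default | meaning |
|---|---|---|
| `E_L` | 13 498 | longitudinal (osteon-axis) Young's modulus |
| `E_T` | 11 025 | transverse Young's modulus |
| `nu_LT`, `nu_TT` | 0.3 | Poisson ratios |
| `G_LT` | `E_L / (2(1+nu_LT))` | longitudinal shear modulus |

Only `E_L`, `E_T` and a single Poisson ratio are typically measured (by
nanoindentation); the remaining constants of a transversely isotropic solid
must be filled in.  We set `nu_TT = nu_LT` and give `G_LT` the
isotropic-style default, both exposed in the configuration.  Admissibility
(positive-definite 6×6 stiffness) is checked at construction.

Damage degrades the whole stiffness tensor uniformly,

$$\sigma = (1 - D)\,C\,\varepsilon,$$

with the scalar damage variable driven by the criterion strain
$\varepsilon_c$ through an exponential softening law with critical failure
strain $\varepsilon_f$ (default 4.3 %, a compressive failure strain for
young rat femoral cortical tissue):

$$D = 0 \;\; (\varepsilon_c \le \varepsilon_f), \qquad
  D = 1 - e^{1 - \varepsilon_c/\varepsilon_f} \;\;
  (\varepsilon_c > \varepsilon_f),$$

capped at $D_{\max} = 0.9$.  An element whose modulus has dropped to 10 % of
the original ($D \ge 0.9$) is *failed* and loses its load-bearing role.

Three modelling decisions here were genuinely open:

* **Which equivalent strain.**  Commercial codes offer several; we use the
  von Mises deviatoric norm of the *total* strain,
  $\varepsilon_{eq} = \sqrt{\tfrac23\, e\!:\!e}$, the standard choice that
  accounts for transverse, longitudinal and shear strains together.  A
  tensile-equivalent (Mazars-type) form would be wrong here: the loading is
  compressive and a tensile measure would register almost nothing.
* **Instantaneous vs historical driving strain.**  The softening law is
  stated pointwise; we drive it with a history variable
  $\kappa = \max_t \varepsilon_c(t)$, which makes damage irreversible even
  if an element unloads (as elements beside a forming crack do).  Under
  monotone loading the two coincide.
* **Tension.**  Tensile principal strains drive no damage in the
  minimum-principal criterion (`max(0, -lambda_min)`); under axial
  compression of this geometry tensile strains stay small, and a
  tension-compression asymmetric law is out of scope.

The solver advances equilibrium with the *secant* stiffness $(1-D)C$ rather
than the full consistent tangent (which adds the rank-one term
$-(C\varepsilon)\otimes \partial D/\partial\varepsilon$).  With the
staggered scheme below, the secant is sufficient for equilibrium at a fixed
point and far more robust on the softening branch.  The consistent tangent
is implemented (`consistent_tangent()`) and verified against finite
differences, but the default path never needs it.

## Specimen and mesh

No deposited geometry exists for specimens of this kind, so the package
generates one: a hollow, roughly tubular diaphysis segment, voxelized and
meshed one 8-node hexahedron per voxel with exact (integer-lattice) corner
merging.  Defaults: outer diameter 3.5 mm, nominal wall 0.5 mm, height
5 mm.  The height is the physically meaningful dimension (specimens of this
kind are cut to 5 mm); the cross-sectional dimensions are plausible
rat-femur values chosen so that an 80 µm voxel gives a mesh in the
tens-of-thousands of elements, and they are configurable, not measured.

Two asymmetries make the specimen bone-like rather than a perfect tube, and
both are part of the study conditions rather than tuning knobs:

* **Eccentricity 0.25** — the medullary canal is offset toward +x by a
  quarter of the wall thickness.  Real rat femoral cortex is markedly
  asymmetric; a perfect tube would make every failure band an axisymmetric
  ring.
* **Surface undulation, SD 0.03 mm** — both surfaces carry a smooth
  low-order Fourier perturbation (3 circumferential × 3 axial modes, random
  phases).  The coefficients are drawn *once* from the seed, so the
  underlying smooth surface is independent of the voxel size: the
  mesh-sensitivity study meshes the *same* specimen at every resolution.

Segmented micro-CT masks (MetaImage or NRRD, isotropic voxels) can be
imported in place of the generator; only the largest 26-connected component
is kept so isolated voxels cannot produce a singular stiffness matrix.

The test-scale default voxel is 0.25 mm (~1.5k elements), the smallest size
that still resolves the wall with two elements; studies that need finer
resolution state it.

## Boundary conditions

The physical test compresses the specimen between rigid platens at
1 mm/min, the lower contact effectively frictionless and the upper one
frictional.  A true contact solver is out of scope; platens are replaced by
nodal constraints:

* bottom: axial displacement fixed, lateral free (frictionless);
* top (default **stick**): axial displacement prescribed, lateral fixed — a
  conservative stand-in for frictional contact that transmits shear into
  the upper specimen;
* top (**frictionless** option): lateral free, used for analytic
  verification, with in-plane rigid-body modes pinned at two bottom nodes
  on a common lattice line (exactly stress-free for the uniform uniaxial
  states this mode is used to verify).

This is the largest deliberate deviation from the physical setup and every
run summary records it.  Its main visible consequence is discussed under
*Limitations*.

## The progressive-failure driver

Loading is displacement-controlled: the platen displacement (default
0.5 mm, i.e. 10 % nominal strain on a 5 mm specimen) is applied in equal
increments (default 100).  Each increment runs a staggered (operator-split)
fixed-point iteration: solve equilibrium with the current per-element secant
factors, recover centroid strains, advance $\kappa$ and $D$, repeat until
the largest per-element damage change is below `stagger_tolerance`
(default 10⁻³, capped at 25 iterations; a non-converged increment is
accepted with a warning and flagged in the result).  Because every element
of a voxel mesh is a congruent cube, the damaged element stiffness is a
scalar multiple of one reference matrix, and re-assembly reduces to a
sparse matrix–vector product; the numeric Cholesky factorisation is updated
in a fixed symbolic pattern (supernodal CHOLMOD).  When the damage field is
unchanged the solution is reused by linear scaling, so pre-damage
increments cost no factorisation.

Failed elements are not deleted; their secant factor is floored at
`stiffness_floor` (default 10⁻⁴) to keep the system positive definite.  If
more than 5 % of elements switch to failed within one increment, the
increment is discarded and re-tried at half size (down to 1/16 of the
nominal step) so the brutal softening branch is not overshot.  Load factors
are tracked as exact integer fractions, so prescribed displacements carry
no accumulated roundoff, and the damage threshold comparison carries a
10⁻⁹ relative guard so a state loaded *exactly* to $\varepsilon_f$ is
undamaged, as the strict inequality requires.

A run terminates at full displacement, when the reaction has dropped 20 %
from its peak (after damage has begun), or when the failed elements
percolate — operationalized as the face-connected graph of *intact*
elements no longer linking the top voxel layer to the bottom one.  "Apparent
failure once failed elements accumulate" has no unique formalization; both
rules are config-exposed and the result records which fired.

## Derived quantities

* **Fracture load** = peak reaction; **fracture displacement** = its
  location; **fracture time** = displacement ÷ (1 mm/min).  Peak of the
  quasi-brittle curve is the standard reading; nothing else on these curves
  is better defined.
* **Apparent stiffness** = least-squares slope of the ascending branch
  restricted to reactions in [10 %, 40 %] of peak (window-perturbation
  stable to <2 % on elastic runs).
* **Crack plane** = principal-axis fit to the centroids of the largest
  face-connected failed cluster (normal = direction of smallest spread);
  **crack angle** = angle between that normal and the loading axis;
  ≤ 15° classifies *transverse*, otherwise *oblique*.  The 15° split is a
  package choice — the underlying field observation is qualitative
  ("perpendicular to the load" vs "at a certain angle").

## Study sizes and what the suite shows

The bundled studies run at desk scale deliberately: single elements for
constitutive verification; ~1.5k elements (0.25 mm voxels) for the
criterion comparison; 150/200/250 µm for the sensitivity sweep (~7k
elements at the finest).  These sizes keep a full study in minutes on one
CPU while preserving the mechanisms of interest.

What passing tests show: the constitutive behaviour is exact at the printed
parameter level (moduli, Poisson ratio, threshold, damage cap); the
criterion ordering is structural — under compression the equivalent strain
of a uniaxial state is ~0.87× the axial strain, so the minimum-principal
run always enters fracture first, at lower load, with the pre-damage curves
coinciding — and holds across specimen seeds.  What they do not show:
agreement with any individual physical specimen (geometry is synthetic and
the experimental curves are not digitized), or mesh-converged fracture
loads (element-wise damage without regularization is mesh-sensitive by
construction; that sensitivity is itself one of the reported findings).

## Numerical choices

* Voigt order (11, 22, 33, 12, 13, 23); engineering shears only at the
  stiffness-matrix boundary, tensorial shears in every strain tensor.
* Per-element vectorized closed-form (trigonometric) symmetric 3×3
  eigenvalues for the minimum principal strain; `eigen()` serves as the
  independent oracle in the tests.
* One strain/damage evaluation point per element (the centroid), while the
  element stiffness uses full 2×2×2 Gauss with a uniform $(1-D)$ factor —
  consistent with element-level failure semantics.
* Direct sparse Cholesky per stagger iteration; equilibrium residuals are
  checked against a 10⁻⁸ relative tolerance in the one-shot solver.
* Degenerate inputs: empty masks, anisotropic spacings, too-coarse voxels
  and inverted elements are explicit errors; isolated voxels are dropped
  with a warning.

## Limitations

* **Platen friction.**  The stick-platen stand-in transmits shear but also
  laterally confines the whole top face, which stiffens the upper specimen
  axially (confined modulus > `E_L`) and pushes strain — and hence failure —
  toward the frictionless bottom at coarse resolution.  One consequence:
  the characteristic *oblique* crack of minimum-principal runs under
  frictional compression is reproduced only marginally at desk scale (the
  failed cluster tilts once the shear boundary layer is resolved, ~150 µm,
  and for some specimen instances at 0.25 mm), whereas with true penalty
  friction it is the robust outcome.  The equivalent-strain run's
  transverse band is robust.
* **Quasi-brittle collapse is resolution-limited in load increments**: the
  post-peak branch depends on increment size and the bisection rule; only
  pre-collapse quantities (fracture load, stiffness) are treated as
  reportable.
* **Self-convergence of the staggered scheme is linear**, so the fixed
  point is polished, not exact: tightening the stagger tolerance 10×
  moves the fracture load by ~10⁻⁴ relative on damaged branches (damage-free
  increments are exact).
* Small-strain kinematics throughout, although the nominal end-of-run
  strain is 10 %; the fracture quantities of interest occur near 4–5 %.
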
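---
title: "Harmonic-field orthotropic material assignment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic-field orthotropic material assignment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthobone)
```

## The model

Bone is modelled as a linearly elastic continuum whose material symmetry
is orthotropic: three mutually orthogonal principal axes — radial (1),
tangential/circumferential (2), axial/longitudinal (3) — with nine
independent engineering constants $E_1, E_2, E_3, G_{12}, G_{13},
G_{23}, \nu_{12}, \nu_{13}, \nu_{23}$. In a curved bone such as the
mandible these axes rotate from point to point, so a single global (or
even per-zone) coordinate system cannot represent them. The package
constructs a per-element axis field from two volumetric harmonic
fields:

1. $\varphi_{\mathrm{long}}$ solves the discrete Laplace equation on the
   P1 (linear tet) space, with Dirichlet seeds $\{0, 1\}$ on the two
   ends of the bone. Harmonic fields conform to the domain shape, so
   $\nabla \varphi_{\mathrm{long}}$ follows the curved long axis.
2. $\varphi_{\mathrm{rad}}$ solves the same equation with the
   cortical–cancellous interface at 0 and the periosteal (outer)
   surface at 1.

Per element (P1 gradients are constant per tet):
$e_3 = \nabla\varphi_{\mathrm{long}} / \lVert\cdot\rVert$,
$e_1 = \mathrm{GS}(\nabla\varphi_{\mathrm{rad}} \perp e_3)$,
$e_2 = e_3 \times e_1$, giving a right-handed orthonormal triad
$R = [e_1\, e_2\, e_3]$. The local stiffness (Voigt order 11, 22, 33,
23, 13, 12, engineering shear strains) is rotated into global
coordinates by the Bond congruence $C' = M(R)\, C\, M(R)^{\mathsf T}$
and used in a constant-strain tet4 elastostatic solve.

### The alveolar-ridge problem and virtual elements

On a dentate mandible the longitudinal field cannot flow through the
tooth-bearing ridge, so its level sets bend around the alveolar region
and $e_3$ there deviates from the true trajectory of maximum stiffness.
The remedy implemented here fills the ridge region with *virtual finite
elements*: they enter the $\varphi_{\mathrm{long}}$ assembly (and only
that assembly) so the field passes through the ridge, and they are
ignored once frames are assigned — they never carry material or load.
On the proxy geometry this reduces the mean angular deviation of $e_3$
from the analytic centerline tangent in the ridge-adjacent band from
about 8° to about 3° (the paired run is asserted by the test suite).

Whether the radial field should also see the virtual elements is an
open choice; it is solved on bone only, because the ridge interruption
is a longitudinal-flow problem and the radial seeds (interface/outer
surface) are unaffected by the notch. A config override can include
them.

### Seed placement

Seeds are named node *sets* (patches), not single points: point seeds
make the discrete solution mesh-dependent and needlessly concentrate
the field. Any node set can be seeded with any value through
`dirichlet_spec()`, so condyle/coronoid-style point selections remain
possible.

## Comparison models

* **isotropic** — cortical and cancellous bone get effective isotropic
  constants; all other components (implant, crown, enamel, dentin,
  cartilage) are isotropic in every model.
* **orthotropic** — per-element frames as above, nine-constant rows for
  both bone tissues.
* **zoned** — the simplified comparator: elements are binned into
  `n_zones = 4` equal-width intervals of element-mean
  $\varphi_{\mathrm{long}}$ and every element of a zone shares the
  single frame of the element nearest the zone centroid. Anatomic zone
  definitions from the literature are not reproducible on a synthetic
  proxy; equal-width field bins are the neutral analogue that preserves
  the defining feature (a handful of fixed frames on a curved domain).
  Its mean frame deviation (~8°) exceeds the per-element model's (~3°),
  and the induced stress/strain pattern is correspondingly irregular.

### Effective isotropic moduli

The isotropic bone constants are derived from the orthotropic rows via
the Voigt (uniform strain, stiffness average) and Reuss (uniform
stress, compliance average) bounds on the bulk and shear moduli, with
the Hill arithmetic mean and the conversions $E = 9KG/(3K+G)$,
$\nu = (3K-2G)/(2(3K+G))$. `voigt_reuss_hill()` reports all three
estimates so the choice of reduction is inspectable. For the cortical
row this yields $E_H = 16.42$ GPa, $\nu_H = 0.320$, matching the
effective values in common use. For the cancellous row the reduction
yields $E_H \approx 1.61$ GPa, $\nu_H \approx 0.446$, which does *not*
match the widely quoted effective cancellous values
($E = 0.482$ GPa, $\nu = 0.26$) stored in `material_db()`: those are
inherited from the source measurements and are not derivable from the
nine-constant row by any standard combination of the bounds (we checked
both Poisson-denominator conventions, all axis permutations, and
arithmetic/geometric/harmonic means). `material_db()` therefore carries
the literature values for the isotropic model, while
`voigt_reuss_hill()` reports what the reduction actually gives.

### Conventions

* Poisson convention $S_{ij} = -\nu_{ij}/E_i$ (i.e. $\nu_{ij} =
  -\varepsilon_j/\varepsilon_i$ under uniaxial stress along $i$), the
  dominant engineering convention; both packaged bone rows are verified
  positive definite under it at construction.
* Voigt order pairs $S_{44}$ with $G_{23}$, $S_{55}$ with $G_{13}$,
  $S_{66}$ with $G_{12}$, consistent with the radial/tangential/axial
  direction naming.
* Units: coordinates mm, moduli GPa, forces N, tractions and reported
  stresses MPa (1 GPa·mm² = 1 kN internally).
* Axis signs: $e_3$ is oriented along the analytic centerline tangent
  where one exists (else toward increasing $\varphi_{\mathrm{long}}$);
  elastic response is sign-invariant, stable signs make runs
  comparable.

## The synthetic proxy

`generate_proxy()` builds a circular-arc tube (default: arc radius
25 mm, arc angle 120°, outer cross-section radius 7 mm) with a 2 mm
cortical shell — typical mandibular body curvature and cortex — around
a cancellous core, a crestal notch (depth 3 mm over a 30° arc window)
standing in for the alveolar ridge interruption, virtual elements
filling the notch flush with the unnotched surface, and a vertical
implant cylinder (10.0 mm × ⌀4.8 mm, a wide-neck molar fixture) at 65%
of the arc, bonded to bone by shared nodes with only its occlusal
platform exposed. Meshing is a deterministic structured template (Kuhn
subdivision of a bent square-to-disc grid); the seed only jitters
strictly interior single-region nodes by ≤10% of the edge length, so
interfaces and sets are seed-invariant.

What the proxy does **not** emulate: anatomic cross-section shape,
teeth/periodontal ligament, TMJ contact, muscle attachment sites, and
density heterogeneity. Passing tests therefore certify the *method* —
field construction, frame quality, tensor algebra, solver exactness,
and the qualitative peri-implant pattern — not patient-specific
percentage changes, which depend on real geometry.

The default load case is bite-like: 150 N axial plus 20 N lateral on
the implant platform nodes, with both tube ends fully restrained (the
analogue of bilateral distal restraints). Loads are deliberately config
data, since published muscle-resolved load sets are tied to anatomic
attachment sites the proxy does not have.

## Numerical choices

* P1 stiffness $K_{ab} = \sum_e V_e \nabla N_a \cdot \nabla N_b$ with
  unit conductivity; plain Laplace is the canonical harmonic-field
  operator.
* Direct sparse Cholesky (`Matrix::solve`) for both the Laplace and the
  elasticity systems: meshes are desk-scale (the default proxy has
  11 520 tets / 2 511 nodes; the full three-model comparison runs in
  about 20 s) and direct solves are deterministic. Dirichlet values are
  imposed by row/column elimination, so seeds are met exactly.
* Degenerate frames: if $\lVert\nabla\varphi_{\mathrm{long}}\rVert <
  10^{-12}$ or the two gradients are within 1° of parallel, the element
  is flagged. With the default radial seeds the radial field is
  *constant* throughout the cancellous core (the core is bounded
  entirely by its zero-valued seed surface), so radial degeneracy there
  is structural, not accidental. The fallback keeps the element's own
  valid $e_3$ and borrows only the radial direction of the nearest
  non-degenerate element (re-orthogonalised); whole-frame copying is
  reserved for elements whose longitudinal gradient also vanishes.
  Flags are retained in the output.
* Stress statistics are per-element (constant-strain values), not
  nodal-averaged: ROI maxima would be diluted by averaging. ROI =
  elements of the target tissue whose centroid lies within 1.0 mm
  (configurable, reported in the CSV metadata) of the implant-surface
  node set.
* Equivalent strain uses the conventional effective Poisson ratio
  $\nu_{\mathrm{eff}} = 0.3$ normalisation,
  $\varepsilon_{\mathrm{eq}} = \frac{1}{1+\nu_{\mathrm{eff}}}
  \sqrt{\tfrac12[(\varepsilon_1-\varepsilon_2)^2 +
  (\varepsilon_2-\varepsilon_3)^2 +
  (\varepsilon_3-\varepsilon_1)^2]}$.
* Compressive statistics are signed third-principal values; the "max
  compressive" is the most negative, with magnitude columns alongside.

## Known limitations

* Constant-strain tets are stiff in bending; absolute stress values on
  the coarse default mesh are indicative, and the package's claims are
  therefore comparative (between material models on the same mesh), not
  absolute.
* The discrete maximum principle is guaranteed only on meshes without
  strongly obtuse dihedral angles; the unjittered template satisfies it
  and the test suite checks it there.
* No contact: the implant is perfectly bonded (osseointegrated); crown,
  abutment and screw internals are not modelled.
* The mandible-proxy percentage changes should not be quoted as
  clinical predictions; they demonstrate the direction and relative
  magnitude of the orthotropy effect (cancellous ≫ cortical
  sensitivity) on an idealised geometry.
```{r session}
sessionInfo()
```
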
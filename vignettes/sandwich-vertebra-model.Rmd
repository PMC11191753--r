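---
title: "A parametric finite-element model of the cemented sandwich vertebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A parametric finite-element model of the cemented sandwich vertebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svfem` studies how the lateral distribution of vertebroplasty cement in the
vertebrae above and below an untreated "sandwich" vertebra (T12, between
augmented T11 and L1) changes the mechanical load on that vertebra and its
discs. This vignette is the package's own account of the model: what it
assumes, which parameters matter, how the synthetic anatomy was calibrated,
and — importantly — what the model can and cannot say about the published
comparison it stands in for.

## 1. The model and its assumptions

The segment is solved as a monolithic small-strain, small-rotation,
isotropic linear-elasticity problem in a mm/N/MPa unit system. There is no
plasticity, damage, time dependence or geometric nonlinearity; the only
nonlinearity is the unilateral behaviour of the ligaments (tension-only) and
of the interspinous bony stop (compression-only), resolved by a fixed-point
active-set iteration.

**Geometry.** Each vertebral body is an elliptical cylinder (defaults:
30 mm anterior–posterior by 42 mm lateral, 24 mm tall) with a cortical shell
whose thickness is exactly 1.5 mm everywhere on a transverse section — the
inner cortical boundary is the true inward normal offset of the outer
ellipse, not a scaled copy. Endplates are 0.5 mm layers on every disc-facing
surface, bounded laterally by the cortical rim (the ring apophysis), so the
cortical ring runs the full body height. Discs fill the same elliptical
footprint with an annulus matrix around a nucleus that occupies 40 % of the
cross-section, its centroid 1.5 mm posterior. Posterior elements are
idealised prisms: pedicle bars spanning three sectors of the posterolateral
body wall, a lamina block, spinous and transverse processes, and superior /
inferior articular processes joined into a continuous pars-interarticularis
column between the facet bands. The whole construction is exactly
mirror-symmetric about the sagittal plane until unilateral cement is placed.

**Meshing.** A single 2D cross-section (elliptical rings plus the posterior
block) is swept along one global z-grid; every active prism splits into
three tetrahedra with diagonal rules that depend only on coordinates through
the mirror-invariant key (x, |y|), so meshes of symmetric geometry are
exactly mirror-symmetric element by element, interfaces are conforming
("fully bound" contact = shared nodes), and the mesh is bit-reproducible.
Quadratic TET10 elements are the default, matching the published element
type and avoiding volumetric locking against the ν = 0.499 nucleus.

**Materials** follow the published table verbatim; the model is osteoporotic
by default (cortical 8 040 MPa, cancellous 34 MPa, endplate 670 MPa — the
table prints 34 MPa although 67 % of the normal 132 MPa would be 88.4; both
values are exposed, the printed one is the default). Cement (3 000 MPa,
ν = 0.4) is fully bonded: cement cylinders re-tag the cancellous elements
whose centroids they contain, so all four experimental groups share one
discretisation and differ only in material assignment. This is a deliberate
departure from the published workflow, which re-meshed each group; it makes
the group comparison a controlled experiment on identical degrees of
freedom.

**Ligaments.** Seven groups (anterior/posterior longitudinal, ligamentum
flavum, supraspinous, interspinous, intertransverse, capsular) are vertical
truss elements between mesh nodes, tension-only, with the published Young's
moduli and total cross-sectional areas; each level receives the full
sectional area, split evenly across that group's trusses.

**Facet joints.** The published model used surface-to-surface contact with
friction 0.1. A tied (bonded) cartilage slab is available
(`facet_mode = "bonded"`), but bonding couples the slab's shear stiffness
(which resists flexion and bending) to its compressive stiffness (which
resists axial rotation) at the fixed isotropic ratio E/G ≈ 2.8, and no
geometry then reproduces the published motion pattern, where rotation is
2–4 times stiffer relative to flexion than bonding allows. The calibrated
default is therefore a *sliding* facet: a linearised contact layer of
bilateral springs across the cartilage gap that transmits transverse forces
but leaves the cranio-caudal glide free. Its three ingredients:

- normal springs (stiffness E·A/t of the cartilage layer) along the joint
  gap;
- crossed diagonal springs between neighbouring columns of the two
  articulating faces, the linearisation of the arcuate (curved-in-the-
  transverse-plane) facet surfaces that interlock against axial rotation;
  their share is set by `facet_curvature_ratio` (default 0.40 of the normal
  stiffness). Every spring acts along the line connecting its two nodes, so
  the layer is exactly self-equilibrated;
- a compression-only interspinous stop (midline, cartilage-grade stiffness
  over `interspinous_stop_area` = 140 mm²), the contact counterpart of the
  tension-only interspinous ligament: in extension the posterior elements
  approximate until the spinous processes abut. Its midline position gives
  it a large extension lever and no engagement in bending or rotation.

**Loads.** All six cases are force-controlled on the free T11 superior
surface: the 500 N preload as a consistent uniform traction, the 7.5 N·m
moment as a self-equilibrated nodal couple (net force zero, net moment exact
to 1e-10). A rigid-platen alternative (`build_rigid_coupling`) exists but is
not used by the runner: a platen forces the top of T11 to settle uniformly,
which measurably suppresses exactly the cement-asymmetry effects the study
is about. The L1 inferior surface is fully fixed. Sign conventions: +x
anterior, +y subject-left, +z superior; flexion is +7.5 N·m about +y,
extension −y, right bending +x, left bending −x, left rotation +z, right
rotation −z.

**Outcome measures.** Stress is evaluated at element centroids (for
straight-sided TET10 this equals the Gauss-point average), which keeps
maxima well defined without nodal extrapolation. The reported T12 maxima are
taken over the vertebral body (cortical shell, cancellous core, endplates,
cement), excluding elements that touch the loaded or fixed surfaces and
excluding the posterior elements: the idealised prismatic plates meet at
sharp re-entrant corners whose stress concentrations do not converge under
refinement and are insensitive to the cement — they are geometric artefacts
of the idealisation, and the published stress maps display the body.
Maximum T12 displacement is the nodal displacement magnitude (mm) over the
same body region. Segmental ROM is the relative rotation, about the load
axis, of least-squares rigid transforms fitted to the superior endplate node
sets of the two levels.

## 2. Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `body_width_ap` × `body_width_lat` × `body_height` | 30 × 42 × 24 | mm | vertebral body envelope (typical thoracolumbar) |
| `cortical_thickness`, `endplate_thickness` | 1.5, 0.5 | mm | fixed by the study description |
| `disc_height` | 10.3 | mm | calibrated: global compliance knob |
| `nucleus_fraction`, `nucleus_offset` | 0.4, 1.5 | –, mm | disc composition |
| `pedicle_sectors`, `pedicle_length` | 3, 6 | –, mm | posterior frame attachment width/offset |
| `process_thickness`, `block_depth` | 7, 6 | mm | articular-process stiffness (calibrated: rotation) |
| `cartilage_gap` | 0.21 | mm | facet layer stiffness (calibrated: rotation) |
| `facet_overhang`, `lamina_halfheight` | 3, 5.25 | mm | facet band height / frame root |
| `facet_curvature_ratio` | 0.40 | – | transverse interlock share (calibrated: rotation vs flexion) |
| `spinous_length` | 8.5 | mm | posterior ligament levers (calibrated: flexion) |
| `interspinous_stop_area` | 140 | mm² | extension stop (calibrated: extension) |
| `mesh_edge`, `cartilage_edge` | 5, 1.5 | mm | desk-scale density (published: 2, 0.5) |
| `preload`, `moment` | 500, 7.5 | N, N·m | fixed by the study description |
| cement dims / volume | printed boxes scaled to 6.0 mL | mm, mL | see section 4 |

## 3. Calibration of the range of motion

The study validated its CT-based model against published segmental ROM for
T11–T12, T12–L1 and T11–L1 in six directions. The synthetic anatomy has no
CT to inherit stiffness from, so the free geometric parameters above were
calibrated once, by coarse grid search (`calibrate_rom`), to the reference
ROM column — the procedure the package treats as part of the study
conditions. Validation runs apply pure moments (no preload): with the 500 N
preload active, the model's posterior mass distribution converts compression
into a sagittal tilt that contaminates the flexion/extension readings; the
runner records which protocol was used. After calibration all 18 values lie
within ±30 % of the reference and T11–L1 flexion (6.32°) falls inside the
printed corridor [6.26°, 6.60°] — re-confirmed by `run_validation()` in the
acceptance suite at every run.

Two posterior mechanisms were *added* during calibration because the initial
thin-plate idealisation could not reach the reference motion pattern in any
parameter combination; both are standard anatomy rather than free knobs: the
pars-interarticularis fill (without it, axial rotation is 2–3× too soft
because the articular processes hang from narrow strip roots) and the
interspinous stop (without it, extension is ~2× too lax because tension-only
ligaments provide no posterior compression path). The disc height lands at
10.3 mm, above the anatomical 6–9 mm: in this idealisation the disc absorbs
compliance that real segments distribute over endplate curvature, bony
microstructure and ligament laxity. It should be read as an effective
stiffness parameter, not an anatomical measurement.

A mesh-convergence study is available as `refine_study()`; the desk-scale
default (5 mm solids / 1.5 mm cartilage, ≈29 000 TET10 elements, ≈100 000
dof) solves a full six-case group in well under a minute, and the published
density (2 mm / 0.5 mm, ≈10⁵–10⁶ elements — the counts land in the published
range) remains available behind the same flag.

## 4. Cement geometry

The study description gives cylinder sizes of 10.5 × 10.5 × 18 mm
(unilateral) and 12 × 12 × 14 mm (bilateral) *and* "approximately 6 mL" per
augmented vertebra; no single reading of the printed sizes (diameters or
semi-axes) is consistent with 6 mL for both shapes. The package treats the
printed triplets as bounding boxes of elliptical cylinders and scales them
isotropically so each augmented vertebra receives exactly
`target_total_volume` (6.0 mL, split over two cylinders when bilateral).
One forced exception: the isotropically scaled unilateral cylinder is taller
than the cancellous cavity of a 24 mm body, so its height is capped (keeping
a 1.75 mm margin to the endplate and cortical caps) and the cross-section
alone is rescaled to preserve the volume. Unilateral cylinders sit at 25 %
of the cancellous lateral semi-axis (left = +y); bilateral pairs at ±45 %,
where the unilateral offset would make the pair interpenetrate. Placement
is validated against the cortical shell (every cement boundary point at
least one shell thickness from the outer surface) and is exactly
mirror-equivariant: mirroring a plan and reflecting the geometry commute.

## 5. Numerical machinery

- one sparse supernodal Cholesky factorisation per cement group (the mesh is
  shared; cement changes only element materials, so the stiffness is updated
  incrementally over the re-tagged elements);
- tension/compression-only elements: all trusses start active; after each
  solve, elements violating their sign condition are toggled until the
  active set is stable (cap 50 iterations, cycle detection). Removing a
  truss is a rank-one downdate, applied through a precomputed Woodbury basis
  (`W = K⁻¹U`, `G = UᵀW`), so no re-factorisation is ever needed; the
  active set is verified against brute-force enumeration on small systems in
  the test suite;
- element assembly is vectorised over elements and chunked to bound peak
  memory; the patch test (constant-strain fields reproduced to 1e-8
  relative, TET4 and TET10), a slender cantilever against Euler–Bernoulli
  theory (within 2 %), exact rigid-body modes, and global force/moment
  equilibrium at 1e-8 relative anchor the implementation;
- everything is deterministic: identical configurations give bit-identical
  meshes and summaries.

Degenerate inputs fail loudly: zero disc height, colliding posterior
dimensions, cement intersecting the cortex, unmeshable regions, singular
(under-constrained) systems, degenerate rigid fits.

## 6. What the generator does and does not emulate — and the honest result

The synthetic anatomy reproduces the features the study *fixes*: the
three-level column with its shell/endplate thicknesses, disc composition,
ligament table, material table, cement volumes and placements, load
protocol, and a motion envelope matching the published validation corridor.
It deliberately omits patient-specific features: curved endplates, nonuniform
cortical thickness, asymmetric vertebral shape, realistic articular
geometry, and the per-group re-meshing of the original workflow.

That omission turns out to be decisive for the comparative endpoint. In this
controlled setting (identical mesh, perfectly symmetric bone, cement the
only asymmetry), the effect of cement *distribution* on the sandwich
vertebra's peak stress is **below 1 %** in every load case, and the strict
published orderings (B-B < L-B < L-R < L-L for T12 stress and displacement)
do not emerge; the corresponding acceptance check is deliberately left
failing rather than weakened. Tracing the load path explains why: at cement
mid-height the axial force split between the left and right halves of an
L-L-augmented T11 differs by ~59 %, but the asymmetry collapses to ~1 % by
the time the load crosses the adjacent disc, because the nearly
incompressible nucleus (ν = 0.499) acts as a fluid cushion that equalises
pressure on the sandwich vertebra, and the stiff cortical ring carries the
remainder around the osteoporotic core. The published 10–15 % group
differences therefore require ingredients this stand-in intentionally lacks
— the interaction of cement with an asymmetric patient geometry, and
possibly the group-to-group mesh variation of the original pipeline (each
group was re-meshed; peak stresses at concentrations are mesh-sensitive).
Consistent with this reading, the published values themselves break the
strict order in rotation. What the model does reproduce: the order of
magnitude of the T12 peak stress, the exact mirror-equivalence of
reflected cement plans under reflected loads (a property the original could
not test), an extension that follows B-B < L-B < L-R < L-L, and T12/L1 disc
stress higher under L-L than B-B in four of six directions.

## 7. Known limitations

- Prismatic column: all three vertebrae share one cross-section; widths and
  cortical thickness cannot vary by level, discs share nucleus geometry.
- Linear kinematics: the 7.5 N·m rotations (~3–6°) stretch the small-angle
  assumption at the few-percent level; facet contact is linearised
  (no gap opening/closing geometry, friction dropped).
- The posterior elements are stiffness surrogates; their own stress fields
  are not meaningful (hence the body-restricted maxima).
- Absolute stress values are specific to this idealisation; only
  comparisons and orders of magnitude travel.
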
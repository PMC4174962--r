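---
title: "Volume-conductor fields and nerve activation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor fields and nerve activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the two-step
model, the numerical realization, the parameters that matter, what the
synthetic anatomy does and does not emulate, and the choices made where
the design was genuinely open.  It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The two-step model

Transcutaneous stimulation is simulated in two decoupled stages.

**Volume conduction.**  At stimulation-pulse time scales the tissue is
treated as purely resistive (the quasistatic approximation): a single
real conductivity per tissue, taken at the working point appropriate for
a 0.5 ms square pulse (about 2 kHz), governs the extracellular potential
through `div(sigma grad Ve) = 0`.  Muscle is transversely isotropic
(82.38 mS/m across, 329.53 mS/m along the limb z-axis); skin, fat,
cortical bone, bone marrow, blood and nerve-trunk tissue are isotropic
with the tabulated values in `tissue_conductivities`.  Current enters
and leaves through two square skin patches; every other boundary is
insulated (the surrounding air is not part of the problem).  Because the
equation is linear, one solve for unit injected current (the lead field)
suffices: the field at any amplitude is a scalar multiple.

**Fiber excitation.**  A straight myelinated fiber parallel to the limb
axis is discretized at its Ranvier nodes (McNeal's compartment cable).
The extracellular potentials sampled at the nodes drive the membrane
through their second spatial difference; node dynamics are the CRRSS
sodium-plus-leak description of mammalian nodal membrane at body
temperature; myelin is a perfect insulator by default.  An action
potential counts when the transmembrane deviation exceeds +80 mV at a
node well away from the stimulation focus, and the activation threshold
is the smallest cathodic pulse amplitude that achieves this, located by
bisection to a 10 uA bracket within the 5–500 mA search range.

## 2. Geometry representations

Three representations share one layer vocabulary (bone marrow, cortical
bone, muscle, fat, skin, innermost first; thicknesses from the two
tabulated subjects):

* **CM** — concentric finite cylinders.
* **PM** — a stack of rectangular slabs.  The tabulated geometry gives no
  slab width or limb length, so the package fixes: width = half the
  cylinder's outer circumference (comparable stimulated surface,
  negligible edge truncation), axial length 40 cm by default (63 mm
  fiber + electrodes + ample insulated-end margin), marrow at the bottom
  of a single one-sided stack with insulated bottom and sides.
* **PSEUDO\_AM** — the synthetic anatomy: the same stack with smooth
  low-order angular harmonics (<= 4, default peak amplitude 3 mm) on the
  muscle and fat boundaries, the skin following the fat boundary at
  constant thickness, an off-centre femur (default 11.24 mm toward the
  anterior sector, the magnitude of the tabulated bone-location
  adjustment), and two cylindrical inclusions: a blood vessel
  (700 mS/m) on the medial ray, 20.17 mm from the fat-muscle boundary,
  and a nerve trunk (29.89 mS/m) on the posterior ray at 30.07 mm, with
  cross-sections of 16% and 6% of the cortical-bone annulus.

Sites sit at 90-degree intervals: lateral +x, anterior +y, medial -x,
posterior -y (x runs medial to lateral, y posterior to anterior, z along
the limb).  Electrode pairs keep their centerline at z = 0 as the
edge-to-edge gap varies; the proximal (cathode) patch occupies negative
z, and the fiber midpoint sits beneath its centre.  On curved surfaces
the "square" patch is measured geodesically (arc length x axial extent).

The synthetic anatomy emulates the *structural features* an image-derived
model contributes — non-circular nested boundaries, an eccentric bone,
discrete high/low-conductivity inclusions at realistic distances — but
none of the following features of real limbs: multi-muscle
compartmentation and fascia, curved or branching nerve trajectories,
z-varying cross-sections, or subject-specific shape.  Tests passing on it
therefore demonstrate that the *pipeline logic* (field solve, sampling,
thresholding, error bookkeeping) responds correctly to anatomical
structure; they do not validate any particular human geometry.  The
inclusion distances are exact placement parameters here, whereas in
anatomy they are averages.

## 3. Numerical realization

**Discretization.**  All representations are extruded along z, so a
cell-centered 2-D cross-section is built once and replicated over the z
slices.  The cross-section grid conforms to the tissue boundaries:

* The radial representations (cylinder stack and pseudo-anatomy) use a
  mapped polar grid: every layer interface — including the perturbed
  muscle/fat boundaries and the offset cortical-bone circle, all
  single-valued radial functions of the angle — lies exactly on cell
  faces, so cells are pure tissue and refinement changes cell sizes
  smoothly.  A Cartesian voxelization of the same geometry leaves a
  staircase whose grid-phase noise keeps successive-refinement
  threshold changes at a few tenths of a percent, which is why it is
  not the default for the curved stacks (it remains available for
  comparison).  Two exceptions are handled by sub-cell sampling inside
  otherwise pure cells: the embedded vessel/nerve inclusions, and the
  marrow/cortical interface when the bone offset is too large for that
  circle to be star-shaped about the limb axis (the core is then
  meshed as one conforming band against the cortical outer boundary).
* The slab (PM) uses a Cartesian grid with directional sub-cell
  homogenization for layer faces that do not land on cell boundaries:
  a cut cell carries the arithmetic subsample mean for flow tangential
  to the layering and the harmonic mean (with void fractions
  shortening, not blocking, the series path) for flow normal to it;
  cells at least a quarter inside the model join the network with
  porosity-weighted conductances, so the conducting cross-section is
  carried by weights rather than cell counts.

Electrode couplings weight each surface face by the exact overlap of
its geodesic footprint with the patch rectangle, so the discretized
patch area equals the nominal area to rounding — the behaviour the
patch-area contract asserts.  Polar radial faces carry the series
conductance of the two half-cells they join; tangential, axial and
Cartesian faces the harmonic mean of the adjacent effective
conductivities.  The resulting system is a weighted graph Laplacian,
symmetric positive semi-definite with the constant null vector.  A
refinement level multiplies the target degree-of-freedom count by
2.08, and the realized counts are checked (with the target nudged up)
so each level has at least twice its predecessor's cells despite
ring/layer rounding.

Profiles are sampled smoothly: a cubic spline along z (the cable model
differentiates the profile twice along z, where piecewise-linear
interpolation would quantize the drive at the mesh scale), cubic
radial splines within the enclosing tissue layer plus Catmull-Rom
across angular columns on polar grids, and bicubic transverse
interpolation on Cartesian grids.  Every stage interpolates, so
sampling at a cell centre reproduces the stored value exactly.

**Solvers.**  Two routes solve the same weighted-graph-Laplacian system.
Whenever the load is known per cell — interior point sources and the
uniform-current-density electrode variant — the extrusion along z is
exploited exactly: expanding in the cosine eigenbasis of the axial
stencil decouples the solve into independent 2-D systems
(A2 + lambda_k diag(gz)), each factorized by a sparse Cholesky shared
across modes through a diagonal similarity.  This direct route reports
true residuals near machine precision and makes multi-million-cell
refinement levels cheap.  The floating-equipotential electrode couples
all slices through its two electrode nodes and therefore uses
Jacobi-preconditioned conjugate gradients (Rcpp) with the constant mode
projected out of every iterate — which simultaneously handles the
pure-Neumann singularity and fixes the zero-mean gauge — to a 1e-8
relative residual.

Electrodes default to the floating-equipotential formulation (each
patch's cells couple to one electrode node carrying the total-current
constraint); the uniform-current-density variant is a switch, because
the boundary treatment of conductive surface electrodes is genuinely
ambiguous at this level of description.  The two formulations agree on
thresholds to within a few percent.  The sweep and refinement layers
run the uniform-current variant: its per-cell load admits the exact
direct solve, and on the conforming polar grid the surface cells it
loads are pure skin, free of the partial-fill artifacts that make the
floating-patch contact mesh-sensitive for small patches on a
voxelized grid.  On the Cartesian slab grid the prescribed current is
instead deposited bilinearly at the exact skin-fat interface position
beneath each face (the resistive skin suppresses lateral spread, so
that is where the current physically enters the conductive interior),
which avoids the dependence on whether a surface cell happens to
homogenize skin alone or skin plus fat.  Currents of +1 A and -1 A
enter at the anode and cathode, so the stored potential is the
cathodic unit lead field (negative beneath the cathode).

**Verification.**  The solver is checked against an interior source/sink
pair in a homogeneous block: the sampled potential must match the
superposed closed form I/(4 pi sigma r) — coordinate-scaled,
V = I / (4 pi sqrt(st) sqrt(sl (x^2+y^2) + st z^2)), in anisotropic
muscle — within 3% at 5–20 mm from the poles.  Three details make this a
fair test of the discretization rather than of its artefacts: sources are
smeared over a 4.5 mm ball (ellipsoid in the conductivity metric), whose
exterior potential is *exactly* the point-source form while suppressing
the near-field error of the discrete Green function; the box spacing is
scaled along z by sqrt(sl/st) so the conductivity-scaled lattice stays
cubic; and the arbitrary gauge constant is fitted on the far samples.
Conservation (unit current through any separating plane), exact
linearity, and reciprocity under electrode swap complete the solver
contract.

**Cable integration.**  Semi-implicit stepping at 2 us: gates advance by
their exact exponential update at the current voltage, then the voltage
solves an implicit tridiagonal system with the ionic conductances frozen
at the new gates (Thomas algorithm in Rcpp).  This is uniformly stable at
the stiff nodal kinetics; halving the step moves thresholds by well under
0.5% (asserted).  With the CRRSS constants (gNa 1445 mS/cm^2,
gL 128 mS/cm^2, ENa +115.5 mV, c 2.5 uF/cm^2, rho_i 54.7 Ohm cm, rest
-80 mV) the leak reversal is re-derived so that rest is an exact
equilibrium of m_inf(0), h_inf(0) — this guarantees resting stability
independent of rounding in published constants.  The rate functions are
clamped to stay positive below -267 mV, far outside the physiological
range, to keep them total functions.

**Fiber geometry.**  Internode length = 100 x outer diameter, axon
diameter = 0.7 x outer, node length 1.5 um — the standard conventions,
config-exposed because the source geometry leaves them implicit.  The
node count is the largest odd integer fitting the 63 mm length, which
pins one node exactly beneath the cathode centre (8 um -> 79 nodes,
12 um -> 53, 16 um -> 39).  A passive-internode variant (10 compartments
per internode, constant membrane conductance) sits behind a switch; the
default is the perfect-insulator reading.

**Detection guard.**  The +80 mV criterion is applied to the deviation
from rest (consistent with a -80 mV resting potential) at nodes at least
five internodes from the most-depolarized node at the end of the pulse.
Without the guard, the local passive depolarization under the cathode
can cross any fixed voltage at high amplitude without launching a
propagating spike; with it, detection coincides with propagation to the
fiber ends.

## 4. Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| pulse width | 0.5 | ms | the studied stimulation pulse |
| amplitude search range | 5–500 | mA | studied range; out-of-range results are flagged, never clamped |
| bisection bracket | 0.01 | mA | the 10 uA threshold-accuracy contract |
| fiber depth below fat-muscle boundary | 5 | mm | the anatomical average used by the source studies is not published; config input |
| time step | 2 | us | < 0.5% threshold shift on halving |
| electrode areas / gaps | 1–25 cm^2, 0–6 cm | | studied grids; values outside warn |
| field-solve residual | 1e-8 | relative | iterative-solver contract |
| refinement start | 2e5 | DOF | convergence-protocol start, then x2.08 per level |
| boundary-perturbation amplitude | 3 | mm | "tissue irregularity" scale; <= 4 angular harmonics |

## 5. Problem sizes used by the tests and scripts

The suite and the acceptance script run on one CPU; sizes were chosen as
the smallest at which each scientific statement is cleanly resolved.
Field oracles use ~1.6e6 cells (1.8 mm transverse spacing).  The
convergence protocol runs the 2e5-start doubling ladder under the
uniform-current electrode formulation (the direct separable solve keeps
the multi-million-cell levels tractable) until successive thresholds
differ by less than 0.1%; note that the 10 uA bisection bracket itself
quantizes reported thresholds at about 0.02%, which is the protocol's
intrinsic resolution.  Representation comparisons use 5e5-cell grids:
the smallest studied electrode (1 cm^2) then spans several cells per
side, below which its absolute threshold is noisy at the +/-10% level
and the PM-vs-CM ordering unreliable — for electrodes of 9 cm^2 and
above the ordering and the >0.99 curve correlation are robust far
coarser.  The omission study uses 3.5e5 cells on 24 cm-long models,
enough to resolve both inclusions (the 3 mm nerve trunk is the binding
one) with at least two cells across.  The geometry metrics are
analytic.

## 6. Design choices where the design was open

* **Electrode boundary condition** — equipotential patches with a
  total-current constraint as default, uniform current density as a
  switch: conductive electrodes are closer to equipotential, but the
  source description names both boundary types without resolving them.
* **Gauge** — zero mean over the domain rather than grounding a node:
  both electrodes carry current, so no physical ground exists.
* **Lead-field scaling** — the amplitude search scales one unit solve;
  mathematically identical to re-solving per amplitude and ~16x cheaper;
  a solve counter keeps the claim auditable.
* **Activation error** — unsigned relative percent as primary (the
  directionless reading of the source definition), signed retained in
  the tables for over/under-estimation analysis.
* **Cross-correlation** — Pearson at zero lag: the compared curves share
  an abscissa, so lagged correlation has no meaning.
* **Geometry metrics** — the fat thickness and bone-to-muscle distance
  are radial measures averaged over the site's +/-45 degree window (and
  over z, which is exact for the extruded generator).  A bone shift of
  s therefore moves the window average by s x mean(cos) ~ 0.90 s; the
  adjustment operator solves for its target by root finding on the
  *re-measured* average, so targets are recovered to better than
  0.05 mm regardless.
* **Distance-sweep grids** — the source states two readings of the
  interelectrode-distance range (1–6 cm and 1–60 mm in 5 mm steps); the
  sweep runner takes an explicit gap list so either is reproducible.
* **PM slab width / axial length** — see section 2; both config-exposed.
* **Default bone offset** — 11.24 mm anterior: the one printed
  bone-location magnitude; documented as a modelling default, not an
  anatomical claim.
* **Inclusion distance convention** — measured from the fat-muscle
  boundary to the inclusion *surface* along the site ray, matching the
  boundary-to-boundary reading of the printed averages.

## 7. Degenerate inputs and tie-breaks

Zero fiber depth places the trajectory exactly on the fat-muscle
boundary (accepted); zero-length z-ranges measure a single section;
single-amplitude monotonicity checks are trivially monotone; a constant
threshold curve has no defined correlation and returns NA with a
warning; a predicate already active at the lower bracket end extends
once down to 0.1 mA before flagging `out_of_range = "low"`; sweeps record
per-configuration failures (with reasons) and never abort; under-resolved
inclusions are refused with the level that would resolve them.
Thresholds report the final bracket midpoint — the minimax choice for a
single reported number.

## 8. Known limitations

* The voxelized curved boundaries converge more slowly than a
  boundary-fitted mesh would; the convergence protocol exists precisely
  to bound this, and coarse-grid thresholds on curved stacks are
  systematically a few percent low (visible in `analysis/03`).
* No frequency-dependent (dispersive) tissue behaviour; the single-
  conductivity working point is an input, not a result.
* No electrode-skin interface impedance; the contact layer is the half-
  cell of skin beneath each patch.
* Straight axial fibers only; recruitment of fiber populations, biphasic
  or charge-balanced waveforms, and statistical significance testing of
  the error tables are out of scope — the tables are written tidy so any
  stats package can consume them.
* The pseudo-anatomy is a structural stand-in, not a subject; absolute
  activation errors against it are not comparable to errors against an
  image-derived model, though their *pattern* (growth near omitted
  inclusions, locality) is the behaviour under test.
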
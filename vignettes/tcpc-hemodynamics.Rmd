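---
title: "Hemodynamic assessment of total cavopulmonary connections: models, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic assessment of total cavopulmonary connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`tcpcflow` post-processes time-resolved velocity and pressure fields on
tetrahedral meshes of a total cavopulmonary connection (TCPC): the Fontan
pathway (FP) and superior vena cava (SVC) as inlets, the left and right
pulmonary arteries (LPA, RPA) as outlets, and everything else wall. It does
not solve flow equations; it consumes solutions (from any rigid-wall or
fluid–structure solver, via VTK/VTU series) or fields from its own synthetic
generator, and computes wall-deformation, energy and particle-transport
metrics plus rigid-versus-compliant comparisons.

All internal arithmetic is SI (m, s, Pa). Reporting units follow clinical
convention — cm² for areas, mL and mL/s for volumes and flows, mmHg for
pressures (1 mmHg = 133.322 Pa, applied only at reporting boundaries), mW
for power.

Physical defaults are the standard resting Fontan values: blood density
1000 kg/m³, kinematic viscosity 3.5·10⁻⁶ m²/s, cardiac period 0.86 s.

## Wall-deformation metrics

Cross-sectional areas are computed by exact plane/tetrahedron intersection
at each frame's node positions; the per-cell cut polygons are triangulated
in-plane (shoelace). The cut must form a single face-connected component
within the named branch; anything else is rejected as an ill-posed section.
The deformation index of an area waveform is

$$DI = \frac{A_{max}-A_{min}}{\bar A}\times 100\%$$

with $\bar A$ the **arithmetic mean of the sampled areas** (the data from
which such indices are usually quoted are uniformly sampled cine series, so
the arithmetic mean is the natural reading of "average area"; a waveform
with mean 3.74 cm² and cyclic change 0.20 cm² gives 5.3 % at one decimal).
DI is reported to one decimal in summaries.

Net flow is the sum of inlet boundary fluxes minus outlet boundary fluxes;
the cavity volume is its cumulative trapezoidal integral, and the compliance
estimate divides the peak-to-peak volume change by the peak-to-peak
**volume-averaged** pressure change. Volume averaging weights nodal
pressures by cell volume (nodal values averaged per tet, weighted by tet
volume) — the discretization-agnostic reading of "pressure averaged over the
volume".

## Energy metrics

The pressure drop between two caps is the difference of **area-averaged
static pressure** over the cap facets. Whether such drops should be
area-averaged or mass-flow-weighted is genuinely open; area averaging is the
more common post-processing choice and is independent of the instantaneous
flow profile, so it is the default (a flow-weighted variant would be a small
extension of `patchAverage()`).

Power loss uses the control-volume mechanical-energy flux

$$PL = -\sum_{caps}\int_A \left(p + \tfrac12\rho\lVert v\rVert^2\right)
  (v\cdot\hat n_{out})\,dA,$$

not the volumetric viscous-dissipation integral: the flux form needs only
boundary data, and its instantaneous values may legitimately be negative
under pulsatile flow (energy temporarily stored in the control volume),
which matches how such waveforms are reported. Facet integrals use the
edge-midpoint rule, exact for quadratic integrands. Cycle summaries
(min/max/trapezoid-average) are taken over the **last stored full cycle**;
sub-cycle series are rejected.

On the synthetic junction the power-loss average can itself be negative:
the generator's blended field is kinematic, not a Navier–Stokes solution,
so its boundary energy flux has no positivity guarantee. The analytic
positivity check lives on the Poiseuille fixture, where $PL = \Delta P\,Q$
to within the flux discretization error.

## Particle transport

Particles are seeded at the interior nodes of the seed-cap cross-section,
inset 5 % of the cap radius into the domain, with a small seeded lateral
jitter (2 % of the cap radius by default) so that mirror-symmetric
geometries do not place seeds exactly on symmetry planes. The reference
protocol (700 seeds per event, every 1 ms, for one 0.86 s cycle, tracked
five further cycles) is expressible directly; tests and the default
comparison preset use reduced counts (tens of seeds per event at 20–40 ms
intervals) so the whole suite runs in about half a minute on one CPU.

Advection is classical RK4 with velocity interpolated barycentrically in
space and linearly in time; stored frames cover one period and are extended
periodically (the natural reading of a cycle-resolved periodic solution).
On moving meshes the node positions are interpolated in time the same way,
and the stored velocity already contains the mesh-motion component at the
wall. Numerical choices that matter:

- **Cell location.** A neighbor-walking locator seeded by the particle's
  previous cell, with a bounded breadth-first search fallback for points the
  walk wedges on (corner cells with two boundary faces), and an exhaustive
  scan for initial seeding and as a reference implementation
  (`locator = "scan"`); a property test asserts walk/scan equivalence
  particle-for-particle. Barycentric containment tolerance is 1e-10.
- **Exits.** A cap crossing is detected from the sign change of the signed
  distance to the cap plane over a substep, within 1.15 cap radii laterally;
  the exit time interpolates the crossing linearly within the substep.
- **Walls.** A substep that would leave the domain through the wall is
  bisected back to the interior and the unconsumed displacement is slid
  along the wall plane (projected off the outward face normal; off both
  normals at wall edges), with a small pull toward the cell interior. This
  no-flux treatment conserves particle count — particles are never deleted
  at walls — and lets near-wall particles creep through tapering sections
  instead of pinning. Particles are marked `stranded` only if they can no
  longer be located at all (possible in principle under mesh motion).
- **Washout clock.** `W95` is the earliest *absolute* time by which 95 % of
  the seeded particles have exited, with the clock starting at t = 0 — this
  matches quoting washout in "number of cardiac cycles" as time/period. If
  fewer than 95 % exit within the horizon, `W95` is `NA` and the achieved
  fraction is reported.
- **HFD binning.** Instantaneous %HFD(LPA) attributes each particle's fate
  to its *seed* time and uses a sliding window over the seeding cycle
  (default 50 ms), since the instantaneous curve is usually plotted against
  the injection phase; exit-time binning would be a trivial variant.
  Particles that leave through the caval caps (backflow) count as exited for
  washout but are excluded from the HFD denominator, which is defined over
  lung-bound flow.

## The synthetic generator

The generator stands in for patient-specific CFD/FSI solutions. The
geometry is a central junction box (half-width 0.9 × the largest branch
radius) with four tube arms whose cross-sections morph smoothly from the
box face to exact circles over 35 % of the arm length, meshed as structured
hexahedra split into tetrahedra by the Kuhn decomposition (conforming,
watertight by construction, verified by the validity checks). Default radii
(FP 1.09, SVC 0.80, LPA/RPA 0.60 cm) give the cap areas typical of an
adolescent Fontan (FP ≈ 3.7 cm², SVC ≈ 2.0 cm²); arm lengths are 2.5–3 cm.
A lateral caval offset shears the FP arm smoothly.

Inflows are Fourier series $Q(t)=\bar Q[1+\sum_k a_k\cos(k\omega t+\phi_k)]$
— the patient waveforms behind such studies are not tabulated, so no
figure-derived numbers are embedded; the defaults (FP 30, SVC 20 mL/s,
first-harmonic amplitudes 0.30–0.35) give a resting venous return of
3 L/min with mild, strictly positive pulsatility. Outlet flows split the
instantaneous total by the LPA fraction λ (default 0.5).

Within each branch the velocity is an axial profile
$u \propto 1-(1-s)\rho^2$ carrying the branch's instantaneous flow, where
$\rho$ is the normalized radial coordinate and $s$ is a small **wall-slip
fraction** (default 0.05, profile renormalized to carry the exact flow).
The slip is a deliberate regularization: in a strictly no-slip *kinematic*
field, tracer particles near the wall advect arbitrarily slowly and freeze
entirely inside boundary cells whose four nodes all lie on the wall, so
desk-scale washout would never complete for near-wall seeds. Real unsteady
flows redistribute near-wall fluid by recirculation and wall motion; the
slip emulates that at the 5 % level. Set `wall_slip = 0` for strict no-slip.
The junction box blends the four branch fields with inverse-square-distance
partition-of-unity weights; the blend is smooth and exactly matches each
branch field on its face, but it is **not divergence-free** and has no
closed form — analytic assertions deliberately exclude the blended region.

Pressure is a per-branch linear drop with Hagen–Poiseuille resistance
$8\mu/(\pi R^4)$ per unit length, continuous across the junction (blended
the same way). Mass closure at the caps is exact by construction in rigid
mode; because all four caps share one logical grid, the discretization error
of the flux integral is a common factor that cancels in ΣQ_in − ΣQ_out, so
rigid net flow is zero to rounding.

In moving mode the FP arm wall (and interior nodes) scale radially by
$1+\epsilon\sin(2\pi t/T)\,\phi(s)$ about the arm centerline, where $\phi$
is a sine-squared axial window (default 0.45–0.85 of the arm length) that
vanishes well before the caps — caps stay fixed, and the window is
restricted to the circular part of the arm so area and volume change in
closed form:

$$\Delta V(t)=\pi R^2 L_w\,\epsilon q\left(1+\tfrac38\epsilon q\right),
\qquad q=\sin(2\pi t/T),$$

with exact derivative `movingVolumeRate()`. Outlet flows are reduced by
this dV/dt, so global mass balance holds exactly at the caps. The default
amplitude ε = 0.013 comes from the thin-wall (Laplace) map
`stiffnessToAmplitude()` at a Young modulus of 0.07 MPa, Poisson-type
thickness 2 mm and an effective transmural pressure amplitude of 1.25 mmHg,
chosen once so that the default stiffness yields a Fontan-pathway DI of
about 5 % — the magnitude seen in compliant intra-atrial pathways. Because
the wall moves as $+\sin$ while the default inflow's first harmonic is
$+\cos$, dV/dt is in phase with the inflow surplus and the motion acts as a
genuine compliance: it damps the outlet-flow — and hence pressure-drop and
power-loss — fluctuations, reproducing the qualitative rigid-vs-compliant
contrast. What the generator does **not** emulate: secondary/swirling flow,
caval flow collision and vortex dynamics in the junction, and the
boundary-layer redistribution by which a genuinely compliant wall
accelerates particle washout — so the washout-time *ordering* between rigid
and compliant runs is reported by `runComparison()` but not asserted, and
passing tests say nothing about washout magnitudes in real anatomies.

Determinism: the mesh and fields are deterministic for a fixed
configuration; the only randomness (seed jitter, node subsampling) is
governed by the configured seed.

## The lumped compliant-chamber surrogate

A single chamber of compliance C (mL/mmHg) fed by both caval inflows and
drained through two linear resistances to a common downstream pressure:

$$C\frac{dP}{dt}=Q_{FP}(t)+Q_{SVC}(t)-\frac{P-P_{out}}{R_{LPA}}
 -\frac{P-P_{out}}{R_{RPA}},\qquad V(t)=C\,P(t)+V_{ref}.$$

This is the minimal topology that carries the compliance estimate
(`estimateCompliance()` applied to the simulated V and P recovers the
configured C exactly, by the linear V–P relation) and the
fluctuation-damping contrast: at periodic steady state the mean transmural
pressure and the flow split $R_{RPA}/(R_{LPA}+R_{RPA})$ are independent of
C, while the pressure fluctuation amplitude follows the first-order
low-pass response $|H|=R_\parallel/\sqrt{1+(\omega R_\parallel C)^2}$. No
patient downstream pressures or pulmonary resistances are available, so the
defaults (R = 0.3 mmHg·s/mL per lung, P_out = 10 mmHg) are documented
placeholders and every assertion about the surrogate is C-relative, never
absolute. The integrator is Crank–Nicolson with a closed-form linear update
(second order; dt ≤ period/100 enforced, default period/400), which meets
the 1 % frequency-response check; the rigid case C = 0 is solved
algebraically and is exact. The chamber is a surrogate and is labeled as
such in outputs; it makes no claim to predict 3D fields.

Stiffness calibration (`calibrateStiffness()`) solves DI(stiffness) = target
by bracketing bisection (monotone-decreasing forward model required, 100
iteration cap, relative tolerance 1e-3). The packaged forward model maps
stiffness → wall-motion amplitude (Laplace scaling) → DI (closed form
$DI = 400\epsilon/(1+\epsilon^2/2)$); an end-to-end test replays the
calibrated amplitude through the mesh, the area waveform and
`deformationIndex()` and recovers the target within 0.2 percentage points.

## Numerical tolerances and problem sizes

Discretization errors of the cap-flux and power-loss integrals scale as
O(h²) in the cross-sectional edge length (polygonal-cap area deficit plus
linear interpolation of the quadratic profile). The test fixtures are sized
so each assertion's discretization error sits well inside its tolerance:
the 1 % Hagen–Poiseuille checks run on a 0.5 mm pipe mesh (measured error
≈ 0.6 %), the 1 % moving-wall net-flow check on a 1 mm junction mesh
(≈ 0.6 %), while topology/locator oracles use sub-5000-cell meshes where
exhaustive search is affordable. Cross-section cuts for deformation-index
assertions are placed on mesh stations, where the prescribed radial scaling
of the cut polygon is exact. Particle-transit assertions seed on interior
grid nodes, where the interpolated Poiseuille profile is nodally exact, so
the 0.1 % transit check isolates integrator and exit-detection error.
The default test run uses meshes of 2.4 k–300 k cells, 9–25 frames per
cycle, and 40–240 particles per tracking study; the full suite completes in
roughly half a minute on one CPU.

Degenerate inputs are rejected early with named errors: non-positive cell
volumes, non-watertight boundaries, non-monotone frame times, field/node
cardinality mismatches, NaN fields, empty waveforms, zero pressure ranges,
sub-cycle summaries, substeps larger than the frame interval, seeding planes
outside the domain, and calibration targets outside the attainable range.

## Interfaces

The package's functions are its interface: `readFieldSeries()` /
`writeFieldSeries()` for VTK-legacy/VTU series with a YAML manifest (patch
labels travel in a facet sidecar table, since neither format standardizes
boundary labeling), `runComparison()` for the paired rigid/compliant
workflow with JSON/CSV bundles, and `refinementStudy()` for the
mesh-sensitivity harness. Scripted pipelines call these directly from
`Rscript`; `scripts/acceptance.R` is an example of exactly that pattern.

## Known limitations

- The synthetic junction flow is kinematic: not divergence-free off the
  caps, no junction vortices, no swirl; control-volume power loss on it can
  be negative on average.
- The wall-slip regularization (5 %) biases near-wall residence times short
  relative to a true no-slip boundary layer.
- Washout and HFD statistics at desk-scale particle counts carry binomial
  noise of a few percentage points; tests use 3σ bounds.
- The 0D chamber has no inertance and a single pressure node; it cannot
  represent wave propagation or branch-wise pressure differences.
- Flow extensions sometimes added upstream of such junctions for boundary
  independence are not modeled; all metrics operate between the cap planes.
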
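---
title: "Immersed finite element methods in ifem2d: models, discretization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immersed finite element methods in ifem2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ifem2d` simulates a deformable solid moving through a viscous fluid without
ever fitting the fluid mesh to the solid: the fluid lives on a fixed
(Eulerian) triangulation of the whole computational domain, the solid on its
own moving (Lagrangian) triangulation, and the two exchange information only
through interpolation of velocities and distribution of forces.  This
vignette explains the model equations the package discretizes, the three
coupling algorithms it provides, the numerical choices behind them, and what
its synthetic test problems do and do not demonstrate about real systems.
All quantities are CGS (cm, g, s, dyn).

## The overlapping-domain picture

The whole domain Ω is filled with fluid of density ρ^f and viscosity µ, even
where the solid sits.  The region covered by the solid therefore contains an
*artificial fluid* co-occupying the solid's volume.  The effect of this
fictitious material must be removed, and the solid's actual mechanics
inserted, through an interaction body force f^FSI applied to the fluid.  The
force is first evaluated on the solid nodes and then spread onto fluid nodes
with an interpolation kernel φ; fluid velocities travel the opposite way
with the transpose of the same kernel.  Storing the kernel as a sparse
matrix Φ (one row per solid node, rows summing to one) makes velocity
interpolation `Φ v` and force spreading `Φᵀ F` exact adjoints, so the total
spread force always equals the total solid force to machine precision —
these two identities (partition of unity and conservation) are asserted at
1e-12 in the test suite.

Two kernels are built in.  The default is the *sharp finite element* kernel:
the weights are the P1 shape functions of the fluid element hosting each
solid node, which gives at most three nonzeros per node, exact reproduction
of linear fields, and conservation by construction on arbitrary unstructured
meshes.  A smoothed cosine discretized-delta kernel (support radius two
element sizes, renormalized to sum one) is available for comparison; the
reproducing-kernel option is recognised but deliberately not implemented.
The kernel depends on the current solid position, so it is rebuilt every
step.

## Fluid solver

The fluid is incompressible Navier–Stokes discretized with equal-order
linear triangles for velocity and pressure.  Equal-order pairs are not
inf-sup stable on their own, so the solver uses SUPG/PSPG residual
stabilization with the standard element parameter

τ = ( (2/Δt)² + (2|v|/h)² + (12 ν/h²)² )^{-1/2} / ρ,

where h is the element length scale and ν = µ/ρ the kinematic viscosity.
Time stepping is implicit backward Euler; the convective term is linearized
by Picard iteration with adaptive under-relaxation (the update is damped
whenever the iteration residual grows, which extends convergence into
convection-dominated and high-density-contrast regimes).  A step that uses
all iterations is accepted if its final relative change is below 1e-2 and
rejected as diverged otherwise.  The viscous term is kept in gradient
(Laplacian) form, so "traction" boundary conditions impose the
pseudo-traction −p n + µ(∇v)n of the do-nothing family — the form for which
a traction-free outflow is exactly consistent with fully developed channel
flow.  When no traction or outflow segment exists the pressure is gauged by
pinning one node.

Three solver variants share one assembly path:

* **plain**: constant density ρ^f everywhere (the explicit algorithm);
* **effective density**: the momentum equation uses the nodal field
  ρ̄ = ρ^f + (ρ^s − ρ^f) I(x), and gravity enters as ρ̄ g, so the overlap
  carries the solid's inertia and weight implicitly (the semi-implicit
  algorithm); with ρ̄ ≡ ρ^f and no interaction force this reduces exactly to
  the plain operators (asserted in the tests);
* **pseudo-compressible**: the continuity equation gains the lumped term
  (1/κ^s)(∂p/∂t) I(x) on nodes inside the overlap, so the pressure can
  accommodate solid volume change; κ^s defaults to the plane-strain bulk
  modulus of the solid and as κ^s → ∞ the incompressible solution is
  recovered (asserted at 1e-6 relative).

## Indicator function

The indicator I(x) distinguishes real fluid (I = 0) from overlapped solid
(I = 1).  Rather than a staircase element flag, it is obtained by solving a
Poisson problem ∇²I = ∇·G on the fluid mesh, where G is the solid's outward
boundary normal field spread onto fluid nodes by midpoint quadrature over
the boundary loop(s).  Fluid nodes further than a safety band (default 1.5
element sizes) from the interface are clamped to 0 outside and 1 inside
(point-in-polygon plus distance tests against the current boundary
polygon); the solve then produces a smooth 0-to-1 transition across the
interface.  Small over/undershoots are clipped to [0, 1] and logged.  For a
disc in a box the integral of I recovers the disc area to well under the 5%
the acceptance suite demands.

## Solid mechanics

Solids are plane-strain, linear triangles.  Three constitutive kinds are
provided: linear elastic (isotropic Hooke), Kelvin–Voigt viscoelastic
(σ = c ε + η ε̇, with the viscous stress acting componentwise on the tensor
strain rate), and compressible Mooney–Rivlin evaluated from the full
deformation gradient (finite strain; volumetric penalty κ^s(J − 1)).  The
small-strain kinds use the infinitesimal strain on the reference
configuration with no co-rotational correction — a documented validity
limit: rigid rotations of finite angle produce spurious stress, so these
kinds are trustworthy only while strains and rotations stay small.  Internal
forces are the weak-form divergence of the element stress (exactly minus
the strain-energy gradient, checked against central differences), layered
materials are realized through an element-wise stiffness scale (used by the
two-layer fold case, body layer four times stiffer than the cover), and
structural dynamics uses trapezoidal Newmark (β = 1/4, γ = 1/2), which is
unconditionally stable and conserves energy for undamped linear problems.

## The three coupling algorithms

All three orchestrators advance one staggered pass per time step, with no
sub-iteration to mutual convergence within the step.

**Explicit IFEM** evaluates the interaction force on the previous solid
configuration,

f^FSI,s = −(ρ^s − ρ^f) ü + (∇·σ^s − ∇·σ^f) + (ρ^s − ρ^f) g,

spreads it, solves the fluid, and then *sets* the solid velocity to the
interpolated fluid velocity and moves the solid by u ← u + v Δt.  The solid
acceleration is estimated by backward difference of the interpolated
velocities (zero at the first step).  Each term of the force contributes a
coupling error proportional to Δt times a property ratio — ρ^s/ρ^f − 1,
K/ρ^f, (ρ^s/ρ^f − 1)g — so the algorithm is only conditionally usable:
`coupling_error_estimate()` reports these ratios, and the acceptance suite
demonstrates the divergence at density ratio 1000 directly.

**Semi-implicit IFEM** keeps only the internal mismatch
f^FSI,s = ∇·σ^s − ∇·σ^f in the force; inertia and gravity move into the
momentum equation through ρ̄.  The stiffness ratio governing the remaining
explicit part becomes K/ρ^s instead of K/ρ^f, which is what buys the larger
stability range: on the falling-disc configuration at density ratio 1000
(air against tissue-density solid, Δt = 2·10⁻⁵ s) the explicit update blows
up within a couple of steps while the semi-implicit one completes 200 steps
bounded.

**Modified IFEM (mIFEM)** inverts the kinematic roles: the solid momentum
equation ρ^s ü = ∇·σ^s is *solved* (Newmark) with boundary data
interpolated from the previous fluid state, and the artificial fluid is
driven to follow the solid.  The solid velocity is never overwritten by
interpolation.  The fluid sees the semi-implicit force plus a correction
force f^Δv = ρ^s(Dv^s/Dt − Dv^f/Dt), which vanishes exactly when the
overlap fluid already moves with the solid; the overlap continuity equation
is pseudo-compressible with the solid's κ^s.

Two design choices here were genuinely open:

* *Solid boundary data.*  The fluid can drive the solid either through a
  Dirichlet displacement increment u ← u + v^f Δt on the wetted boundary or
  through the interpolated fluid traction σ^f·n.  Both are implemented; the
  default is the traction form, which lets the solid's own dynamics respond
  to the load instead of being kinematically slaved — for wall-attached
  bodies such as the fold pair this is the physically meaningful choice.
  The traction is applied with n the outward solid normal (traction
  continuity); a sign convention tied to the fluid-outward normal appears
  in some statements of the same condition and is reconciled by this
  physical reading.
* *Correction-force discretization.*  Evaluating Dv^f/Dt from the two
  previous fluid states makes the correction force a one-step-delayed
  negative feedback on the overlap velocity — a marginally stable two-cycle
  that divergence tests showed to be unusable in the staggered loop.  The
  implementation therefore discretizes the same force implicitly inside the
  fluid solve: the time part contributes ρ^s-weighted masses (distributed
  through the kernel) to the momentum diagonal, and the convective part is
  taken from the current Picard iterate, so at convergence the whole
  material derivative is evaluated at the new time level.  The explicit
  `correction_force()` operation is retained and used for the algebraic
  identity checks.  Enabling the correction measurably tightens the
  interface no-slip match (the acceptance suite compares 50-step runs with
  it on and off).

## Evaluating the fluid stress divergence on the solid

The term ∇·σ^f in the interaction force deserves its own discussion because
the obvious discretizations fail.  Assembling the weak residual of σ^f on
the fluid mesh and interpolating it to the solid re-injects the previous
interaction force exactly — by discrete momentum balance the fluid residual
*contains* f^FSI,f — so grid-scale noise accumulates with unit gain and
every configuration tested diverged after a few dozen steps regardless of
Δt.  Instead, the fluid velocity is interpolated to the solid nodes, the
viscous stress formed on the solid elements, recovered to solid nodes by
lumped L2 projection, and the divergence of that recovered linear field
integrated as nodal loads.  Only the volume term survives: the fluid stress
is smooth across an immersed interface, so no surface (traction-jump) term
belongs to it, and keeping one (for example by integrating by parts)
manufactures an artificial ring of interface forces out of the smooth
pressure field.  By default the pressure is excluded from σ^f in this term
altogether: for an incompressible medium the pressure is one shared
Lagrange-multiplier field for solid and artificial fluid alike and cancels
in σ^s − σ^f; an `include_pressure` flag restores the full form for
experimentation.

## Robustness guards

Two guards keep long demo runs alive after local events that would
otherwise end them, at a documented cost in local fidelity:

* a *strain saturation cap* (off by default; the cell case uses 0.5) clamps
  the strain entering the stress evaluation, preserving the direction but
  bounding the magnitude of restoring forces once an element is deformed
  beyond small-strain validity — regions that engage the cap are
  qualitative only;
* a *wall-penetration clamp* pulls any solid node that steps through a
  no-slip wall in one advection step back to its last interior position
  along its path (bisection), since an impenetrable wall admits no
  through-flux and the overshoot is purely a time-discretization artifact.

A CFL guard warns once per run when max|v| Δt/h exceeds a configurable
bound, and per-step diagnostics (divergence norm, force-conservation
residual, Picard iterations, minimum solid element area, indicator clipping,
no-slip residual, solid centroid) are recorded for every step.

## Demo cases and what they show

**Cell in a bifurcated microvessel** (explicit IFEM).  A soft viscoelastic
disc of radius 2.66 µm is released on the axis of an 8 µm mother vessel
carrying plasma-like fluid (ρ = 1.03 g/cm³, µ = 0.012 g/(cm·s)) at 0.1 cm/s
mean inlet speed, with branch angles π/4 and 3 µm fillets.  The daughter
widths are not fixed by the physical description beyond their ratio; the
generator sets w1 + w2 = 1.8 w0 (total lumen cross-section grows across
microvascular branch generations) so that both daughters remain passable
for the cell — under Murray's law the narrow daughter of the 1.44 case
would be narrower than the cell itself, which contradicts the observed
traversal the case is meant to reproduce.  Outlet flow splits are imposed
as parabolic velocity profiles scaled to Q1/Q2 against the discrete inlet
flux; the perfusion is established by a steady solve before coupling
starts.  The cell's Young modulus (200 dyn/cm² at desk scale, ν = 0.45,
small Kelvin–Voigt viscosity) is chosen inside the explicit algorithm's
stability envelope at Δt = 2·10⁻⁵ s on the h = 0.85 µm mesh.  The run stops
just after the cell centroid passes the rounded apex nose and reports the
branch as the sign of the transverse centroid coordinate there.

With a 3:1 flow split in a symmetric vessel the cell reliably exits the
high-flow branch, and the fully symmetric control drifts less than a sixth
of an element size before the junction — discretization noise does not
pre-select a branch.  The equal-flow asymmetric case (w1/w2 = 1.44) does
*not* reproduce the expected selection of the narrower, faster branch at
this fidelity: for any branching construction with symmetric centerlines
the inner-wall intersection sits about 0.9 µm on the narrow-branch side of
the axis, the axis-released cell therefore meets the junction on the wide
branch's side of the stagnation point, and the finite-size suction toward
the faster branch does not overcome that geometric bias with a small-strain
cell; the cell drifts toward the narrow branch on approach (about −0.8 µm)
but finally enters the wide one.  The corresponding acceptance expectation
is left failing rather than re-tuned; resolving it would need the exact
source geometry (published only as a figure) or a finite-strain
membrane-type cell model, both out of scope.

**Self-oscillating fold pair** (mIFEM).  Two mirrored two-layer trapezoidal
bodies (cover E = 10 kPa, body E = 40 kPa, ρ^s = 1 g/cm³, ν = 0.3,
Kelvin–Voigt damping) are attached to the walls of a 2 × 1 cm air channel
(ρ^f = 1.3·10⁻³ g/cm³, µ = 1.8·10⁻⁴ g/(cm·s); solid/fluid density ratio
about 770) driven by a constant inlet pressure.  The demo defaults to 2% of
the 1 kPa reference drive and a 60-step horizon at Δt = 10⁻⁵ s — enough to
show the opening phase of the glottis (half-widths Gw grow from the
geometric gap, volume flow rate develops) on a one-minute desk run while
staying inside the Picard solver's robust regime; the full drive produces a
glottal jet at cell Reynolds numbers that the coarse default mesh cannot
carry.  Because the fold geometry is parametric (the source gives only
coarse overall dimensions), the oscillation frequency of a long-horizon run
is a property of this package's geometry, not a reproduction of any
published value; the `spectrum()` helper that would measure it is tested
against synthetic tones instead, including a 234 Hz test tone at 10 kHz
sampling.

## Problem sizes and determinism

The bundled tests and the acceptance script run on meshes of a few hundred
to a couple of thousand nodes with horizons of tens to a few thousand
steps — sizes chosen so the whole suite completes in minutes on one core
while every claimed property is still measurable; all demo geometry is
generated from parameters at run time, nothing is stored.  The solvers
themselves are deterministic: reruns from the same configuration are
bit-identical (asserted), and randomness appears only in test utilities
under explicit seeds.

## Known limitations

* Small-strain solids lack co-rotation: large rotations or strains are
  outside validity (the strain cap only bounds the damage).
* Mooney–Rivlin is available for force evaluation in the explicit and
  semi-implicit algorithms, but the implicit solid solve of mIFEM supports
  the small-strain kinds only (a Newton loop for finite strain is not
  implemented).
* The staggered coupling never sub-iterates; very stiff solid/fluid
  combinations still bound the usable Δt even in mIFEM.
* Contact is not modeled: the fold pair may not close completely, and
  multiple cells interact only hydrodynamically.
* All of this is 2D; flow rates are per unit depth.
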
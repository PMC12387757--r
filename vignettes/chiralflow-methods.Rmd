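---
title: "Methods: the active chiral flow model and its quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the active chiral flow model and its quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
numerical choices are what they are. The worked numbers quoted in the README
are the ones the test suite and `scripts/acceptance.R` actually compute;
nothing here asserts a result the code does not produce.

## The physical model

A dome-shaped epithelial cell on a substrate carries a concentric band of
actomyosin under its dorsal membrane. Each actomyosin bundle is a bipolar
contractile unit: it exerts a force dipole (contraction along its axis,
amplitude $\zeta^a > 0$) and, because Myosin II walks with a chiral bias, a
torque dipole (amplitude $\zeta^c > 0$). Coarse-grained over the band, with
the orientational field fixed to the azimuthal direction
$\mathbf p = S(\rho, z)\, \mathbf e_\varphi$, momentum balance at zero
Reynolds number reads

$$ 0 = -\nabla P + \eta \nabla^2 \mathbf v
      + \zeta^a \nabla\!\cdot(\mathbf{pp})
      + \tfrac12 \zeta^c \nabla\times\nabla\!\cdot(\mathbf{pp}),
      \qquad \nabla\cdot\mathbf v = 0 . $$

The model assumes steady state, an axisymmetric cell, a fixed activity
pattern (no feedback of flow on $S$), a single effective viscosity, and no
organelles — the rotating nucleus is a *readout* of the flow, not part of
the model. The molecular length scale of spin-rate relaxation is taken to
zero, which is what reduces the angular-momentum balance to the single
curl term above.

Scaling lengths by the cell radius $R_0$, velocities by $\zeta^a R_0/\eta$
and pressure by $\zeta^a$ leaves one control parameter, the chiral-to-achiral
activity ratio $\zeta = \zeta^c/(\zeta^a R_0)$. In cylindrical components
the azimuthal flow decouples,

$$ \Big(\partial_\rho^2 + \partial_z^2 + \tfrac1\rho \partial_\rho
   - \tfrac1{\rho^2}\Big) v_\varphi = \frac{\zeta}{\rho}\, S\, \partial_z S , $$

while $(v_\rho, v_z, P)$ solve the axisymmetric incompressible Stokes system
with the contractile body force $S^2/\rho$ in the radial equation. Because
$S$ increases toward the dorsal membrane, $S\,\partial_z S \ge 0$: the active
torque strengthens with height, and it is this *vertical gradient* that
forces a clockwise ($v_\varphi < 0$ viewed from above) rotation. The
meridional problem is independent of $\zeta$; $v_\varphi$ is exactly linear
in it. Both facts are asserted as tests.

## Geometry

The meridional outline is piecewise analytic: an apical cap circle (radius
$r_1$), a shoulder circle, and a straight contact line meeting the substrate
at angle $\alpha$, joined tangentially. Given $(Z_0, R_0, r_1, \rho_2,
\alpha)$ the shoulder circle is fixed by two tangency conditions; the
package evaluates the closed forms for its height $Z_2$, radius $r_2$ and the
junction radii $\rho_1 < \rho_3$, and the tests verify them against an
independent brute-force root-finder for the tangency system (paper-default
and 20 randomly perturbed parameter sets, agreement to $10^{-8}$). The
closed form divides by $\sin^2\alpha$; parameter sets with
$|\sin\alpha| < 10^{-8}$ are rejected rather than special-cased, since the
flat-edge limit is never used. Defaults: $Z_0 = 8.2$, $R_0 = 35$,
$r_1 = 15$, $\rho_2 = 22$ µm, $\alpha = 7^\circ$ (stored in radians).

## The activity band

The band is built around an *inflated* copy of the cell outline with height
$Z_0' = 1.5\,Z_0$ and edge tilt $\beta = 1.7\,\alpha$, so that it hugs the
real dorsal membrane over the shoulder and dies away toward both the apex
and the thin cell edge. Two smoothed (tanh) expressions describe it, and the
domain is split by the ray through the junction of the inflated shoulder arc
and its tangent edge line:

* on the **inner** (shoulder) side, $S$ is a smoothed step on the distance
  to the inflated shoulder-circle centre, at radius $r_2' + \xi$ — this is
  what gives the ring a finite inner radius, since the real membrane falls
  away from the inflated arc toward the apex;
* on the **outer** (edge) side, $S$ is the product of a step above the
  inflated edge line (sharpness $\lambda_1$, offset $\xi$) and a radial
  cutoff at $\xi_3$ (sharpness $\lambda_2$).

This branch assignment is a deliberate design decision. The two expressions
are tangent continuations of one another, so *either* assignment is
numerically continuous across the dividing ray (the tests measure the jump:
$<10^{-3}$); but only this one produces the phenomenology the model is
calibrated to — a ring-shaped band (the radial cutoff active inside its own
branch, $S \approx 0$ over the apex, inner radius $\rho_a \approx 14$ µm),
a peak non-dimensional speed $\approx 2\times10^{-4}$, and an
angular-velocity profile peaking at $\rho/\rho_a \approx 1$. The reversed
assignment extends the edge-line band over the whole dome, puts the profile
maximum on the axis, never activates the radial cutoff, and yields a peak
speed four times larger.

Parameter literals are resolved to dimensionally consistent units:
sharpnesses $\lambda_1 = 150/R_0$, $\lambda_2 = 20/R_0$ per µm; lengths
$\xi = 0.06\,R_0$, $\xi_3 = 0.7\,R_0$ µm. The inner-branch sharpness (whose
symbol is printed unsubscripted in the source model) is taken equal to
$\lambda_1$, the inner-edge sharpness whose role it plays; it is exposed as
the separate argument `lambda_eq19_per_um` so the choice is overridable.
The z-derivative $\partial_z S$ used by the forcing is coded analytically
and checked against central differences at relative $10^{-5}$.

## Discretisation

**Mesh.** The section is triangulated by mapping a structured grid: uniform
columns in $\rho$, each with nodes spaced uniformly between the substrate
and the exact dorsal curve, and a triangle fan collapsing onto the contact
corner. Column nodes lie on the analytic boundary; between columns the
discrete surface is the chord (second-order geometry error). The mapping
refines $\Delta z$ where the cell is thin — exactly where the activity band
sits. Default spacing `h_um = 0.35` µm ($R_0/100$) resolves the radial
cutoff layer (width $\sim 1/\lambda_2 = 1.75$ µm) with five elements and
the sharp inner-edge layer (width $\sim 2/\lambda_1 \approx 0.5$ µm) with
two to four points of the local $\Delta z$; the profile peak changes by
less than 0.1% from `h = 0.7` to `h = 0.175`, so the default is comfortably
inside the mesh-converged regime (a 2% Cauchy bound is asserted in tests).

**Elements and weak form.** Velocities are quadratic (P2), pressure linear
(P1) — the inf-sup-stable Taylor–Hood pair, so no pressure stabilisation is
needed. All weak forms carry the cylindrical weight $\rho\,d\rho\,dz$,
which regularises the $1/\rho$ and $1/\rho^2$ terms; with a degree-5
(7-point) Gauss rule no quadrature point touches the axis. The momentum
equations are kept in vector-Laplacian (gradient) form, matching the
component equations above, and the active terms enter as body forces
evaluated from the analytic $S$ and $\partial_z S$.

**Boundary conditions.** Ventral: no slip. Axis: $v_\rho = v_\varphi = 0$,
natural for $v_z$. Dorsal: free slip — $\mathbf v\cdot\mathbf n = 0$
imposed by rotating each boundary dof pair into (normal, tangential)
components using the analytic boundary slope and constraining the normal
one, with the tangential traction left natural; for $v_\varphi$ the natural
flux of the $\rho$-weighted form is $\rho\,\partial_n v_\varphi$, so the
"zero natural flux" and "zero normal derivative" readings of free slip
coincide and no switch between them is needed. The apex (axis ∩ dorsal,
vertical normal) and the contact corner (ventral ∩ dorsal) are fully
fixed. The pressure is gauged to zero $\rho$-weighted mean by a Lagrange
multiplier.

**Solver.** One sparse direct LU factorisation per subproblem
(deterministic; $\zeta$-linearity holds to $10^{-8}$ nodewise and is
asserted). The "discrete divergence" diagnostic is the residual of the
continuity rows — the constraint the mixed method actually imposes — and
sits at solver precision ($\sim 10^{-12}$ relative); the *pointwise* L2
divergence of the P2 interpolant is also reported and is O(1) relative in
the under-resolved tanh layer, as expected for Taylor–Hood, which is why
the discrete residual is the accepted incompressibility measure.

**Verification.** The method of manufactured solutions runs on a
rectangular annular section ($\rho \in [0.3, 1]$, $z \in [0, 0.3]$), where
Dirichlet data can be imposed exactly on straight sides: target fields are
R expressions differentiated symbolically (`stats::D`), the meridional pair
is built from a stream function so incompressibility is exact, and the
observed L2 orders over meshes $n = 8, 16, 32$ are 3 (velocity, scalar and
Stokes) and 2 (pressure) — the theoretical Taylor–Hood orders.

## Flow analysis

The z-averaged clockwise angular velocity is
$\omega(\rho) = \langle -v_\varphi/\rho \rangle_z$ with uniform weight over
the local height (a per-column average, not a volume average — the readout
mimics a planar projection, not a mass average), computed with 24-point
Gauss–Legendre quadrature per column at 174 radii. The ring inner radius
$\rho_a$ is the smallest radius where $\max_z S \ge 0.8$, bisected to
$10^{-3}$ µm; the max-over-z reduction is our choice where the operational
z-slice is not specified, and with the band hugging the membrane it is
equivalent to evaluating at the dorsal surface. The profile peak is refined
by parabolic interpolation through the three samples around the discrete
maximum (exact for a parabola; boundary maxima are flagged, not
interpolated).

**Calibration.** Non-dimensional velocities are converted by matching the
simulated peak *azimuthal* speed to an experimental peak speed (default
$10^{-2}$ µm/s, the upper end of the measured range and the only value
consistent with a velocity scale of 50 µm/s): the experimental number comes
from planar imaging of the rotating band, so the azimuthal peak is the
matching simulated quantity. This gives velocity scale
$\approx 47$ µm/s and time scale $\eta/\zeta^a \approx 0.74$ s at the
defaults; matching the all-component peak instead would give 0.84 s and
lower the profile peak from $\approx 74$ to $\approx 65$ deg/hr — both
inside the model's stated tolerance, but the azimuthal matching is the
self-consistent one. The calibration identities (velocity scale =
experimental/simulated peak; time scale = $R_0$/velocity scale) are
definitions and are tested exactly.

**Swirl handedness.** A swirl *pattern* viewed from above is classified by
the chirality of its spiral streamlines, which combines the radial and
rotational senses: inward + clockwise (or outward + counter-clockwise) is
sinistral; the two opposite combinations are dextral. Classifying by the
rotation sign alone cannot work — the dorsal and ventral layers share the
same (clockwise) rotation yet form mirror-image spirals because their
radial senses are opposite. Means within `noise_floor` (default $10^{-4}$
of the peak speed) of zero give "indeterminate", which is what a
zero-$\zeta$ solve returns.

## Quantification of experimental-format inputs

**PIV post-processing.** Image convention throughout: y increases downward,
so $v_\varphi = \hat x v_y - \hat y v_x$ is positive for clockwise motion
as displayed and no sign flip is ever applied. $\omega = v_\varphi/r$ is
masked inside `r_min` (default one grid spacing) — the division is
otherwise unbounded; this exclusion rule is our choice. Temporal averaging
(per grid point, over its valid frames) precedes angular averaging
(per-annulus mean ± SEM, default bin width one grid spacing), matching the
order used on the experimental data; profiles can be rescaled by a
manually identified ring inner radius. The cell centre is a user input (in
the experiments it is the xy position of the cell's highest point, which
is not part of a velocity export); a mask-centroid helper exists but is
not the primary path.

**Nuclear rotation.** The orientation of the line joining two tracked
nucleoli is unwrapped frame-to-frame (differences wrapped into
$(-180, 180]$ degrees, or $(-90, 90]$ in "line" mode, which is invariant
to label swaps) and accumulated from zero; windowed rates interpolate the
endpoints linearly. Vector mode is the default because nucleoli are
identified landmarks; the averaging window is always explicit because the
measurement origin differs between experimental designs. Translation
invariance, label-swap invariance, time-reversal antisymmetry and
unbiasedness under orientation jitter are property-tested.

## Synthetic data: what it does and does not emulate

`make_swirl_series()` emulates the *post-PIV* world: a clockwise rotation
profile plus centripetal inflow on a uniform grid, circular mask, and
i.i.d. Gaussian noise per velocity component scaled by the local speed.
Defaults (50 deg/hr, $-0.002$ µm/s inflow, 10% noise, 40 frames at 14.8 s)
mirror the magnitudes of the experimental recordings. It does **not**
simulate microscopy images or the PIV correlation step, so spatially
correlated PIV errors, window-size bias, mask irregularities and
intensity-dependent dropout are outside what passing tests demonstrate;
recovery tests show the *decomposition and averaging* are unbiased given
honest gridded velocities, not that PIV itself is. Similarly
`make_landmark_track()` generates rotating landmark pairs with orientation
jitter, not images of nucleoli. `sample_solution_to_grid()` bridges the
simulation into the PIV pipeline (dorsal/ventral/max-speed layers) for
end-to-end consistency checks. All generators are bit-reproducible from
their seed and embed their ground truth as attributes.

## Problem sizes used by the tests

The shared test solve uses `h = 0.7` µm (≈2,500 P2 nodes, about 2 s); the
acceptance checks and the reproduction script use the default `h = 0.35`
(≈9,800 P2 nodes, ≈22,000 Stokes unknowns, about 12 s); the refinement
check compares against `h = 0.35` from `h = 0.7`. Manufactured-solution
studies use $n = 8, 16, 32$ rectangles. These sizes put every headline
quantity well inside the mesh-converged regime documented above.

## Known limitations

* Steady state only; no inertia, no moving boundary, no nucleus inclusion,
  no feedback of flow on the actomyosin pattern, no 3D non-axisymmetric
  modes.
* Straight-edged (affine) P2 elements: the curved dorsal boundary is
  approximated by chords, an $O(h^2)$ geometric error consistent with, but
  not better than, the field accuracy actually needed here.
* The sharp inner-edge tanh layer is marginally resolved at the default
  mesh; integrated quantities (peaks, profiles) are converged, pointwise
  derivative fields inside the layer are not.
* The experimental numbers the model is compared against (nuclear rotation
  rates across cells, inhibitor responses) require the study's imaging
  data and are outside what this package can recompute; they enter only as
  the defaults of the synthetic generators.
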
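---
title: "An analytical model for non-invasive fractional flow reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An analytical model for non-invasive fractional flow reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffram)
```

## The problem

Fractional flow reserve (FFR) — the ratio of pressure distal to a coronary
stenosis to aortic pressure under maximal hyperemia — is the reference
standard for deciding whether a stenosis starves the myocardium it
supplies; FFR ≤ 0.80 defines ischemia. Measuring it requires a pressure
wire during invasive angiography, and the established non-invasive
alternative requires CFD simulation over a patient-specific mesh, at a
cost of minutes to hours per case. This package implements a purely
analytical route: every pressure loss between the aorta and a distal
centerline point is written in closed form in terms of quantities that can
be read off a reconstructed lumen geometry and two scalars of patient
physiology (left-ventricular mass and cuff pressure).

## Model and assumptions

At each centerline point,

$$\mathrm{FFR}(s) = 1 - \frac{\Delta P_1 + \Delta P_2}{P_a},$$

under steady, laminar, incompressible flow in rigid vessels.

**Aortic pressure.** $P_a = [\mathrm{DBP} + (\mathrm{SBP} -
\mathrm{DBP})/3] - 6.8$ mmHg: mean cuff pressure minus a fixed offset for
the systemic pressure fall during adenosine hyperemia. The offset is a
config value (`pa_offset`); setting it to 0 recovers plain MAP.

**Upstream drop** $\Delta P_2$ is the Hagen–Poiseuille integral
$\int 8\pi\mu\, q(s) / A(s)^2\, \mathrm{d}s$ from the orifice to the
lesion, evaluated by trapezoidal quadrature on the resampled centerline
grid, with each branch carrying its own hyperemic flow. Intervals covered
by a detected lesion are excluded — they are charged as $\Delta P_1$.

**Lesion drop** $\Delta P_1$ uses a three-segment idealization of the
lesion: a contracting taper of length $L_{ps}$ from area $A_p$ down to the
throat area $A_s$, a flat throat of length $L - L_{ps} - L_{sd}$, and an
expanding taper of length $L_{sd}$ back to $A_d$. Each taper contributes a
closed-form viscous drop (exact for a linear-radius taper,
$\frac{8\mu q}{\pi}\frac{L}{3(r_1-r_2)}(r_2^{-3} - r_1^{-3})$, with the
continuous limit $L/r^4$), the throat contributes Poiseuille at $A_s$, and
the tapers additionally carry algebraic entrance/exit losses quadratic in
flow:

- contraction: $\zeta_c\,\frac{\rho}{2} q^2 (A_s^{-1} - A_p^{-1})^2$ with
  $\zeta_c = 0.5\,(1 - A_s/A_p)^{3/4}\sin\alpha$ (a gradual-contraction
  correlation — zero for a smooth entrance);
- expansion: $\zeta_e\,\frac{\rho}{2} q^2 (A_s^{-1} - A_d^{-1})^2$ with
  $\zeta_e = \min(1,\, 2.6 \sin\beta)$ (a diffuser-angle rule capped at
  the sudden-expansion Borda–Carnot value).

The flow entrance and exit angles are taken from the endpoint radii of the
equivalent circular cross-sections: $\alpha = \arctan((r_p - r_s)/L_{ps})$,
$\beta = \arctan((r_d - r_s)/L_{sd})$, in degrees, with a 90° convention
for a zero-length taper. This arctangent construction was a genuinely open
design point; it is the direct geometric reading of the three-segment
sketch, and for table-scale anatomy (areas of 3–7 mm², taper lengths of
3–4 mm) it produces angles in the clinically reported 5–20° range.

**Loss-only closure.** The decomposition deliberately carries no net
Bernoulli term: all three components $\Delta P_{ps}, \Delta P_{ss},
\Delta P_{sd}$ are non-negative, so each is individually interpretable as
a loss, and distal pressure recovery (which would make $\Delta P_{sd}$
negative in a full Bernoulli accounting) is treated as unrecovered —
conservative for post-stenotic flow separation. A flag
(`include_bernoulli_net`) adds the net term
$\frac{\rho}{2}q^2(A_d^{-2} - A_p^{-2})$ for study. The two loss
coefficients are isolated in `contraction_loss()` / `expansion_loss()` so
the closure can be swapped without touching any caller.

**Serial lesions** add along the path with no interaction correction; the
dominant lesion of a vessel is the one with the largest drop, ties going
to the proximal-most.

## Flow model

Total resting coronary flow is linear in LV mass, $Q = q_0 \cdot
\mathrm{LVM}$ with $q_0 = 0.8$ mL·min⁻¹·g⁻¹ by default — a standard
resting myocardial perfusion value, exposed in the config because the
proportionality constant is not uniquely established. At every junction
the incoming flow splits among the daughters in proportion to
$d^{7/3}$ (the flow–diameter scaling law; Murray's exponent 3 is available
by config). The reference diameter of a daughter is the 75th percentile of
equivalent diameters over its proximal 5 mm, so a stenosis sitting at a
daughter ostium does not starve its own subtree — the analytical model
must not create that feedback, since the invasive quantity it mimics is
measured under fixed anatomy.

Hyperemia multiplies each terminal outlet's resting flow by $k(DS)$,
piecewise-linear from $k_{max} = 4$ (adenosine hyperemia in an
unobstructed bed) at $DS \le 0.3$ down to 1 at $DS \ge 0.9$; $k$ is
evaluated at the *maximum* stenosis severity on the outlet's supply path
(conservative for serial disease), and internal flows are recomputed by
summation so junction conservation is exact to machine precision. The
upstream integral $\Delta P_2$ uses hyperemic flow, consistent with the
hyperemic definition of FFR.

For a single-vessel model, `patient_context(territory_fraction = ...)`
scales the vessel's share of total LV flow; virtual cohorts set it by the
same scaling law against a nominal 6.8 mm² proximal vessel carrying half
the LV flow, so small vessels receive proportionally small flows, as in a
real tree.

## Lesion detection and parameterization

Lumen area (not diameter) is the stored primitive; profiles are resampled
onto a uniform grid (default 0.25 mm) by a shape-preserving monotone cubic
Hermite interpolant — a plain cubic spline can undershoot at a narrowing
and fabricate a deeper throat than the data support. A moving-median
filter (default 1 mm window) removes isolated segmentation spikes without
rounding shoulders. The disease-free reference profile interpolates
linearly between "healthy anchors" (local maxima above the branch's 60th
area percentile, plus the endpoints). Lesions are maximal runs where the
instantaneous diameter stenosis $1 - \sqrt{A/A_{ref}}$ reaches `ds_min`
(default 0.25, the floor of the "mild" anatomical grade), extended outward
to where it falls below `ds_min/2` — the lesion *shoulders*, which also
serve as the measurement points for $A_p$ and $A_d$ (measuring at fixed
offsets instead was considered and rejected: offsets can land inside an
adjacent lesion). The throat is the maximal contiguous region with
$A \le 1.05 A_s$; a tolerance is needed because a pointwise minimum would
give the "maximally stenosed segment" zero length on any smooth profile.
Severity is graded minimal/mild/moderate/severe/occluded at the standard
25/50/70/100% diameter cut-points.

## Synthetic data: what it emulates, what it does not

The generators exist so that every downstream stage is testable without
patient data. `make_stenosed_vessel()` realizes the three-segment lesion
with half-cosine (C¹-smooth) radius tapers — deliberately *not* the
linear-radius shape assumed by the closed forms, so detection and angle
estimation are exercised on non-trivial profiles. One consequence is
geometric: on a smooth taper the instantaneous severity crosses the
shoulder level ($ds_{min}/2$) well inside the nominal taper, so the
detected lesion length is intrinsically shorter than the nominal
generative length; recovery tests therefore compare detected extents
against the closed-form shoulder crossing of the known profile, while
severity is compared directly against the generated value (|Δds| ≤ 0.01).

Virtual cohorts draw anatomy from truncated normals centered on
FFR-interrogated clinical vessels (reference area 6.8 ± 3.7 mm² on
[3, 15] mm² — the lower bound is a ~2 mm vessel, the smallest caliber
interrogated with a pressure wire; lesion length 10.8 ± 6.7 mm; taper
lengths ≈ 3.6 ± 3 mm) and physiology from adult norms (LVM 115 ± 31 g,
cuff 134/77 mmHg). Severity is uniform on [0.5, 0.85] with probability
`prevalence` (default 0.43) and on [0.1, 0.5) otherwise, so the expected
obstructive fraction equals the prevalence exactly. Per-vessel RNG
substreams are counter-derived, so enlarging a cohort never reshuffles
earlier vessels.

The cohorts do **not** emulate tortuosity, eccentric or non-circular
lumens, diffuse disease, collaterals, or microvascular variability, and
their "truth" is the generated geometry, not CFD or invasive pressure.
Passing tests therefore demonstrate internal consistency and correct
mathematics of the analytical model at clinical scales — not clinical
diagnostic accuracy.

## Numerical choices

- Clinical units (mm, mm², mL/s, mmHg) at every data structure and file
  interface; strict SI inside the physics kernels; the single conversion
  constant 133.322387415 Pa/mmHg is pinned package-wide.
- Quadrature is trapezoidal on the branch grid; lesion intervals are
  masked strictly inside their extents so boundary points stay with the
  viscous integral. The numeric oracle used in tests integrates the same
  pointwise closure on grids fine enough that its own error is below the
  comparison tolerances.
- Taper closed form switches to its $L/r^4$ limit when
  $|r_1 - r_2| < 10^{-9} r$.
- If the accumulated drop reaches $P_a$ (occlusive disease, outside the
  model's validity), FFR is clamped at `ffr_floor` (default 0.01) with a
  warning rather than reported negative.
- Occluded branches (area 0, flagged) are rejected by flow and pressure
  operations with a dedicated error instead of dividing by zero.
- Ties in dominant-lesion selection break proximal-most,
  deterministically.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
1000-draw closed-form-vs-quadrature sweeps, 200 random three-segment
lesions against the numeric oracle, 200-vessel severity-recovery sweeps at
0.25 mm grids, 100-tree monotonicity sweeps, 2000-replicate null
calibration of the DeLong test at n = 30, and 150-vessel cohorts in the
acceptance script. The full suite completes in well under a minute on one
CPU.

## Known limitations

Steady flow only (no pulsatility, no wave-free-period indexes), rigid
vessels, circular-equivalent cross-sections, no microvascular or
collateral modeling, no lesion-interaction correction for serial disease,
and loss coefficients taken from standard engineering correlations rather
than fitted to coronary data. The hyperemic multiplier's piecewise-linear
form is a two-parameter stand-in for the underlying stenosis-resistance
physiology: monotone, bounded, and easy to reason about, but not
mechanistic.
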
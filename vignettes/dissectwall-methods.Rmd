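---
title: "Hemodynamic and geometric assessment of residual type B aortic dissection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic and geometric assessment of residual type B aortic dissection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissectwall)
```

## Scope and model

After a type B aortic dissection, the intimal flap divides the descending
aorta into a true lumen (TL) and a false lumen (FL) communicating through an
entry tear. Whether the FL degenerates into an aneurysm depends on an
interplay of geometry (TL/DA area ratio, tear size, tortuosity) and
hemodynamics (FL flow fraction, wall shear stress at the tear, inter-lumen
pressure). `dissectwall` implements the full post-processing chain used to
characterize such aortas — wall-shear descriptors, lumen geometry metrics,
flow partition, pressure differentials, verification utilities and cohort
statistics — together with a synthetic generator that stands in for the two
components that cannot be reproduced at desk scale: patient CT anatomies and
a transient 3D CFD solver.

The CFD surrogate is the classical Womersley solution for pulsatile flow in
a rigid straight tube. For a one-sided harmonic decomposition of the
volumetric flow $Q(t) = \Re\{\sum_{k\ge 0} c_k e^{ik\omega t}\}$
($\omega = 2\pi/T$, $T = 0.8$ s), each oscillatory harmonic contributes

$$u_k(r,t) = \Re\left\{\frac{c_k}{\pi R^2}\,
  \frac{1 - J_0(\Lambda_k r/R)/J_0(\Lambda_k)}
       {1 - 2J_1(\Lambda_k)/(\Lambda_k J_0(\Lambda_k))}\,
  e^{ik\omega t}\right\},
  \qquad \Lambda_k = i^{3/2}\alpha\sqrt{k},$$

with Womersley number $\alpha = R\sqrt{\omega/\nu}$; the steady component is
the Poiseuille profile, and the wall shear is taken from the analytic radial
derivative (a $J_1$ expression), never from finite differences — the
finite-difference comparison is reserved for the test suite, where it serves
as an independent oracle. $J_0$ and $J_1$ at complex argument are evaluated
by the ascending power series up to $|z| = 80$ (cancellation error
$\lesssim 10^{-5}$ on the $i^{3/2}$ ray) and by leading-order asymptotics
beyond, where only the well-scaled ratios are ever formed.

Blood is Newtonian and incompressible ($\rho = 1060$ kg/m³,
$\mu = 3.19\times 10^{-3}$ Pa·s); walls are rigid with no slip. These match
the modeling conventions for large-vessel simulation that the package
emulates.

## Wall descriptors

For the wall-shear vector $\tau(t)$ sampled on a uniform periodic grid:

$$\mathrm{TAWSS} = \tfrac{1}{T}\int_0^T |\tau|\,dt,\quad
  \mathrm{OSI} = \tfrac{1}{2}\Bigl(1 -
    \tfrac{|\int_0^T \tau\,dt|}{\int_0^T|\tau|\,dt}\Bigr),\quad
  \mathrm{RRT} = \bigl[(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}\bigr]^{-1}.$$

The descriptor names alone do not pin down a formula, so the standard
literature definitions above are frozen here as the package's contract. Integrals use the composite trapezoid
on the periodic grid (identical to the rectangle sum once the period wrap is
included), which makes the descriptors exactly invariant under cyclic
rotation of the time grid. Vertices with vanishing $\int|\tau|dt$, or with
perfect reversal (OSI = 0.5), have undefined (infinite) residence time and
are flagged rather than zeroed. Region summaries weight each vertex by one
third of its incident triangle area; RRT means are taken over finite values
only, and a requested empty region is reported `present = FALSE`, never as a
zero.

The tear statistic "peak TAWSS distributed over the entry tear margins" is
implemented as (peak TAWSS over tear-rim vertices) × (tear perimeter), in
Pa·mm. Whether the original metric was a peak–perimeter product or a margin
line integral is not decidable from its verbal description; the
`line_integral` method (mean margin TAWSS × perimeter) is provided as the
alternative, with `peak_perimeter` the default.

## Geometry metrics

*Tortuosity* is the arc–chord ratio of the centerline. *TL/DA ratio* is the
mean of TL/(TL+FL) cross-section areas over three planes; the anatomical
stations (above the left pulmonary artery, at the left inferior pulmonary
vein, at the diaphragm) are mapped to configurable fractions 0.15/0.50/0.85
of the descending arclength, since the synthetic anatomy has no organs.
Sections are obtained by slicing the wall mesh with the plane normal to the
centerline, chaining the intersection into a closed contour, and applying
the shoelace formula; the flap chord splits the contour into the two lumens
by a half-plane clip.

The *entry tear* is summarized by a circle of effective diameter
$d = (h+w)/2$ (area $\pi d^2/4$, perimeter $\pi d$). Clinical measurements give only a height and a width, with the area
approximated as a circle; the mean-diameter is chosen because it is symmetric in $(h,w)$ and
exact when $h = w$. The ellipse alternative ($\pi h w/4$, Ramanujan
perimeter) is available behind `method = "ellipse"`; the two differ by under
~15% at clinically reported aspect ratios.

*Growth classification* uses the endpoint slope per surveillance plane
(last minus first diameter over elapsed years) and labels the aorta rapid
when any plane reaches the threshold, 3 mm/yr, inclusively. Endpoint slope,
not regression, matches the clinical-guideline framing of diameter change
over a surveillance interval.

## Flow partition, regime screening and pressure

The outflow split sends 55% of the time-averaged inlet flow through the
descending aorta and divides the remaining 45% among the three arch branches
proportionally to their outlet areas. FL flow fraction is
$100\,Q_{FL}/(Q_{FL}+Q_{TL})$ at the sample of maximum total descending
flux, measured at the most proximal plane (no convention fixes the
measurement plane; just distal to the entry tear is the natural choice). Inter-lumen pressure profiles report mean FL minus mean TL
pressure at three phases resolved from the flow curve: systolic peak
(argmax Q), systolic deceleration (midpoint of the descending systolic
limb), diastolic peak (argmin Q after end-systole). Only the peak has a
sharp definition; the other two are qualitative phases and are documented,
configurable conventions.

Regime screening computes $\alpha$, the peak inlet Reynolds number
$Re_{peak} = \rho U_{peak} D/\mu$, the Strouhal number $St = fD/U$ and the
pulsatile transition correlation
$Re_{crit} = 169\,\alpha^{0.83}St^{-0.27}$. Two genuinely open choices are
resolved as follows and exposed as parameters:

* the correlation originates from pulsatile-transition experiments in
  straight tubes; it is adopted as the default and replaceable via the
  `re_crit` argument;
* the characteristic velocity in $St$ is undocumented. With the mean
  velocity, the correlation yields $Re_{crit} \approx 3100{-}3600$ at
  physiologic aortic diameters — *below* $Re_{peak}$, i.e. supercritical,
  contradicting both the reported subcritical finding and the printed
  $Re_{crit}$ band (4366–5552). With the peak velocity, $Re_{peak}$ spans
  ~2650–4650 and $Re_{crit}$ ~3600–4900 across 2–3.5 cm at resting cardiac
  output, subcritical throughout and inside the printed bands. The peak
  velocity is therefore the default (`char_velocity = "peak"`), with
  `"mean"` selectable; a zero-mean waveform then raises an explicit error.

The same reasoning treats the printed Reynolds ranges as plausibility bands,
not reproduction targets: they derive from 22 unavailable anatomies.

## The synthetic world

`dissection_params()` describes one idealized anatomy: a 15 mm-radius tube
swept along ascending segment (60 mm), arch semicircle (radius 40 mm,
carrying three branch tubes of 6/4/5 mm) and descending segment (200 mm).
The intimal flap is a zero-thickness plane placed at the chord offset whose
circular segment gives exactly the requested TL area fraction — zero
thickness keeps TL + FL = DA an exact, testable identity. The entry tear is
an elliptical hole through the flap (height axial, width transverse), rim
labeled `tear_margin`; a tear wider than the local flap chord is rejected
with an explanatory error. A sinusoidal out-of-plane perturbation of the
descending centerline controls tortuosity
(`amplitude_for_tortuosity()` inverts the arc-chord integral). The builder
draws no random numbers at all, so meshes are bit-reproducible; branch tubes
abut the arch without a boolean union, which is the one respect in which the
surface is not watertight beyond its open inlet/outlet caps.

`synthesize_fields()` replaces the transient solver: each region receives
the rectified Womersley wall-shear magnitude for its flow share and
effective radius ($R\sqrt{f}$ for a lumen of area fraction $f$), directed
along the local axial tangent. The FL series is phase-lagged (8% of the
cycle), attenuated (×0.8) and given a sign-reversing component by
subtracting `fl_osc` (default 1.2) times its cycle mean — so FL OSI exceeds
TL OSI, reproducing the qualitative finding that the false lumen sees
oscillatory, recirculating shear while the true lumen sees organized forward
shear, without claiming the absolute OSI levels of a 3D solve. Setting
`fl_osc = 0` with zero noise yields an exactly non-reversing field (OSI
$\equiv$ 0), the degenerate case the tests pin down. Tear-margin vertices
get the TL series amplified by `jet_factor` (default 4), a surrogate for
entry-jet impingement. Gaussian noise (default sd 0.05 Pa) is added in the
local tangent plane so noise-free fields remain exactly tangent to the
surface. Plane fluxes split the descending flow exactly by the TL share, so
mass conservation holds to machine precision; plane pressures integrate the
per-harmonic Womersley pressure gradient, and the FL−TL offset is
configurable (default: +40 Pa weighted toward diastole, the phase where
higher FL pressure is most consistently observed).

`simulate_cohort()` draws a 22-patient cohort (11 stable / 11 rapid by
default) whose per-group feature distributions restate the published
summary table values: TL/DA 0.42 ± 0.12 vs 0.29 ± 0.11, tear area
144.8 ± 173.7 vs 210.0 ± 182.6 mm² (drawn lognormal to respect positivity at
these dispersions), tortuosity 1.38 ± 0.3, FL flow 55 ± 20 vs 63 ± 15%,
growth 1.34 ± 0.92 (truncated below 3) vs 4.61 ± 1.82 mm/yr (truncated above
3). Within the stable group a 4/11 fraction is drawn from the adverse
stratum (tear 280.7 ± 238.7 mm², FL flow 66 ± 24%). FL flow is coupled to
tear area and TL/DA ratio through a linear latent model whose population
correlations equal the configured r = 0.55 and r = −0.64 exactly. Outcome
flags come from a fixed deterministic risk score
$z = (FL\%/100 - 0.55)/0.18 + (tort - 1.38)/0.30 + 0.5\ln(area/150)$
(death at $z \ge 1$, re-intervention at $z \ge 0.4$) — a documented
generator convention reproducing the qualitative associations, not a
clinical claim; because the adverse stratum is drawn with high-risk
features, stratum label and death flag agree statistically rather than by
construction. `cohort_effects(null = TRUE)` collapses every group to the
stable distributions for type-I-error calibration.

What a green test does **not** establish: the synthetic anatomy has no
patient-specific curvature, no flap motion, no thrombus, no re-entry tear
meshing and no 3D jet structure, and its absolute TAWSS/OSI/RRT levels are
those of an idealized straight-tube surrogate (TL mean TAWSS ≈ 0.37 Pa at
defaults versus ~1 Pa reported from full CFD). Green means the
*post-processing chain* is correct on fields whose ground truth is known
analytically.

## Statistics

`compare_groups()` follows the small-cohort convention: Shapiro–Wilk on each
group (α = 0.05); on failure, a natural-log transform for strictly positive
data with retest ("apposite transformation"); Mann–Whitney otherwise (exact
for n ≤ 10 per group without ties — the two-sided exact p is the doubled
one-sided tail capped at 1 — and the tie-corrected normal approximation
otherwise). Fisher's exact test handles categorical variables, with the
two-sided p summing all margin-consistent tables at most as probable as the
observed one. Pearson's r is tested via $t = r\sqrt{(n-2)/(1-r^2)}$. No
multiple-testing correction is applied, matching per-variable reporting.
One known discrepancy is documented in the tests: the published group table
prints p = 0.400 for male sex at counts 6/11 vs 9/11, while exact
enumeration gives 0.361 (the subgroup counts 3/7 vs 3/4 do reproduce the
printed 0.545 exactly).

A calibration note: the published TL/DA effect (Δ = 0.13 at sd 0.11–0.12,
n = 11/11) has analytic noncentral-t power 0.71–0.75. The test suite checks
the gated procedure against that closed-form oracle (they agree to under one
point); an acceptance criterion asserting ≥ 80% replicate-cohort rejection
for this effect is therefore left failing by design — the shortfall is a
property of the stated effect size, and nudging generator parameters to
cross the threshold would falsify the stated world.

## Numerical choices and defaults

| quantity | default | rationale |
|---|---|---|
| cycle period $T$ | 0.8 s | stated cardiac cycle (75 bpm; a "76 bpm" label is display-only and inconsistent with 0.8 s) |
| waveform peak | 283 mL/s | 0.4 m/s peak velocity in a 30 mm aorta; mean ≈ 66 mL/s ≈ 4 L/min |
| harmonics | 8 | reconstruction RMS < 2% of peak for the packaged curve |
| descending flow share | 0.55 | stated outflow split |
| time samples/cycle | 64 | TAWSS refinement error < 0.1% on smooth fields |
| `n_theta` | 64 | inscribed-polygon area error 0.16% < the 0.5% section tolerance |
| growth threshold | 3 mm/yr, inclusive | stated clinical threshold |
| mesh-selection tolerance | 2% on mean AND max WSS | "negligible" is unquantified; both curves are shown, so both must qualify |
| CFL band | 0.5–2 ms | stated time-step range |
| tear-margin band | rim vertices | one-cell rim of the tear hole; a geodesic-band generalization is a known limitation |

Degenerate inputs are errors, not silent values: coincident centerline
endpoints (tortuosity undefined), zero total flux at the systolic peak,
empty tear margin, zero finest-mesh reference, constant samples in the
normality gate (falls through to Mann–Whitney with a warning), NaN shear
vectors (reported with vertex ids).
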
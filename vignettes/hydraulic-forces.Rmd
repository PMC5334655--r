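---
title: "Hydraulic forces on the AV plane: model, generator and simulator"
author: "AVHydraulics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic forces on the AV plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AVHydraulics)
```

## The model

During diastole the open mitral valve makes the left atrium (LA) and left
ventricle (LV) a single hydraulic chamber. The common blood pressure acts on
the atrial face of the atrioventricular (AV) plane over the atrial short-axis
area (ASA) and on the ventricular face over the ventricular short-axis area
(VSA). Because these areas differ, Pascal's principle yields a net
longitudinal force even at exactly equal pressures:

$$F \;=\; VSA \cdot P_{LV} \;-\; ASA \cdot P_{LA},$$

positive apex-to-base (toward the atrium, aiding filling). Only the
longitudinal component is modelled; for a curved wall it is governed by the
largest cross-section orthogonal to the long axis, independent of the wall's
curvature. Two VSA definitions bracket the truth: the endocardial border
(blood pool only — hydraulic forces certainly act here) and the epicardial
border (including the myocardium, the limit in which intramyocardial fluid
pressures contribute fully). Transmitral and intraventricular pressure
gradients of early rapid filling are deliberately neglected: the force
matters most during diastasis, when those gradients have vanished and the
equal-pressure assumption is exact. Radial force components and aortic-wall
recoil are out of scope.

All computation is done in SI (Pa, m², N); cm² and mmHg appear only at the
interface. The conversion uses the exact conventional definition
1 mmHg = 133.322368 Pa, so 10 mmHg is 1333.22 Pa (1333 Pa at whole-pascal
rounding).

## The synthetic cohort generator

In-vivo area measurements at this level of temporal detail are rarely
available, so the package generates cohorts whose structure matches healthy
cine CMR findings. Each chamber's curve is a piecewise **half-cosine**
through three landmark areas — end diastole (t = 0 and 1), end systole
(`tEs`) and mid diastasis (`tDd`) — with a diastasis plateau and a return
segment from the atrial-kick onset (`tAk`). Half-cosines were chosen over
splines deliberately: each segment is monotone between its landmarks, has
zero slope at the landmarks (smooth joins), and has the closed-form midpoint
value \((v_0+v_1)/2\), which makes the interpolant exactly testable.

**Timing defaults.** The endocardial crossover (VSA$_{endo}$ rising above
ASA) is placed at 53 % of the cycle, and that crossover is known to span
75 % of diastole; internal consistency of the two facts fixes end systole at
$t_{es} = 1 - 0.47/0.75 \approx 0.3733$. Mid diastasis (0.70) and
atrial-kick onset (0.90) are not constrained by measurement and were chosen
once to give a visible plateau.

**Area defaults (cm²).** ASA 14.0 / 20.0 / 16.0, VSA$_{endo}$ 26.0 / 12.0 /
23.7, VSA$_{epi}$ 45.0 / 38.0 / 41.4 at end diastole / end systole / mid
diastasis. The two mid-diastasis differences (23.7 − 16.0 = 7.7 and
41.4 − 16.0 = 25.4 cm²) are the calibrated quantities; absolute levels are
free parameters, exposed in the config, because only area *differences*
enter the equal-pressure force.

**Between-subject variability.** Each subject carries one standard-normal
effect $z_i$; endocardial ventricular landmarks are shifted by
$4.4\,z_i$ cm² and epicardial ones by $7.3\,z_i$ cm² (SEM × √10 for printed
SEMs of 1.4 and 2.3 cm² at n = 10). A single shared effect — rather than
independent endo/epi draws — encodes that a subject with a larger
endocardial difference also tends to have a larger epicardial one; atrial
landmarks stay at the population values, since only the VSA−ASA differences
are calibrated. Draws violating positivity or epicardium ⊇ endocardium are
redrawn (at most 100 attempts, then an error). Each subject has its own seed
derived from (cohort seed, subject index), so subject i is reproducible in
isolation.

**Anchoring.** The population-mean endocardial curve is built with an
*anchor*: its diastolic rise is split at the crossover so it equals the mean
ASA curve's value exactly at t = 0.53 and exceeds it thereafter. Individual
subjects are generated without the anchor — the cohort-level statement "the
crossover sits at 53 % of the cycle" is a property of the mean curve, and
anchoring every subject would artificially remove all between-subject
variation in crossover timing.

What the generator does *not* emulate: measurement/segmentation error of
CMR contours, heart-rate variability of phase timing, atrial-landmark
variability, and any pathology. Passing tests therefore show that the
pipeline recovers the structure it was calibrated to, not that it validates
the physiology of any new cohort.

## Forces over diastole

`forceCurve()` evaluates the three curves on the diastolic interval
\([t_{es}, 1]\) and applies the force formula frame-wise.
`fractionDiastolePositive()` measures the time with \(F > 0\) on the
continuous piecewise-linear interpolant, locating sign changes by linear
interpolation between frames, so the result is essentially independent of
grid resolution. On the default population-mean geometry (1001 frames; the
package uses 3001 in the acceptance script, where the discretization error
is below $10^{-6}$):

```{r}
fc <- forceCurve(populationGeometry(), PressureModel(10))
c(endo = fractionDiastolePositive(fc, "endo"),
  epi = fractionDiastolePositive(fc, "epi"))
```

## Driving-force comparison

The peak driving force of filling is estimated as force-per-unit-mass
(25 mN/g, a literature constant taken as input, not re-derived) times the
inertial load: LV mass (125 g) plus 75–275 g of accelerated blood and
great-vessel roots, i.e. 200–400 g and hence 5–10 N. The hydraulic fraction
reports the extreme ratios of the two ranges. The headline fraction uses the
whole-newton rounded cohort forces (1 and 3 N), matching the convention of
the source estimates, giving 10–60 %; the unrounded fraction is reported
alongside so no precision is lost.

## The piston rig simulator

The physical analog is a hollow piston with a small ("atrial") and a large
("ventricular") end face sliding in a two-chamber housing pressurized by a
~1.4 m water column; the open conduit through the piston plays the open
mitral valve. The lumped dynamics are

$$m\dot v = \rho g h\,(A_{large}-A_{small}) - f_{ext} - c\,v,$$

with the column height slaved to piston position by incompressibility,
\(h = h_0 - (A_{large}-A_{small})(x-x_0)/A_{column}\) — an algebraic
constraint, so volume conservation holds to machine precision by
construction. Integration is classic fixed-step RK4 (default dt = 10⁻⁴ s;
fixed step keeps trajectories bit-reproducible), and stop contact is
perfectly inelastic: the position is clamped and inbound velocity zeroed,
mirroring the rig coming to rest without introducing a restitution
parameter nothing constrains. Column-height feedback can be switched off in
the constant-pressure limit by making `aColumn` large.

Only the column height (~140 cm) and the qualitative behavior of the rig
are constrained by observation; end areas (20 and 27 cm², sized so the
static force is of order 10 N), piston mass (0.5 kg), damping (50 N·s/m)
and travel (3 cm) are invented defaults exposed in the config.

```{r}
traj <- simulateRelease(PistonRig(), x0 = 0, dt = 1e-3, tEnd = 1)
tail(trajectoryStates(traj), 1)
```

## Exact statistics

Cohort summaries are mean ± SEM (sample SD / √n). Paired VSA-vs-ASA
comparisons use an exact Wilcoxon signed-rank test: zero differences are
dropped (Wilcoxon's original procedure), tied absolute differences get
average ranks, and the null distribution of \(W^+\) over all \(2^n\) sign
assignments is computed exactly by a generating-function convolution on the
realized (possibly tied) ranks. The two-sided p is
\(\min(1, 2\min(P(W\le w), P(W\ge w)))\) — one reproducible choice among the
definitions in circulation. Only the exact test is offered, for n ≤ 15:
the target cohorts are small and exactness is what makes the independent
enumeration oracle in the test suite meaningful. Note that a fully
sign-consistent cohort of ten gives p = 2/1024 ≈ 0.002; reported p-values
near 0.02 in comparable in-vivo cohorts imply some opposite-sign subjects,
so p-values are treated as properties of the data, not calibration targets.

## Numerical choices and degenerate inputs

- Curve lookup is linear interpolation on the stored grid, exact at grid
  points; t outside [0, 1] is a domain error.
- Periodicity is enforced exactly (the t = 1 sample is set to the t = 0
  value, guarding against floating-point drift in the cosine evaluation).
- An anchor is infeasible if the end-systolic area is not below the ASA
  value at the crossover, or the curve fails to exceed the ASA after it;
  both raise errors rather than producing a silently wrong shape.
- Single-subject cohorts produce summaries with `NA` SEM; all-zero
  difference vectors are a degenerate-sample error for the exact test.
- Problem sizes used throughout the examples and tests: cohorts of 10
  subjects × 30 frames (typical cine CMR temporal resolution),
  population-mean curves at 1001–3001 frames, piston trajectories of
  10⁴ steps — all chosen as the natural desk scale of the analysis.

## Known limitations

The generator's absolute area levels are unconstrained by measurement, so
quantities depending on absolute areas (not differences) are arbitrary. The
equal-pressure force model is exact only in diastasis; early-diastolic
values bracket rather than measure the true force. The piston model lumps
all losses into one viscous coefficient and ignores conduit inertance and
hose elasticity.
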
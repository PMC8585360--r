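---
title: "Modelling ploughing forces in cortical bone: methods and design notes"
author: "boneplough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ploughing forces in cortical bone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneplough)
```

## The problem

Scribing topological microstructures into the surface of cortical bone —
microgrooves that guide bone-cell differentiation during repair — can be
done efficiently with a conical single-point diamond tool (SPDT) driven
in a ploughing regime: the tip displaces material without forming a
chip.  Planning such cuts requires predicting two forces as functions of
the programmed depth (uncut chip thickness, UCT, $h$) and of the
direction of the cut: the normal force $F_z$ pressing the tool into the
bone, and the tangential (ploughing) force $F_p$ resisting the feed.
Cortical bone is strongly anisotropic — it is a composite of oriented
osteons (Haversian systems) — so $F_p$ depends on the *cutting angle*
$\theta$ between the feed direction and the osteon long axis.

This package implements the mechanistic model chain for that problem,
its calibration from replicate cutting trials, the preprocessing of the
dynamometer force traces those trials produce, and a synthetic generator
that emulates the whole experiment so every stage is testable without
laboratory data.

## Normal force

Contact of a rigid cone with the bone is described by three nested
laws, all with $\varphi$ the angle between the cone side and the
workpiece plane (45° for the reference 90°-cone tool, so
$\tan\varphi = 1$):

1. **Elastic (Sneddon) regime** — before yield,
   $F_z = \frac{2}{\pi} E h^2 \tan\varphi$ (`elastic_normal_force()`).
2. **Yield regime** — once the contact yields, stress is carried at the
   yield strength $\delta_s$ over the horizontal projected area,
   $F_z = \delta_s A$ with $A = \pi h^2 / (8\tan^2\varphi)$
   (`yield_normal_force()`).  The factor 8 in $A$ is adopted as part of
   the reference calibration's working definition; it is not re-derived
   here (purely geometric projection would give $\pi h^2/\tan^2\varphi$).
3. **Depth-integrated yield law** —
   $F_z = \int_0^h A\,\delta_s\,\mathrm{d}h
        = \frac{\pi \delta_s h^3}{24\tan^2\varphi}
        = \frac{\delta_s V}{8\tan^2\varphi}$
   (`integrated_normal_force()`), where
   $V = \pi h^3/(3\tan^2\varphi)$ is the indented volume
   (`indentation_volume()`).

Because the effective yield strength varies across the multilevel
micro/nano structure of bone, the physical laws are summarised for
prediction by an **empirical power law in indented volume**,

$$F_z = C\,V^{\alpha},$$

with $(C, \alpha)$ calibrated from indentation data
(`fit_power_law()`).  The reference calibration is
$F_z = 707.53\,V^{0.39}$ (newtons, mm³).  With $\alpha < 1$ the law is
concave: burying additional tool volume raises the force at a
decreasing rate.

## Tangential force and the ploughing coefficient

The tangential force is shear on the forward projected flank area
$A_p = h^2/\tan\varphi$, with an orientation-dependent shear stress

$$\tau_p(\theta) = \left(C_1 + C_2\sin(C_3\theta +
\theta_0)\right)\tau_s,$$

where $\tau_s$ is the inherent shear strength of the bone.  Empirically
the ratio of tangential to normal force is a material constant at fixed
orientation, the **ploughing coefficient**

$$f_p(\theta) = \frac{F_p(\theta)}{F_z}
  = C_1 + C_2\sin(C_3\theta + \theta_0), \qquad
  F_p(\theta) = f_p(\theta)\, F_z,$$

which is how the package predicts $F_p$ (`ploughing_coefficient()`,
`tangential_force()`).  The identity $F_p = f_p F_z$ holds to machine
precision by construction.

**Angle convention.**  $\theta$ and $\theta_0$ are carried in degrees
(matching how cutting angles are reported: 0°/45°/90°) while the
sinusoid argument $C_3\theta + \theta_0$ is evaluated in radians, so
$C_3$ has units rad/deg.  This mixed convention is the only one that
reproduces the calibrated endpoint values: with $C_1 = 0.294$,
$C_2 = 0.934$, $C_3 = 0.45$,

```{r}
am <- calibrated_anisotropy_model()
round(ploughing_coefficient(c(0, 45, 90), am), 4)
```

i.e. $f_p$ is smallest cutting along the osteons (0.29), peaks at 45°
(1.21), and is intermediate across them — the measured ordering.

**Two written forms.**  The calibration identity is sometimes composed
so that the sinusoid is additionally multiplied by
$f_p(\theta_0) = 0.29$ (equivalently, a tangential-force prefactor
$f_p(\theta_0)\cdot C \approx 205\!-\!208$).  Taken literally that
double-counts the reference level: it would give $f_p(0°) = 0.29 \times
0.294 = 0.085$, contradicting the measured $f_p(0°) = 0.29$.  The
package therefore evaluates the *canonical* form
$f_p = C_1 + C_2\sin(C_3\theta+\theta_0)$ by default, and retains the
literal composed form behind
`anisotropy_model(..., convention = "literal")` purely for
transparency.

**Phase aliasing.**  A three-angle design (0°/45°/90°) identifies
$C_3$ only up to aliasing: every $C_3'$ with the same sine values at
the design angles fits identically.  The compact conventional value
$C_3 = 0.45$ is such an alias ($0.45 \times 45 \bmod 2\pi \approx
1.400$ rad, versus the exact first-branch phase $1.425$ rad);
`fit_anisotropy()` therefore constrains the fit to the first branch
$0 < C_3\,\theta_{\max} \le \pi$ and reports the aliases alongside.
One practical reason to prefer the first-branch rate for
*interpolation* between design angles: the aliased $C_3 = 0.45$
sinusoid completes roughly 6.4 periods over $[0°, 90°]$ and dips
negative between the design angles, whereas the first-branch curve
($C_3 \approx 0.0317$) is a single monotone-then-falling arc that stays
positive over the whole quadrant.  At the design angles the two agree
to two decimals.

## Calibration

* `fit_power_law()` — default `"loglog"`: ordinary least squares of
  $\log F_z$ on $\log V$.  Force errors are multiplicative
  (instrumental noise scales with signal level), so log-space OLS is
  the natural weighting; a direct nonlinear least-squares mode
  (`"nls"`, via the `port` algorithm, robust to zero-residual inputs)
  is available for comparison.  Diagnostics are computed on the fitting
  scale.
* `fit_anisotropy()` — for fixed $C_3$ the model is linear in
  $(C_1, C_2)$, so the fit profiles the residual sum of squares over
  $C_3$ on the first branch with an exact linear solve at each
  candidate (coarse 400-point scan, then unimodal refinement to
  tolerance $10^{-12}$).  No starting values are needed.  $\theta_0$ is
  fixed at 0 by default (its calibrated value); `fit_theta0 = TRUE`
  estimates it through the linearisation $C_2\sin(C_3\theta+\theta_0) =
  a\sin(C_3\theta) + b\cos(C_3\theta)$.  The amplitude convention is
  $C_2 > 0$; if the profiled optimum violates it (a falling response),
  the fit aborts with a diagnostic instead of silently wrapping to
  another branch.
* `solve_three_angle()` — on the exact 0/45/90 design the least-squares
  problem decomposes into the three per-angle means and has the closed
  form $C_1 = m_0$, $\cos x = (m_{90}-m_0)/(2(m_{45}-m_0))$,
  $C_2 = (m_{45}-m_0)/\sin x$, $C_3 = x/45$.  It is kept as an
  independent oracle: the iterative fit must coincide with it to
  $10^{-8}$ on three-angle designs, and the test suite enforces that.

```{r}
d <- plough_coefficients()          # bundled replicate measurements
fit <- fit_anisotropy(d$theta_deg, d$fp)
coef(fit)
```

`regression_diagnostics()` reports $R^2 = 1 - SSE/SST$, the standard
regression $F$ statistic $(SSR/\mathrm{df_{reg}})/(SSE/\mathrm{df_{res}})$,
residuals and per-point relative error rates $100\,|pred-obs|/obs$.
The historical error-rate and $F$-measure figures that accompany the
reference calibration were computed with definitions that cannot be
recovered from any standard formula we constructed; the package
deliberately reports the standard definitions above instead, and the
test suite checks properties (closed-form/quadrature equivalence,
closed-loop recovery, the $F_p = f_p F_z$ identity) in their place.

## Preprocessing of force traces

Raw dynamometer channels carry occasional acquisition glitches.
`hampel_filter()` implements the standard Hampel identifier: a sample
deviating from its rolling-window median by more than
$k \times 1.4826 \times \mathrm{MAD}$ is replaced by that median
(defaults: half-width 5 samples, $k = 3$).  Choices worth noting:

* *"Spacing 5"* is read as a half-width of 5 samples; `halfwidth =
  FALSE` switches to a total-width reading.
* Windows are truncated at the series ends — no data is fabricated at
  trace boundaries.
* A zero-MAD (locally constant) window flags any nonzero deviation.
* The filter is *exactly* idempotent, and trial summaries are *exactly*
  invariant to injected spikes, in the regime the filter targets:
  isolated outliers on an otherwise clean signal.  On series with
  continuous noise a second pass can flag a few additional borderline
  samples (replacement slightly tightens the rolling MAD), and removing
  a spike changes the summary mean at the $\mathcal{O}(\sigma/n)$
  level.  The tests assert exact invariance on clean signals and
  statistical bounds on noisy ones.

`segment_steady_state()` finds the engaged stroke as the longest run of
normal force above 10% of the trace's robust maximum (95th percentile)
and keeps its central 80% (`trim_fraction = 0.1`, configurable; the
extraction rule is this package's choice, as the original workflow does
not document one).  `summarize_trial()` chains filter → segment → means
and reports the observed coefficient $f_p = \bar F_p / \bar F_z$.

## The synthetic experiment generator

`generate_experiment()` emulates the reference study conditions: a full
factorial of UCT $\in \{0.5, 0.6, 0.7, 0.8\}$ mm × cutting angle
$\in \{0°, 45°, 90°\}$ × 5 replicates (60 trials), stroke 10 mm at
100 mm/min (hence 6 s engaged), 1 kHz sampling, with force plateaus at
the model values $F_z = C\,V(h)^\alpha$ and $F_p = f_p(\theta) F_z$.
What it adds beyond the stated conditions, and why:

* **Noise** is multiplicative log-normal with sd 1% by default — forces
  are positive and instrument error scales with level, and this choice
  keeps the log-space power-law fit unbiased.  The instrumental noise
  of the real rig is not characterised in the source; 1% is a realistic
  dynamometer figure.
* **Engagement edges** ramp linearly over 50 ms rather than stepping,
  so segmentation is testable without unrealistic discontinuities;
  lead-in/out of 0.5 s of zero force surround the stroke.
* **Spikes** (off by default) multiply isolated plateau samples by 10,
  emulating acquisition glitches for filter tests; they never alter the
  embedded ground truth.
* **Determinism**: a single named seed; per-trial seeds are derived as
  `seed + trial_index - 1` and recorded in the manifest, and identical
  inputs give byte-identical CSV output.

What it does *not* emulate: tool vibration/chatter spectra, thermal
drift, charge-amplifier dynamics, tool wear, or the real
depth-dependence of bone heterogeneity.  Passing closed-loop tests
therefore demonstrate that the pipeline is self-consistent and unbiased
under the assumed noise model — not that the model captures every
feature of laboratory traces.

## Problem sizes used in the tests

The test suite runs the pipeline at reduced sampling rates (50–200 Hz)
and replicate counts, chosen so the full suite completes in well under
a minute while the statistical checks keep comfortable margins; the
generator's physics is rate-independent, so this scaling changes only
the per-trial averaging error ($\propto 1/\sqrt{n}$), which the bounds
account for.  The power-law recovery experiment uses the full $n =
1000$ points; the Hampel filter is checked against a brute-force oracle
on 1000 random series.

## Default parameter values

| Parameter | Default | Units | Why |
|---|---|---|---|
| $E$ | 15000 | MPa | mid-range of reported bovine cortical stiffness (10–22 GPa) |
| $\delta_s$ | 150 | MPa | top of reported bovine compressive-strength range |
| $\tau_s$ | 3 | MPa | the tabulated bone shear value used by the tangential law |
| $\varphi$ | 45 | deg | 90° cone of the reference tool |
| $C, \alpha$ | 707.53, 0.39 | N·mm$^{-3\alpha}$, — | reference indentation calibration |
| $C_1, C_2, C_3, \theta_0$ | 0.294, 0.934, 0.45, 0 | —, —, rad/deg, deg | reference anisotropy calibration |
| Hampel window, $k$ | 5, 3 | samples, MAD | conventional identifier defaults |
| `trim_fraction` | 0.1 | — | conservative steady-state trim |
| noise sd | 0.01 | — | realistic instrument noise, keeps log-fit unbiased |

$\tau_s$ deserves a caveat: identifying the tabulated 3 MPa "shear"
entry with the inherent shear strength is inherited from the source
calibration; it is a user-settable parameter of `bone_material()`, not
a claim of this package.

## Known limitations

* The model is quasi-static and isothermal: no cutting-speed or
  temperature dependence (the reference trials ran at 100 mm/min
  precisely to suppress heating), no tool wear.
* The sinusoid is the only anisotropy form implemented; no model
  selection across alternatives is attempted.
* Uncertainty reporting is limited to the regression diagnostics —
  no bootstrap or Bayesian intervals.
* A three-angle design cannot separate aliased phase rates; claims
  about $f_p$ between the design angles rest on the first-branch
  interpolation argument above, not on data.
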
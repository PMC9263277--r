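---
title: "Isokinetic force-velocity profiling and two-point method screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isokinetic force-velocity profiling and two-point method screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofv)
```

## The model

Across a range of imposed angular velocities, the external force a muscle
group produces during single-joint isokinetic testing declines approximately
linearly with movement velocity. The **force-velocity (F-v) profile**
summarizes this relationship by a fitted line

$$F(v) = F_0 + S_{fv}\, v, \qquad S_{fv} < 0,$$

with four canonical parameters:

* $F_0$ (N·kg^-2/3^) — force-axis intercept, the theoretical maximal force;
* $v_0 = -F_0 / S_{fv}$ (m/s) — velocity-axis intercept, the theoretical
  maximal velocity;
* $S_{fv}$ — the slope, indexing force- vs velocity-dominance;
* $P_{max} = F_0 v_0 / 4$ (W·kg^-2/3^) — the apex of the parabolic
  power-velocity curve implied by a linear F-v relationship.

Raw dynamometer torque (N·m) is divided by the lever-arm length to give
force and allometrically normalized by body mass^2/3^ to remove body-size
effects; angular velocity (deg/s) is converted to linear velocity through
the same lever arm, **in radians**: $v = \omega (\pi/180) L$. Without the
radian conversion the familiar $v_0 \approx 3\text{--}3.5$ m/s magnitudes
for the knee are unreachable, so the package treats it as non-optional.

The full protocol measures nine velocities (30--300 deg/s). The **two-point
method** fits the same line through only two of them; the practical question
the package answers is *which* pair of velocities yields parameters that
agree with the nine-point reference well enough to replace it.

## Pipeline stages

1. **Signal processing** — torque-time traces sampled at 500 Hz are
   low-pass filtered with a second-order Butterworth filter at 5 Hz. The
   filter is applied forward and backward (zero phase): the direction of
   the pass does not bias peak timing, which matters because the analysis
   keys on peak torque inside the isokinetic plateau. The plateau itself is
   detected as the maximal run where achieved velocity stays within ±5% of
   the protocol velocity for at least 50 ms; neither the tolerance nor the
   minimum dwell is standardized in the literature, so both are exposed as
   arguments with those defaults. Of the six repetitions in a set, only the
   last four are analysed (the first two serve as ramp-in), and the
   maximum peak among them is kept, ties resolved toward the earlier
   repetition for reproducibility.
2. **Profiling** — per subject, `fit_linear()` (OLS on all isokinetic
   points), `fit_polynomial()` (degree 2) and `two_point_profile()` (exact
   line) produce `fv_profile` objects. Isometric (0 deg/s) measurements are
   never included in a regression: the line is a model of the *isokinetic*
   range and its $F_0$ is then compared against measured isometric force.
3. **Agreement battery** — for each parameter and each candidate method:
   paired *t* and Cohen's *d* (mean difference / SD of differences), single
   and average two-way mixed ICC with F-distribution 95% CIs, SEM, CV% with
   a chi-square CI, minimal detectable change, Bland-Altman limits.
4. **Screening** — all $\binom{9}{2} = 36$ velocity pairs are evaluated
   per task and parameter and flagged valid when the ICC CI lower bound is
   at least 0.75, the paired-*t* p-value is at least 0.05, and the CV CI
   bound is at most 10%.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| filter cutoff | 5 | Hz | standard for torque traces at 500 Hz; well below repetition bandwidth |
| filter order | 2 | — | second-order Butterworth per pass (fourth-order zero-phase magnitude) |
| plateau tolerance | 0.05 | — | ±5% of protocol velocity |
| plateau min duration | 0.05 | s | rejects transient crossings during acceleration |
| analysed repetitions | last 4 of 6 | — | opening repetitions are ramp-in |
| normalization exponent | 2/3 | — | allometric body-mass scaling |
| ICC validity threshold | 0.75 | — | lower bound of the single-ICC 95% CI ("good") |
| bias threshold | 0.05 | — | paired-t p-value floor (no systematic bias) |
| CV limit | 10 | % | applied to the CV CI bound |

## Statistical conventions, and why

**SEM and CV.** The tables this battery is designed to mirror are
internally consistent with SEM $= s_d/\sqrt{2}$ (the within-subject SD of
a two-method design) feeding both CV% $= 100\cdot\mathrm{SEM}/\bar{x}$
(grand mean of the two method means, absolute value so negative-slope
parameters get a positive CV) and MDC $= 1.96\sqrt{2}\cdot\mathrm{SEM}$.
The standard error of the mean difference $s_d/\sqrt{n}$ is a different
quantity; `sem_cv()` reports both, labelled `sem` and `sem_n`, and CV/MDC
are built on the former.

**CV confidence interval.** Chi-square scaling with $n-1$ degrees of
freedom: bounds are $\mathrm{CV}\sqrt{(n-1)/\chi^2_{1-\alpha/2}}$ and
$\mathrm{CV}\sqrt{(n-1)/\chi^2_{\alpha/2}}$. At $n = 22$ the bound/point
ratios are fixed at 0.7694 and 1.4291, which is exactly the ratio structure
of every CV cell in the reference validity tables.

**ICC.** Two-way mixed (subjects x methods, $k = 2$), Shrout-Fleiss /
McGraw-Wong, computed from explicit mean squares. The consistency
definition is the default — it is insensitive to a fixed offset between
methods, matching how "two-way mixed" is most often run in SPSS — with
absolute agreement available by flag. Confidence intervals use the
F-distribution method; the absolute-agreement average-form interval is a
Spearman-Brown step-up of the single-form bounds.

**Cohen's d** for the paired design is the mean difference divided by the
SD of the differences. Published effect-size columns in this literature are
not always reconcilable with a single formula; this package uses exactly
one and documents it.

**Validity criteria.** The CV criterion is applied to the *lower* bound of
the CV CI, as the screening rule is stated in the source literature, even
though the upper bound would be the conservative choice;
`screening_criteria(cv_bound = "upper")` selects the conservative variant.
No multiple-testing correction is applied across the 36 x 4 tests, again
matching the source convention.

**Degenerate inputs.** Difference SDs below $10^{-10}$ of the data scale
are treated as exact zeros so that analytically identical methods compare
as identical ($t = 0$, $p = 1$, CV $= 0$) instead of producing
noise-driven statistics on $10^{-15}$-level floating-point residuals.
Exact fits have $|r| = 1$; their Fisher $z'$ is flagged infinite and
between-method fit comparisons are skipped with a reason rather than
propagating infinities.

## Numerical choices

* **Butterworth design** is by bilinear transform of the analog prototype
  with the cutoff prewarped, so the -3 dB point is exact at 5 Hz; the
  response deviates from the analog magnitude only toward Nyquist (absolute
  error < 1e-3), which the tests pin against the closed form
  $|H| = (1 + (f/f_c)^4)^{-1/2}$.
* **Zero-phase filtering** uses odd-reflection padding sized to ~3 filter
  time constants plus steady-state initial conditions, so a constant trace
  is reproduced exactly and edge transients decay inside the pads. Odd
  padding anchors the trace endpoints (the same behaviour as the common
  Python/MATLAB implementations); stopband attenuation is therefore
  measured mid-trace.
* **Polynomial $v_0$**: a concave-up quadratic fitted to decreasing data
  need not cross zero ahead of the data. The zero crossing is taken as the
  smallest real root beyond the largest observed velocity; if none exists,
  $v_0$ (and hence $P_{max}$) is flagged undefined rather than raising an
  error, since the other parameters remain meaningful. The quadratic's
  "slope" is reported at the midpoint of the observed velocity range.
* **Indexing** is 1-based and inclusive throughout, the R convention, and
  window invariants are enforced at the API boundary.
* Serialized tables carry 6 significant digits; test comparisons use
  relative tolerance 1e-6 unless an identity is asserted at 1e-9.

## The synthetic cohort: what it emulates, and what it does not

No raw cohort is distributed with the package, so validation rests on a
generator whose *stated world* mirrors the reference study's design:
$n = 22$ subjects (body mass 63.1 ± 4.4 kg, truncated at ±3 SD), nine
isokinetic velocities plus isometric, and 3% multiplicative Gaussian noise
on peak torque — consistent with the 2.5--6.4% within-individual CVs that
this literature reports.

Ground truth per subject and task is a Hill rectangular hyperbola
$(T + a)(\omega + b) = (T_{iso} + a)\,b$ with $a = c\,T_{iso}$,
$b = c\,\omega_{max}$. This single choice reproduces the two empirical
regimes the analysis must exhibit: near-linearity over 30--300 deg/s
(cohort-mean $R^2 \approx 0.95$) *and* systematic underestimation of
isometric force by the extrapolated $F_0$, because the hyperbola is convex.
Curvature $c$ is drawn uniformly from [0.15, 0.45] for knee extension
(typical for human knee musculature) and [0.25, 0.55] for knee flexion.

The remaining distributions are generator choices, not published values,
and were calibrated once against the reference study's descriptive
statistics, then frozen: knee-extension isometric torque
$\sim N(172, 18)$ N·m with $\omega_{max} \sim N(1250, 150)$ deg/s;
knee-flexion torque $\sim N(88, 12)$ with $\omega_{max} \sim N(1150, 150)$
(weaker but relatively faster, flattening the slope); lever length
$\sim N(0.35, 0.03)$ m, which maps 300 deg/s to ≈ 1.8 m/s and extrapolated
$v_0$ to ≈ 3--3.5 m/s. With these defaults the simulated nine-point
profiles land at KE $F_0 \approx 28$ N·kg^-2/3^, $v_0 \approx 3.1$ m/s,
$S_{fv} \approx -9.3$, $P_{max} \approx 22$; KF $F_0 \approx 15$,
$v_0 \approx 3.3$, $S_{fv} \approx -4.6$ — the regime of the reference
cohort.

Trace synthesis adds a kinematic layer: six repetitions per isokinetic
set, trapezoidal velocity with a plateau of at least 1.4 s, torque rising
over a 0.55 s raised-cosine edge to a flat top (slow relative to the 5 Hz
filter, so the zero-phase pass neither rings nor clips the peak — the
pipeline recovers noiseless peaks within 0.5%), ±2% repetition-to-repetition
modulation, and additive white noise (SD 1.5 N·m) on output.

**What a green test does not establish.** The generator draws independent
noise per velocity and subject; real dynamometry has correlated errors
(positioning, motivation, fatigue across the randomized velocity order),
torque-angle interaction, and gravity-correction effects, none of which are
modelled. Passing the screening property therefore shows the *method*
ranks distant combinations above adjacent ones whenever data follow a
quasilinear concave truth with multiplicative noise — it does not certify
any particular dynamometer or population. Likewise the isometric
comparison uses the same lever and normalization as the isokinetic points;
angle-specific torque differences are out of scope.

## Known limitations

* Eccentric velocities, torque-angle modelling and fatigue accumulation
  are not modelled; the generator's non-goals are explicit.
* Hyperbolic fitting of *observed* data is deliberately absent: the Hill
  form exists only as synthetic ground truth, the analysis methods under
  study being the linear, polynomial and two-point fits.
* The absolute-agreement average-ICC confidence interval uses a
  Spearman-Brown step-up of the single-form bounds, an approximation that
  is standard but slightly narrow for very small $n$.
* Printed-table reconstructions inherit the rounding of published summary
  statistics; one CV cell (4.33) back-computes to 4.335 from its own
  printed inputs, and the package reports the recomputed value.
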
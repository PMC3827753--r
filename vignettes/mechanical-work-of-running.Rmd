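---
title: "Partitioning the mechanical work of running, and scaling it to body size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the mechanical work of running, and scaling it to body size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechwork)
```

## The model

The mechanical work a runner performs per unit distance is classically
split into two parts.  *External* work, $W_{ext}$, lifts and accelerates
the body centre of mass (COM) against the environment; *internal* work,
$W_{int}$, accelerates the limbs reciprocally with respect to the COM.
Both are obtained from mechanical energy curves built from sagittal-plane
segment kinematics.

For each of the 11 rigid segments (head–trunk, upper arms, forearms,
thighs, shanks, feet) the kinetic energy relative to the COM is

$$KE_r = \tfrac12 m\,\nu_{ap,r}^2 + \tfrac12 m\,\nu_{v,r}^2
       + \tfrac12 m K^2 \omega^2,$$

where $m$ is segment mass, $\nu_{ap,r}, \nu_{v,r}$ the antero-posterior
and vertical components of the segment COM velocity *relative to the body
COM velocity*, $K$ the segment radius of gyration and $\omega$ its angular
velocity.  Segment curves are summed within each of five groups — left and
right upper limb, left and right lower limb, head–trunk — *before* taking
increments; $W_{int}$ is the sum over groups of the positive increments of
each group curve.  The ordering matters: summing first allows mechanical
energy to transfer freely between segments of the same limb, while
separate incrementing of the five groups forbids transfer between limbs or
between limb and trunk.

The COM energy is

$$E_{CM} = M g h + \tfrac12 M V_{ap}^2 + \tfrac12 M V_v^2,$$

with $h$ the COM height and $V_{ap}$ expressed in the belt frame (lab
velocity plus belt speed), so the forward kinetic term reflects the
progression speed.  $W_{ext}$ is the sum of positive increments of
$E_{CM}$ over the same window; pendular exchange between potential and
kinetic terms is implicitly allowed because they are summed first.
$W_{tot} = W_{int} + W_{ext}$, justified by König's theorem: total kinetic
energy splits exactly into the kinetic energy *of* the COM plus kinetic
energy *about* the COM.  `koenig_residual()` verifies this identity frame
by frame (it holds to machine precision whenever the body COM is the
mass-weighted mean of segment COMs, and is the package's first-line
consistency check).

Only positive increments count, over an integral number of strides: in
steady level running negative work mirrors positive work, and including it
would make the net sum zero.  Works are reported in J kg$^{-b}$ m$^{-1}$ — the
units of the energy cost of running — as $W/(M^b d)$ with $d$ the belt
distance of the window.

## Scaling and performance

Dividing by body mass ($b = 1$) overcorrects quantities that do not scale
isometrically.  The allometric alternative fits $y = a\,x^b$ to cohort
data (mass $x$, absolute $\dot VO_{2max}$ $y$) by ordinary least squares
on the double-logarithmic plot, $\log y = b \log x + \log a$
(`fit_allometric()`, base-10 logs; OLS on logs rather than nonlinear least
squares because the noise is multiplicative).  Mass-specific quantities
are then rescaled per subject as $v\,M^{1-b}$ (`rescale_specific()`);
rescaling group means by the group mean mass is only an approximation, and
the package treats the per-subject path as canonical.  The
work–performance relationship is summarised per component and exponent by
Pearson's $r$ with the least-squares prediction line, performance encoded
in seconds (`work_performance_table()`).

## From markers to energies

* **Filtering.**  A second-order Butterworth filter is applied forward and
  backward (zero lag, effective fourth order) to every marker coordinate.
  Zero lag is obligatory before differentiation.  The cut-off is chosen
  per marker by Winter's residual analysis — the RMS residual between raw
  and filtered series versus candidate cut-offs, intersected with the
  extrapolated high-frequency noise line (within 1% of the series SD) —
  and clamped to 8–11 Hz, the range appropriate for running kinematics at
  240 Hz.  Implementation detail: series are demeaned before
  `signal::filtfilt` (whose filter state starts at zero) and padded by odd
  reflection over $3/f_c$ seconds, so constants pass through exactly and
  edge transients stay far below marker noise.
* **Differentiation.**  Central differences in the interior, one-sided at
  the record ends; exact on linear series, and for a 1 Hz sinusoid at
  240 Hz accurate to about $7\times10^{-4}$ of the peak derivative in the
  interior.  Stride windows are always interior, so the first-order end
  frames never enter a work computation.
* **Stride segmentation.**  Stride boundaries are successive minima of
  the heel marker's vertical position.  The period is first estimated from
  the dominant autocorrelation peak within 0.3–2 s (records whose peak
  autocorrelation falls below 0.3 are rejected as non-periodic); one
  boundary is then placed at the deepest sample in each period-length
  search window, and the last five complete strides form the analysis
  window (half-open in inter-frame steps, so it spans whole periods).
* **Contralateral reconstruction.**  Only the left side is filmed.  The
  right side is reconstructed by delaying the left limb trajectories half
  a stride *relative to the hip marker* and re-attaching them to the
  pelvis at the current time.  A plain time shift of the whole marker
  would also delay the pelvis' own oscillation — which is common to both
  sides — and inject spurious anti-phase COM motion into the estimated
  limbs: a rigidly bouncing body would acquire nonzero internal work.
  The pelvis-anchored shift leaves rigid motion rigid (`anchor = NULL`
  restores the plain shift for comparison).
* **Gap handling.**  Missing marker samples are linearly interpolated up
  to 5 frames with a warning; longer gaps abort the load with the frame
  index.

Tunable parameters and defaults: capture rate 240 Hz; belt speed
3.1 m s$^{-1}$; five strides; cut-off clamp 8–11 Hz; exponents
$b \in \{1, 0.75\}$ plus any cohort-fitted value; gravitational
acceleration 9.81 m s$^{-2}$.  Anthropometry comes from a bundled
body-segment-inertial-parameter table (Winter/Dempster fractions by
default, a de Leva-derived set as alternative, or any user file in the
same format).  The study this lineage of methods comes from does not name
its anthropometric source, so exact work values are not bit-reproducible
from video even in principle; the table is configuration, not code.  Hands
are merged into the forearms and the head into the trunk so that nine
markers per side define all 11 segments.  Segment length is the frame-wise
proximal–distal marker distance and $K$ uses its mean over the analysis
window (rigid-segment assumption).

## What the synthetic data certify — and what they do not

`generate_gait()` builds a fully analytic gait: the pelvis follows
$h_0 + A\sin(2\pi f t)$ at the stride frequency $f$ while the belt
supplies progression, and limb angles are sinusoids at $f$ with fixed
amplitudes and phases.  Defaults: $f = 1.4$ Hz, $A = 5$ cm, thigh swing
0.35 rad about a slightly forward mean, knee flexion $0.45 \pm 0.35$ rad a
quarter-cycle out of phase (breaking half-stride symmetry the way
stance/swing asymmetry does), arms anti-phase to the ipsilateral leg, and
2 mm Gaussian marker noise emulating digitisation error.  The
antero-posterior pelvis oscillation is phased a quarter-cycle behind the
vertical one so that the forward-velocity fluctuation peaks with rising
COM height — the in-phase energy fluctuation that distinguishes bouncing
gaits like running from pendular walking, and the reason the default
preset is external-work dominated.

Ground truth comes from a brute-force oracle: marker positions evaluated
on a dense grid (10 kHz) spanning exactly five stride periods, central
differences on that grid, positive increments summed directly — no
filtering, no event detection, no side reconstruction from data.  Doubling
the grid rate changes the result by well under 0.1%.  The pipeline at
240 Hz, with its 8 Hz filters and detected stride windows, reproduces the
oracle's per-distance $W_{int}$ and $W_{ext}$ within 0.5% on the
noise-free gait; degenerate inputs behave exactly (static body: zero
work; rigid translation: zero internal work; equal-amplitude anti-phase
potential and kinetic COM energy: zero external work).

Deliberate simplifications, and their consequences: all prescribed
oscillations sit at the stride frequency, below the filter band, so
filter-induced distortion is a sub-percent effect by construction — real
running has impact transients well above 8 Hz that the filter removes by
design, and a real pelvis bounces at *step* (twice stride) frequency.
Because the synthetic COM completes one oscillation per stride instead of
two, per-distance works sit below typical treadmill values (the pipeline
prints about 0.33/0.83 J kg$^{-1}$ m$^{-1}$ for $W_{int}$/$W_{ext}$ versus
roughly 0.6/1.2 reported for recreational runners).  Passing these tests
therefore certifies the computation chain — filtering, differentiation,
segmentation, energy bookkeeping, scaling — not the physiological realism
of the waveforms, and says nothing about soft-tissue artefact, marker
misplacement or elastic energy storage, none of which the model contains.

Cohort generators mirror the statistical structure instead:
`generate_vo2_cohort()` draws masses from a truncated normal
(70 ± 10.2 kg, > 40 kg) and imposes
$\dot VO_{2max} = a M^b 10^\varepsilon$ (defaults $a = 454$, $b = 0.49$,
$\sigma_\varepsilon = 0.03$, placing a 70-kg runner at about
52 ml kg$^{-1}$ min$^{-1}$).  Across 500 such cohorts of $n = 14$ the
log–log fit recovers $b$ with bias below 0.01 and t-based 95% CI coverage
above 93% — at this sample size a single cohort's $\hat b$ still carries a
standard error near 0.1, which is why the recovery experiment, not any
single fit, is the certificate.  `generate_runner_cohort()` draws works
around 0.63/1.22 J kg$^{-1}$ m$^{-1}$ and constructs performance times so
the *sample* correlation with $W_{ext}$ equals the target exactly: the
noise vector is orthogonalised against $W_{ext}$ (regression residuals)
and scaled to $|s|\,\mathrm{sd}(W_{ext})\sqrt{1/r^2 - 1}$, making the
empirical correlation $r$ by algebra rather than asymptotics.  Defaults
use the prediction line slope 2649 s per J kg$^{-1}$ m$^{-1}$ and
intercept −621 s, so mean performance lands near 44 min for 10 000 m.

## Numerical choices and limitations

Work integration is frame-wise discrete (no spline fitting), consistent
with the positive-increment definition; windows span whole strides so the
sum is invariant to where the window starts on a periodic signal.  Angles
are unwrapped before differentiation.  Degenerate inputs are handled
explicitly: non-periodic records are refused by the stride detector
rather than silently segmented, and a window can be supplied manually for
inputs (like a static pose) where stride detection is meaningless.  With a
zero belt speed the normalising distance falls back to the COM's
horizontal displacement and may legitimately be zero, in which case only
absolute works are reported.  Negative work is deliberately not reported.

The main limitations are those of the 2-D sagittal, rigid-segment,
symmetric-gait approach itself: no frontal/transverse motion, no
force-platform cross-validation of $W_{ext}$, contralateral kinematics
assumed to be a half-stride delay, and body-segment parameters taken from
cadaver-derived tables rather than the individual.  Analyses at other
speeds or with pathological (asymmetric) gait violate the mirroring
assumption and need both sides filmed.
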
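---
title: "Simulating and analyzing reach-to-grasp kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing reach-to-grasp kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachgrasp)
```

## The problem this package addresses

In psycholinguistic motor-control experiments, participants read a
sentence fragment (a subject pronoun -- *I*, *YOU*, *HE* -- followed by
an action or interaction verb) and, as soon as the verb is
identifiable, reach for and grasp a target object while their hand is
tracked by a motion-capture system. The hypothesis under test is that
the linguistically induced perspective modulates movement planning,
visible in the *transport* component of prehension: in particular the
latency of the wrist velocity peak, normalized by the reach time. A
longer deceleration phase (earlier normalized peak) is the signature of
planning a subsequent act, as interaction verbs like *to give* imply.

No raw data are deposited with studies of this kind, so the package is
built around a synthetic-data generator with known ground truth. Every
stage of the analysis -- filtering, movement segmentation, parameter
extraction, trial rejection, participant exclusion, and the
within-subject inference layer -- is implemented as a tested, reusable
function, and the generator lets us verify each stage by parameter
recovery rather than by eyeballing.

## The kinematic model

### Speed profile

A point-to-point reach is generated from a one-parameter family of
bell-shaped speed profiles,

$$ v(\tau) \propto \tau^{a}(1-\tau)^{b}, \qquad
   a = s\,f, \quad b = s\,(1-f), \quad s = 4, $$

where $\tau \in [0,1]$ is normalized movement time and $f$ the fraction
of the duration at which the speed peaks (the mode of the bell is at
$a/(a+b) = f$). The profile is scaled so its time integral equals the
reach amplitude $D$; positions come from the closed-form beta CDF, so
path length carries no quadrature error. At $f = 0.5$ the profile is
exactly the minimum-jerk speed curve $v = (30D/T)\,\tau^2(1-\tau)^2$
with peak speed $1.875\,D/T$ -- the classical model of unconstrained
reaching. A single parameter therefore controls the study's key
dependent variable (the normalized velocity-peak latency) while keeping
the profile smooth and unimodal.

The wrist travels along a fixed transport direction with small
components on all three Cartesian axes, so that per-axis displacement
thresholds are all exercised; a strictly axis-aligned path would make
two of the three axis thresholds degenerate. Index and thumb markers
sit at $\pm$ half the aperture along a fixed grip axis orthogonal to
the transport direction, which makes the inter-marker distance equal
the aperture profile by construction. The aperture opens from a resting
pinch (5 mm) to its maximum (85 mm by default) and closes back,
following the same beta bell; the aperture peak sits at 66% of the
grasp duration by default. The grip magnitudes and timing are
conventions -- typical values for grasping a computer mouse -- because
no aperture norms are published for this paradigm; only the reach
parameters carry published calibration values.

### Trial timeline

The trial clock is anchored at verb-stem onset ($t = 0$): the stimulus
sequence is fixation (1000 ms), pronoun (500 ms), verb stem (500 ms),
suffix (500 ms), and a movement that starts before $t = 0$ -- before
the verb could be identified -- is an *anticipation* and is rejected.
Movement onset is reaction time plus noise (default 250 ± 50 ms);
recordings keep a 100 ms margin before $t = 0$ and after movement end.

## Segmentation rules and their calibration

Two published rule variants are implemented:

* **Displacement rule** (60 Hz optical capture): reach onset is the
  first frame whose wrist displacement exceeds 0.3 mm on all three
  axes; reach end is chosen among the three per-axis candidates (first
  frame after the velocity peak with per-axis displacement below
  0.3 mm) as the one closest in time to the grasp end.
* **Velocity rule** (200 Hz electromagnetic capture): the reach spans
  the first through last frame with wrist speed above 1 mm/s.

Positions are low-pass filtered before any differentiation
(order-2 Butterworth applied forward and backward, cutoff 10 Hz by
default; the filter design is delegated to the `signal` package, the
zero-phase application is compiled code validated against
`signal::filtfilt`). The source studies report only "a linear smoothing
low pass filter"; cutoff and order are configurable.

Two readings of the displacement rule are genuinely open and both are
implemented: *frame-to-frame* displacement (default) versus
*cumulative* displacement from rest, selectable via
`segmentation_config(displacement_mode=)`. The frame-to-frame reading
is the default because the same 0.3 mm figure also defines the
end-of-motion rule, which is only meaningful for instantaneous motion.
For the grasp end we found the frame-to-frame reading degenerate on
smooth data -- the aperture slope vanishes at the maximum itself, so
the "first frame after the maximum with change below threshold" is
always the very next frame. The default grasp end is therefore the
first frame after the maximum at which the aperture has *returned to
within 0.3 mm of its resting value*, mirroring the onset rule; the
literal frame-step reading remains available
(`grasp_offset_mode = "step"`).

### Why the generator is calibrated to the rules

Threshold rules only see a movement once it is fast enough: with a
smooth speed profile the detected onset is late and the detected offset
early, so the rule-defined reach time is systematically shorter than
the support of the underlying profile, and the rule-defined peak
latency is shifted. The generator therefore treats the requested
condition means as *rule-defined* quantities: it solves for underlying
profile parameters (duration, peak fraction, grasp duration) such that
the full extraction pipeline, averaged over sub-frame onset phases,
recovers exactly the requested values. Noise-free configurations are
solved exactly at the six condition cells; noisy configurations use a
bilinear correction surface on a 9 x 9 grid spanning the configured
means ± 4 SD, cached per configuration.

Frame quantization is handled by *stratified onset dithering*: the
trials of one condition cell receive reaction-time offsets evenly
spread across one sample period, so quantization error averages out in
cell means instead of biasing them. With reaction-time noise enabled
the dither is simply absorbed into the continuous onset distribution.

## Quality control and inference

Trial rejection follows the published rules: linguistic errors (wrong
match/mismatch response; planted by the generator at a configurable
rate, default 1.5%, since they are not recoverable from kinematics),
anticipations ($t_\mathrm{onset} < 0$), segmentation failures, and
catch trials (person-mismatched pronoun-verb pairs, generated with
normal kinematics but never analyzed). Participants with *less than*
50% valid critical trials are excluded -- the boundary is read
literally, so exactly 50% is retained.

Inference operates on per-subject condition means (2 verb types x 3
pronouns, complete cells required):

* **Repeated-measures ANOVA** via the classical within-subject
  decomposition (each effect tested against its subject-by-effect
  stratum; `stats::aov` under the hood, verified against an explicit
  sums-of-squares oracle to 1e-10). Partial eta squared is reported as
  $F \cdot df_1 / (F \cdot df_1 + df_2)$. No sphericity correction is
  applied by default, matching the reported uncorrected degrees of
  freedom; Greenhouse-Geisser is available behind `gg = TRUE`.
* **Planned paired comparisons** of action vs. interaction verbs within
  each pronoun. One-sided p-values are the default because the
  published t/p pairs (e.g. t(11) = 2.81, p = 0.008; t(11) = 0.56,
  p = 0.3) are consistent with one-sided, not two-sided, tails. The
  published values take the tail on the side of the observed
  difference, whose direction differs across pronouns; the default
  `direction = "observed"` reproduces this and records which side was
  used, while a-priori directions and two-sided tests are available.
  The corrected alpha defaults to Bonferroni $\alpha/k$; a fixed
  preregistered level (0.01) is available via `correction = "fixed"`.
* **JZS Bayes-factor ANOVA** comparing the full model (verb + pronoun +
  interaction + subject) against the subject-only null under
  Jeffreys-Zellner-Siow default priors (fixed-effect scale 1/2, subject
  scale 1, both configurable). In the balanced design the orthonormal
  contrast blocks are mutually orthogonal, so conditional marginal
  likelihoods have a closed form and only the per-block $g$ parameters
  are integrated, by seeded Monte Carlo over their scaled
  inverse-chi-squared priors; the Monte Carlo standard error is
  reported. This is an original implementation (no Bayes-factor package
  is assumed); its behavior is validated by property tests: reciprocal
  consistency, null-favoring under the null, monotone growth with the
  interaction strength, and error decay with the number of draws.

## Numerical and design choices

* Velocity-peak ties break to the first qualifying frame; no sub-frame
  interpolation anywhere, since published movement times are
  frame-quantized at 60 or 200 Hz.
* If grasp segmentation fails in the displacement variant, the reach
  end falls back to the latest per-axis candidate and the trial is
  flagged rather than dropped silently.
* Position noise defaults to 0.05 mm (optical tracking floor) in the
  60 Hz preset and 0.01 mm in the 200 Hz preset: the 1 mm/s velocity
  threshold is extremely noise-sensitive, and an electromagnetic
  tracker's effective noise after low-pass filtering is of this order.
* Between-subject and trial-level variability act on the kinematic
  parameters themselves (random subject offsets and independent trial
  deviations; the grasp window shares the reach-window deviations,
  since transport and grip are components of one movement).
* All randomness flows from one master seed through a counter-based
  per-subject/per-trial stream, so any single trial can be regenerated
  in isolation and full datasets are reproducible byte-for-byte.
* Rounding in the report tables is half-away-from-zero at one decimal,
  the convention of the published summary table.

## Default study sizes

The two presets mirror the published designs: `exp1_italian` -- 12
subjects, 60 Hz, 330 mm reach, 5 critical trials per cell plus 10 catch
trials (one block of 40); `exp2_german` -- 13 subjects (the analyzed
sample), 200 Hz, 350 mm reach, 14 critical trials per cell plus 16
catch trials (one block of 100). The parameter-recovery study used in
the acceptance checks runs 200 simulated experiments of the Italian
design with trial-level SDs of 2 percentage points (normalized latency)
and 30 ms (reach time) and a between-subject SD of 1.5 percentage
points; property simulations of the inference layer (type-I error,
power, Bayes-factor behavior) run at the subject-means level with 500
replicates, which is the scale those procedures actually consume.

## What the generator does and does not emulate

It emulates: the factorial within-subject design, sampling rates and
amplitudes of both recording systems, realistic condition means,
between-subject and trial variability, catch trials, linguistic errors,
anticipations, measurement noise, and frame quantization. It does not
emulate: biomechanically realistic hand posture or forces, object
contact dynamics, the post-click placing movement (excluded from
analysis in the source studies), visual stimulus rendering, or
reaction-time effects beyond a constant-plus-noise offset. Passing
recovery tests on synthetic data therefore demonstrates correctness of
the *pipeline*, not validity of the motor model for any particular real
dataset.

## Known limitations

* The aperture's normalized peak latency is recovered with a constant
  offset (about 4-6 percentage points below the generating fraction)
  because the grasp onset threshold cuts a longer slow-opening phase
  than the slow-closing phase it cuts at the end; reach-side parameters
  are calibrated, grip-side normalized latency is not, as no published
  values exist to calibrate against.
* The exact-reciprocity property BF10 x BF01 = 1 holds by construction;
  published BF pairs that are not exact reciprocals (printed rounding)
  are not reconciled.
* With extreme configurations (velocity thresholds far above the peak
  speed, cutoffs near Nyquist) segmentation legitimately fails; the
  flags are the supported behavior, not exceptions.
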
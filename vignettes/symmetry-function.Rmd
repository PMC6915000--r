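---
title: "The time-continuous symmetry function: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The time-continuous symmetry function: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(gaitsf)
```

## The problem

Classical gait-symmetry indices (Robinson's SI, the symmetry angle, ratio
indices) compress a whole stride into one number, usually computed from a
single pair of peak values. That hides *where* in the cycle the two limbs
diverge, and it is exactly the location of asymmetry — early loading, push
off, swing — that matters for rehabilitation after a unilateral
intervention such as total hip replacement (THR). This package implements a
time-continuous alternative: the **symmetry function**

$$
\mathrm{SF}(t) \;=\;
\frac{x_1(t) - x_2(t)}
     {\tfrac12\,\bigl(\mathrm{Range}[x_1] + \mathrm{Range}[x_2]\bigr)}
\cdot 100\%,
$$

where $x_1(t)$ and $x_2(t)$ are the two sides' joint-angle curves over one
gait cycle (time expressed as 0–100 % cycle time, %CT) and
$\mathrm{Range}[x] = \max_t x(t) - \min_t x(t)$ is the scalar range of
motion (ROM) of each curve over the whole cycle. The sign follows the first
curve: positive SF means the first side runs higher at that instant
(`canonical_sign_labels()` fixes which side is "first" in each of the three
standard comparisons).

Two properties define the index and are worth stating precisely:

* **The denominator is a constant per comparison**, not a time-varying
  quantity. This is the only reading under which the index's calibration
  anchors hold: a constant 1° side difference reads 20 % against 5°-range
  curves and 2 % against 50°-range curves, and two equal-range curves whose
  extremes are opposite and simultaneous touch ±200 %.
* **SF is deliberately range-relative.** The same angular difference reads
  very differently against a small and a large excursion. This is a feature
  (it matches how symmetry indices are interpreted clinically) but also the
  index's main caveat: for a movement with a tiny range, measurement noise
  dominates the percentage. `symmetry_function()` therefore refuses pairs
  whose mean range falls below `eps` (default $10^{-6}$°) instead of
  returning arbitrarily inflated values; the report functions carry the
  underlying ROM so readers can judge a large SF against the excursion it
  is relative to.

Algebraically the index is antisymmetric under swapping curves, invariant
to a common additive shift and to a common positive scaling, and responds
to a one-sided constant offset $\delta$ by the constant
$100\,\delta / \tfrac12 (r_1 + r_2)$. The test suite asserts all four
properties, plus agreement with a direct loop transcription of the
definition, at $10^{-9}$ relative on 1,000 random curve pairs.

## Time normalisation

Gait cycles arrive with different durations and sampling rates, so both
sides are first resampled to a canonical 101-point grid (0, 1, …, 100 %CT),
the first sample defining 0 %CT and the last 100 %CT. `time_normalize()`
evaluates, at each grid point, the **local Lagrange interpolating
polynomial** through the four nearest samples (a cubic window, clamped at
the record ends). Design notes:

* A *single* global Lagrange polynomial over a ~130-sample cycle would
  oscillate wildly between samples (Runge's phenomenon); short windows keep
  the fit stable while preserving the interpolation property.
* The interpolant passes through the samples, so input already on the grid
  is returned **bit-identically** (tested), and cubics are reproduced
  exactly. A 120 Hz sine over a 1.1 s cycle resamples to the analytic curve
  within $10^{-4}$° — far below both instrument noise and any physiological
  effect.
* No detrending or smoothing is applied: within one cycle the angle *is*
  the signal, and filtering of marker noise is upstream of this package's
  responsibility.

## Parameterisation, phases and classification

Every curve — angle or SF — is summarised by `parameterize()` into
$\{\mathrm{Peak}^{\min}, t_{\min}, \mathrm{Peak}^{\max}, t_{\max},
\mathrm{ROM}\}$, with ties broken at the first grid occurrence and
$\mathrm{ROM} = \mathrm{Peak}^{\max} - \mathrm{Peak}^{\min}$ holding
identically. Peak times of the SF curve are mapped to Perry's gait phases
(LR 0–10, MSt 10–30, TSt 30–50, TDSt 50–60, ISw 60–73, MSw 73–87, TSw
87–100 %CT; IC 0–2 %CT overlaps LR and is carried as a flag). Phase
intervals are treated as half-open $[\mathrm{start}, \mathrm{end})$ with
100 %CT assigned to terminal swing; the printed boundaries touch without an
assignment rule, and the half-open convention is the standard way to make
them a partition.

Magnitude classification follows the symmetry-index literature's
conventions: summaries below 10 % are typical of non-injured gait, 15 % or
more is associated with injury, and the band between is reported as
*borderline*. The conventions bound a scalar summary rather than a curve,
so `classify_asymmetry()` lets the user choose the statistic: the default
`peak_abs` (the larger absolute SF peak, the conservative choice — a single
instant above threshold flags the subject) or `mean_abs` (the cycle mean of
|SF|, smoother and closer in spirit to single-number indices).

## Cohort aggregation and statistics

`group_param_table()` aggregates in a fixed, documented order: parameters
per cycle → mean within subject → mean ± unbiased SD across subjects. This
order weights subjects equally regardless of their cycle counts, which is
the defensible default for a cohort table built from a repeated-trials
design (three walks of three cycles each). Peak times are averaged linearly
in %GC; peaks that straddle the 0/100 wrap would need circular statistics,
which we deliberately do not apply — such entries should be read with care.

Cohort SF curves can be built two ways, and `sf_compare()` provides both
because they answer different questions: `per_subject` computes one SF per
subject from the subject's cycle-mean side curves and then summarises
across subjects (each subject's asymmetry is measured against their own
ROM), while `mean_curve` compares the two group-ensemble curves once
(group-typical waveform differences, at the price of averaging away
between-subject phase variability). The per-subject mode is the package
default.

`compare_params()` implements the conventional clinical protocol: a
Shapiro–Wilk screen on each sample, then a parametric *t*-test at
$\alpha = 0.05$ — **paired** for side comparisons (both sides are measured
on the same subjects; pairing is forced by the design) and **Welch's**
two-sample test for group comparisons (patient groups show visibly larger
variance than controls, so the pooled-variance variant is not defensible).
A failed normality screen flags the row and warns but does not switch to a
nonparametric test, mirroring how such protocols are actually applied; no
multiple-testing correction is added. The acceptance suite calibrates the
pipeline's type-I error at $n = 12$ per side over $10^4$ null replicates
and requires it to sit in $[0.04, 0.06]$.

## The synthetic cohort generator

No subject-level reference recordings ship with the package, so validation
rests on `simulate_subject()` / `preset_cohort()`: truncated Fourier
series (≤ 3 harmonics per joint) with phases placing the peaks at
physiologically sensible instants, rescaled exactly to target ROM and
midrange per joint. The healthy preset calibrates to typical slow-walking
sagittal magnitudes (hip ≈ 44°, knee ≈ 57°, ankle ≈ 32° ROM); the uTHR
preset models the early post-operative pattern on top of an
uninvolved-side template (hip ≈ 19°, knee ≈ 34°, ankle ≈ 30°, pelvis ≈ 4.8°
ROM, elevated anterior pelvic baseline) with per-joint mechanisms:

* **pelvis**: preserved range but a near half-cycle (47 %CT) between-side
  phase shift — the mechanism that makes pelvic tilt the *largest* SF of
  all joints (≈ ±100 %) despite its small ROM;
* **hip**: involved-side excursion scaled to ≈ 12.6/19 of the uninvolved,
  plus a +5.8° midline shift (restricted extension);
* **knee, ankle**: enlarged involved-side excursions (≈ ×1.35) with small
  offsets, the compensatory pattern.

Asymmetry mechanisms are built to be separable: amplitude scaling acts
about the template's analytic mean (the Fourier baseline), so it leaves the
mean untouched, while an offset leaves the range untouched — each mechanism
then has a closed-form SF oracle, and the zero-noise pipeline must
reproduce it to $10^{-9}$. Those closed-form checks sample the template
exactly at the 101 grid points, where normalisation is the identity; at
120 Hz continuous sampling, cubic-interpolation error (~$10^{-4}$°) would
obscure what is being tested. Noise-bearing checks use the realistic
120 Hz path.

Subject-level jitter (amplitude CV 5 %, baseline SD 0.8°, cycle-duration SD
0.05 s) is applied identically to both sides so that it never manufactures
asymmetry; measurement noise (i.i.d. per sample; 0.15° healthy preset,
0.25° patient preset) is the only symmetric noise source. Two calibration
choices deserve explanation:

* **Healthy pelvic ROM defaults to ~3°** (`pelvis_rom = "literature"`),
  with a `"table"` switch for the ~1° values some speed-matched cohorts
  report. Against a ~1° denominator even fractions of a degree of
  instrument noise read as tens of percent — the small-range instability
  discussed above — and a healthy cohort would stop looking symmetric for
  reasons that have nothing to do with gait. With the ~3° default and the
  0.15° noise level, the expected peak of the noise-induced SF per subject
  (the extreme of ~101 differences of two cycle-averaged noise terms,
  roughly $100 \cdot 3\sigma\sqrt{2}/(\sqrt{9}\,\cdot 3°) \approx 7\%$)
  stays under the 10 % threshold, so the healthy median classification is
  "symmetric" at every joint — the behaviour a generator of *normal* gait
  must show.
* **Noise inflates SF ROM upward** — extremes of a noisy curve are biased
  outward — so the suite asserts mean SF ROM increases monotonically in
  `noise_sd` rather than pretending noise is harmless.

What the simulator does *not* emulate: within-subject stride-to-stride
waveform variability beyond additive noise, kinematic cross-talk between
joints, soft-tissue artefact, gait-event detection error, and any kinetics.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* is correct and well-calibrated, not that any clinical effect
size will reproduce in new patient data.

## A worked comparison

```{r uthr, fig.alt = "SF curve for pelvic tilt, uTHR preset"}
cohort <- preset_cohort("uTHR", n_subjects = 12, seed = 42)
cmp <- sf_compare(cohort, mode = "uTHR_sides")
cmp
summary(cmp$joints$pelvis_tilt$sf)
plot(cmp$joints$pelvis_tilt$sf)
```

The pelvic-tilt SF dwarfs the other joints and peaks at the end of loading
response and in terminal double stance — the signature of a phase-shifted,
small-range movement — while the hip shows one-sided (involved-side
deficient) asymmetry throughout. A healthy cohort under the same pipeline
stays within the 10 % band at every joint:

```{r normal}
healthy <- preset_cohort("normal", n_subjects = 13, seed = 43)
cmp_n <- sf_compare(healthy, mode = "normal_LR")
subset(cmp_n$summary, parameter == "peak_abs")
```

## Numerical choices and limitations

* Grid: 101 points, 1 %CT. `n_points` is configurable for testing only.
* Degenerate ranges: mean ROM below $10^{-6}$° raises a classed error
  (`gaitsf_degenerate_range`; CLI exit code 3).
* Tie-breaks: curve extremes report their first grid occurrence.
* Problem sizes used by the validation suite — 1,000 random pairs for the
  algebraic invariants, 20 seeds × 5 noise levels for the noise-bias
  check, $10^4$ replicates for the type-I calibration, 12 + 13 synthetic
  subjects at 9 cycles for the cohort-level checks — were chosen as the
  smallest sets that make the corresponding sampling error negligible
  relative to the tolerance being asserted.
* SF is not normalised across joints: values are only comparable within a
  joint/degree of freedom, and reported SF should always be accompanied by
  the movement (or absolute angular difference) it refers to.
* Cycle segmentation and gait-event detection are out of scope: inputs are
  per-cycle traces, and 0/100 %CT are defined by the trace endpoints.
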
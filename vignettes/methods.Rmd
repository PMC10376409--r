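---
title: "Measuring the spatial precision of cortical feedback by cross-shift decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the spatial precision of cortical feedback by cross-shift decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftdecode)
```

## The scientific question and the analysis it requires

Primary visual cortex (V1) neurons have small, retinotopically precise
receptive fields, yet their responses are contextualised by feedback from
higher visual areas whose receptive fields span several degrees of visual
angle. One way to measure the *spatial precision* of that feedback is the
occluder paradigm: mask one quadrant of a natural scene so the corresponding
V1 region receives no informative feedforward drive, record multivoxel fMRI
patterns from that non-stimulated region, and ask whether a classifier
trained to discriminate two scenes still discriminates them when the test
images are *spatially shifted* versions of the training images. The largest
shift at which decoding transfers above chance estimates the precision of
the contextual feedback signal.

`shiftdecode` implements that analysis end to end — and, because no public
dataset exists for this paradigm, it also implements a synthetic-data
generator whose ground truth makes every stage testable. The pipeline is:

1. **simulate** multi-run BOLD-like sessions whose condition patterns have a
   controlled similarity decay across shifts;
2. **estimate** single-trial response amplitudes (betas) with an OLS GLM
   after temporal high-pass filtering;
3. **select** a feedback (occluded) and a feedforward (stimulated) region of
   interest from checkerboard-mapping contrasts;
4. **decode** scene identity with a linear SVM under leave-one-run-out
   cross-validation, within and across shifts, scoring single trials (ST) or
   averaged blocks (AB);
5. **infer** group means and middle-95% confidence intervals with a
   two-level bootstrap, plus permutation tests of condition differences.

## The generative model

### Cross-shift pattern similarity

The object of interest is the correlation structure of the scene-specific
voxel patterns across spatial shifts. We model it with a Gaussian similarity
kernel: for tuning width $\sigma$ (degrees),

$$\rho(\Delta) = \exp\!\left(-\frac{\Delta^2}{2\sigma^2}\right),$$

where $\Delta$ is the shift difference in degrees. For each scene image, the
patterns at the design's shift levels are drawn *jointly* from a zero-mean,
unit-variance multivariate normal over shifts with covariance
$K_{jk} = \rho(|s_j - s_k|)$ (`make_patterns()`). This makes the expected
correlation between any two shifts — not only pairs involving the unshifted
condition — exactly $\rho$ of their difference, which matches the analysis
convention that the tested quantity is the absolute train–test shift
difference. (The simpler anchored construction
$p(s) = \rho(s)\,b + \sqrt{1-\rho(s)^2}\,e$ gives correlation
$\rho(s_1)\rho(s_2)$ for shifted–shifted pairs; for the `{0, 3, 7}` design
that is 0.007 between 3° and 7° instead of $\rho(4°) = 0.25$, which would
make the 4° cross-classification condition — the decisive one — impossible
by construction. We therefore use the joint draw.)

Patterns of different images are independent; each subject draws fresh
patterns. With $V$ voxels per region, the *realised* correlation of a
subject's patterns scatters around $\rho$ with SD $\approx (1-\rho^2)/\sqrt{V}$
— at the default $V = 150$ that is $\pm 0.08$, a deliberate and realistic
source of between-subject variability in cross-decoding.

### Design, timing, and the trial schedule

`experiment_design()` encodes the block protocol: two scenes × three shifts
(six image conditions) and three mapping checkerboards (`target`,
`surround1`, `surround2`). A trial is a 12 s block — the stimulus flickers
200 ms on / 200 ms off 30 times, which appears in the model only as the
duration arithmetic $30 \times 0.4\,\mathrm{s} = 12\,\mathrm{s}$; at TR = 1 s
the flicker itself is not resolvable and a trial is a 12 s boxcar. An image
sequence presents the six image conditions once each in random order (72 s),
preceded by a 12 s fixation period. Six image sequences and three mapping
sequences (each: the three checkerboards twice, 72 s) plus a trailing
fixation give a run of 768 s (12 min 48 s) — 36 image and 18 mapping trials
per run over four runs. Two initial volumes per run are generated and later
discarded by the GLM stage (T1-saturation convention). The number of image
sequences per run (hence trials per condition per run) is exposed as
`sequences_per_run` with default 6.

### Signal and noise

Ground truth assigns voxel blocks (`roi_layout()`, 150 voxels per region by
default plus 150 inert voxels): feedback voxels respond to the `target`
checkerboard (amplitude `map_amp = 3` noise-SD units) and carry
`snr × pattern` on image trials *with no mean image response* — the occluded
region receives no informative feedforward drive, so scene information lives
only in the pattern. Feedforward voxels respond to every image trial
(`ff_mean = 2`) plus their own `snr × pattern`; surround voxels respond to
their checkerboard and to images without scene-specific structure.

Each trial's boxcar is convolved with a canonical double-gamma HRF
(`canonical_hrf()`: response gamma with mode at 6 s, undershoot gamma with
mode at 16 s, peak:undershoot ratio 6, peak normalised to 1), scaled per
voxel by the amplitude above and per trial by $(1 + \text{jitter})$,
jitter $\sim N(0, 0.1)$. Noise is stationary AR(1)
(lag-1 coefficient 0.3, SD 1) plus slow per-voxel drift (random mixture of a
linear ramp and a half-cycle cosine, coefficient SD 1.5). These noise values
are package choices of plausible magnitude for 3 T block-design data — real
scanner noise additionally has spatial correlation, physiological components
and motion residuals that the generator does not emulate, so passing tests
demonstrate correctness of the *analysis*, not performance on real data.

All randomness flows from one master seed through a documented counter
scheme (`derive_seed()`), so any subject, run, or bootstrap stream can be
regenerated in isolation and a session is reproducible bit for bit.

## Single-trial GLM

`estimate_trial_betas()` drops the first two volumes of each run, high-pass
filters, and fits one HRF-convolved regressor per trial (images *and*
mapping trials, which keeps the single-trial model saturated) plus an
intercept and linear trend, per run, by OLS. Filtering is projection onto
the complement of an intercept + linear trend + discrete-cosine basis of all
frequencies below 0.006 Hz; the same projection is applied to the task
regressors, which by the Frisch–Waugh theorem equals including the filter
basis in the model and leaves trial amplitudes unbiased. (The projection
form was chosen because it is deterministic and directly testable; the test
suite verifies filter-the-data equals model-the-basis to 1e-8.) OLS rather
than prewhitened GLS is used despite the AR(1) noise: the betas feed a
classifier, not parametric t-tests, and OLS is the standard default for
single-trial estimation in this setting. The one place where nominal t
distributions matter — the null calibration of ROI selection — is tested
with white noise for exactly that reason.

## ROI selection

`select_rois()` mirrors the localiser logic. The *feedback* mask is
`t(target − surround1) > 3` with voxels responding to either surround
checkerboard (t vs baseline above threshold) excluded, minimising lateral
spillover; `surround1` is the near surround. The localiser GLM for this mask
collapses all image conditions into a single regressor, so the mask is
*exactly* invariant to any relabelling of the scenes — the decoding labels
cannot leak into voxel selection (a guard test shuffles labels and asserts
bit-identical masks). The *feedforward* mask is a conjunction: t vs baseline
above threshold for *every* image condition. The default threshold t > 3
(uncorrected) is a package choice — the original protocol does not state
one — and is exposed in the configuration. Baseline is the fixation
periods. With estimated masks the feedback ROI recovers its ground-truth
voxels with sensitivity > 0.8 and false discovery < 0.2 at the reference
snr; the pipeline can also run on ground-truth masks (`roi_source =
"truth"`) to isolate downstream stages from localiser noise.

## Decoding

`train_linear_svm()` wraps a linear-kernel C-SVM (C = 1 by default, the
field-standard setting) on features z-scored with training-fold statistics
only; the stored statistics are re-applied to test patterns, and a leakage
canary test verifies that test-set artifacts cannot alter the trained model.
Decision-boundary ties go to the first class deterministically. The SVM's
decisions are verified against a brute-force maximum-margin oracle (closest
point between class convex hulls) on small 2-D problems.

`loro_crossclassify()` implements leave-one-run-out cross-validation: train
on the `train_shift` single-trial patterns of three runs, test on the
`test_shift` patterns of the held-out run. Mode ST scores every test trial;
mode AB first averages the held-out run's patterns per scene (interpreting
"average across the block" as averaging single-trial betas within the
held-out run — volume-space averaging would be equivalent up to GLM
linearity). For cross-shift conditions the fold accuracy is the mean of both
train/test directions, because a single number per delta is reported; a flag
disables the averaging. The reported delta-0 condition is the
within-condition cross-validation of the *unshifted* images; within-condition
CV of shifted images is computed too and retained for quality control.

## Group inference

Per subject and condition, fold accuracies are bootstrap-resampled (1000
samples) and the mean of means taken — essentially the sample mean, kept for
fidelity to the two-level procedure. Experiments sharing a shift set are
pooled (`pool_experiments()` refuses to pool mismatched delta sets; subjects
from experiments lacking a delta simply do not contribute to it). Group
means and intervals come from resampling subjects (1000 samples): the
interval spans the 2.5th–97.5th percentiles of the bootstrap distribution
and is stored as non-negative offsets below/above the mean, the same
bracketed-offsets format used in the study being emulated. Significance
against the two-alternative chance level of 50% is reported one-sided above
chance (the interval excludes 0.5 *and* the mean is above it) with the raw
two-sided exclusion recorded alongside. Differences between conditions use a
permutation test: condition labels shuffled 1000 times, absolute difference
of group means, significant if the observed difference is in the top 5% of
the null (add-one p-value convention, so p is never exactly 0). All
resampling sorts its input multiset first, making every inference invariant
to subject ordering.

Quality control mirrors the cohort's exclusion rule: a subject whose
within-shift single-trial feedforward decoding (pooled over the three shift
levels: 144 test trials) is not above chance by a one-sided binomial test at
$\alpha = 0.05$ is excluded. The binomial criterion is a package choice —
"chance-level classification" is not operationalised in the original
protocol.

## Calibration of the reference cohort

The reference simulated cohort is 26 subjects split 8/7/6/5 across four
experiments (shift sets {0, 2, 8}, {0, 2, 8}, {0, 3, 7}, {0, 3, 7}) with
$\sigma = 2.4°$, chosen so that $\rho$ crosses the detectability boundary
between 4° ($\rho = 0.25$) and 6° ($\rho = 0.04$). The pattern amplitude
`snr` is the one free parameter; it is calibrated by `calibrate_snr()`: a
pilot grid (0.006–0.016 in steps of 0.001, 16 pilot subjects per point)
measures the 0°-shift feedback ST accuracy on ground-truth masks, and the
smallest grid value landing in 70–75% is chosen. The 70–75% target is the
upper half of the plausible 60–75% working band; the upper half is used
because a power calculation shows the 4° condition (group effect
$\approx \Phi(\rho(4)\,z_0) - 0.5 \approx 6$ percentage points at eleven
subjects) sits near the detection threshold of the two-level bootstrap when
the 0° accuracy is at the band's bottom. The frozen value is
`snr_reference()` = 0.016 (pilot accuracy 72.8%).

At this calibration a reference study typically reports feedback ST
accuracies of roughly 70–75% at 0°, 60–66% at 2°, 58–62% at 3°, 54–58% at
4°, and 47–55% at 6–8°, with significant transfer at 2°–4° and not beyond —
the qualitative footprint of feedback precision of about 4°.

### A known limitation of the Gaussian kernel at 6°

The Gaussian kernel is smooth: $\rho(6°) = 0.044$ is small but *not zero*,
so the generative truth contains a real ≈ +1.3 percentage-point transfer at
6°. With fifteen subjects and the percentile bootstrap (slightly liberal at
this sample size), that residual transfer is declared significant in roughly
a quarter of replicate cohorts. Across 20 replicate studies the exact
significance pattern (2°–4° yes, 6°–8° no) therefore holds in about two
thirds of replicates rather than nearly all of them, and the
majority-vote recovered precision is 4°. A similarity model with a sharper
cutoff would eliminate the 6° excursions, but the Gaussian kernel is the
model this package commits to; users probing the 6° boundary should prefer
larger simulated cohorts.

## Problem sizes and determinism

The shipped tests run the full reference study (26 subjects, four 768 s
runs, 600 voxels) twenty times for the recovery check and one hundred
single-subject pipelines for the null calibration; these sizes were chosen
as the smallest that exercise the study's actual cohort structure. Every
stochastic step takes an explicit seed; rerunning any entry point with the
same configuration and seed reproduces outputs byte for byte. Degenerate
inputs are defined behaviour: zero snr yields chance decoding; identical
subject means yield zero-width intervals; an empty ROI warns at selection
and errors at decoding; rank-deficient designs error with the collinear
columns named.
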
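# shiftdecode

Simulation and analysis pipeline for measuring the **spatial precision of
contextual feedback signals in early visual cortex** with multivoxel pattern
analysis (MVPA).

## The problem

V1 neurons see tiny patches of the visual field, yet they receive feedback
from higher visual areas whose receptive fields span several degrees.
The occluder paradigm isolates that feedback: one quadrant of a natural
scene is masked, so the corresponding retinotopic region of V1 receives no
informative feedforward input — any scene information decodable from its
fMRI patterns arrived top-down. To measure how *spatially precise* that
feedback is, a linear classifier is trained to discriminate two scenes and
then tested on versions of the same scenes displaced by 2–8 degrees of
visual angle (**cross-classification**). The largest displacement at which
decoding still transfers above chance is the precision of the feedback
signal.

`shiftdecode` implements the full analysis for simulated cohorts (no public
dataset exists for this paradigm), with a generator whose ground truth makes
every stage testable:

| stage | functions |
|---|---|
| synthetic BOLD cohorts with controlled cross-shift pattern similarity | `make_patterns()`, `simulate_session()`, `simulate_cohort()` |
| single-trial GLM betas (canonical HRF, 0.006 Hz high-pass, OLS) | `canonical_hrf()`, `highpass_and_detrend()`, `build_single_trial_design()`, `estimate_betas()`, `estimate_trial_betas()` |
| ROI selection from checkerboard-mapping contrasts | `fit_condition_glm()`, `contrast_t()`, `select_feedback_roi()`, `select_feedforward_roi()` |
| linear-SVM leave-one-run-out (cross-)decoding, single-trial and averaged-block | `train_linear_svm()`, `loro_crossclassify()`, `shift_profile()` |
| two-level bootstrap CIs, permutation tests, subject QC | `bootstrap_subject_mean()`, `bootstrap_group()`, `permutation_diff_test()`, `qc_exclude_subjects()`, `pool_experiments()` |
| orchestration and I/O | `pipeline_config()`, `run_full_study()`, `recover_tuning_width()`, `write_results()`, `write_session_bids()` |

The core model: for tuning width σ (degrees), the expected correlation
between the voxel patterns of the same scene at two shifts is
`rho(Δ) = exp(−Δ² / (2σ²))` with Δ the absolute shift difference; per image,
patterns across shifts are one joint Gaussian draw with that covariance.
Decoding accuracy then decays with Δ, and the group analysis — subject-level
bootstrap of fold accuracies, group-level bootstrap percentile CIs (middle
95%, reported as offsets from the mean), significance iff the CI excludes
the 50% chance level — reads off the precision.

## Worked example

The reference study: 26 subjects split 8/7/6/5 across four experiments
(shift sets {0, 2, 8}° for experiments 1–2, {0, 3, 7}° for 3–4), Gaussian
tuning σ = 2.4°, pattern amplitude calibrated by pilot grid
(`snr_reference()`; see the methods vignette).

```r
library(shiftdecode)
res <- run_full_study(pipeline_config(seed = 1L))
print(res)
recover_tuning_width(res, roi = "feedback", mode = "ST")
```

```
<study_results> 26 subjects kept (0 excluded), seed 1
         roi mode delta_deg n_subjects group_mean_pct               ci significant_vs_chance
    feedback   ST         0         26          72.99 [0.0208, 0.0203]                  TRUE
    feedback   ST         2         15          65.59 [0.0253, 0.0252]                  TRUE
    feedback   ST         3         11          60.54 [0.0367, 0.0316]                  TRUE
    feedback   ST         4         11          55.93 [0.0398, 0.0400]                  TRUE
    feedback   ST         6         15          51.54 [0.0317, 0.0292]                 FALSE
    feedback   ST         7         11          48.57 [0.0280, 0.0268]                 FALSE
    feedback   ST         8         15          48.84 [0.0240, 0.0248]                 FALSE
    ...
[1] 4
```

Reading the table: in the non-stimulated (feedback) region, single-trial
decoding of the unshifted scenes is 72.99% correct with a middle-95%
bootstrap CI of −2.08/+2.03 percentage points around the mean; transfer
remains significantly above the 50% chance level out to a 4° shift
(55.93%) and collapses at 6–8°. `recover_tuning_width()` reports the
largest delta whose CI excludes chance — here 4°, the spatial precision of
the simulated feedback signal. The same table contains the averaged-block
(AB) mode and the stimulated (feedforward) ROI; `res$permutation_tests`
holds the 1000-shuffle tests of the 0° condition against each shift, and
`res$qc` the subject-exclusion report (subjects whose feedforward decoding
is at chance are dropped, mirroring the cohort's 28 → 26 exclusion rule).

A YAML-driven command-line runner is included:

```sh
Rscript inst/scripts/run_study.R --seed 1 --out-dir study_out --format both
```

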
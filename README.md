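# engdecode

Decoding grip-type motor commands from multi-channel intrafascicular
nerve recordings.

Thin-film longitudinal intrafascicular electrodes (tfLIFEs) implanted in
the median and ulnar nerves record the activity of a handful of motor
fibers per site. When the user dispatches a hand command — palmar grasp,
pinch grasp, little-finger flexion, or rest — those fibers modulate their
firing. This package implements, as tested and reusable R code, the full
chain that turns such recordings into a grip-type decision, together with
a synthetic-data generator that emulates the recordings (which, coming
from a single implanted subject, cannot be shared) with full ground
truth:

1. **Denoising** — translation-invariant (undecimated, cycle-spun)
   wavelet shrinkage, sym7, 5 levels, with a robust noise estimate
   `sigma_hat = median(|d1|)/0.6745` from the finest detail band.
2. **Spike sorting** — threshold detection on the denoised trace, then a
   two-step template sorter: sequential template creation and assignment
   of each spike to the template maximizing the Pearson correlation,
   subject to a bound on the mean squared difference normalized by the
   template power.
3. **Features** — per epoch, the relative spike-rate vector
   `F_i = n_i / sum_j n_j`, where `n_i` counts the spikes assigned to
   template *i*: the *quality* (which waveforms fire), not the quantity,
   of activity.
4. **Classification** — one-against-one SVM ensemble (LIBSVM via e1071)
   with majority vote, scored by leave-one-out recognition ratio
   (fraction of epochs whose class is identified correctly), with
   exhaustive channel-subset search and cross-day evaluation with and
   without retraining.

## Worked example

```r
library(engdecode)

# two days of synthetic recordings: 3 informative channels, 7 units with
# distinct waveforms and class-specific rate profiles, +5 dB SNR,
# 10 epochs per class; day 2 halves the waveform amplitudes
fx <- make_study_fixture(study_fixture_config(
  epochs_per_class = 10, epoch_s = 2.5, amp_drift = -0.5, seed = 20260))

# denoise, sort, extract features (templates are built on day 1 and
# reused for day 2)
d1 <- decode_day(fx$day1)
d2 <- decode_day(fx$day2, registry = d1$sorting$registry)

# 4-class recognition, leave-one-out, within day 1
loo_validate(d1$dataset)$rr
#> [1] 1

# cross-day transfer vs daily retraining
cross_day_evaluate(d1$dataset, d2$dataset,
                   list(task_set(c("rest", "little", "pinch", "palmar"))))
#>                                task rr_no_retraining rr_retraining
#>  rest vs little vs pinch vs palmar              0.6           0.9
```

On this fixture the day-1 decoder is at ceiling (recognition ratio 1.0
over 40 epochs), and the day-2 drift (waveform amplitudes halved against
an unchanged noise floor) costs the transferred classifier about 0.3 of
recognition ratio, most of which daily retraining recovers — the
qualitative signature of electrode drift.

The numbered scripts under `analysis/` run the same pipeline as a
narrative: `01_simulate.R` renders and stores the two-day fixture,
`02_denoise.R` reports per-channel SNR before/after denoising (about
+12 dB at the +5 dB operating point), `03_spikesort.R` sorts both days
and scores the sorter against ground truth (sensitivity 0.96, false
positives 0.08, assignment accuracy 0.98 on day 1), `04_decode.R` builds
the task-by-task recognition table with best channel subsets, and
`05_evaluate.R` produces the cross-day table, the
performance-vs-channel-count curve, and the normalized firing-rate
profiles in which the palmar-selective unit shows its two-peaked burst
(pre-shaping, then closure). Their tables land under `results/`.

`vignettes/methods.Rmd` documents the model, every tunable parameter,
and the design decisions.

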
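#!/usr/bin/env Rscript
# Step 1: generate the two-day synthetic study recordings.
#
# Three informative tfLIFE channels (one per electrode group: M1-1, M2-5,
# U-9) carry seven units with distinct waveforms and class-specific rate
# modulation; band-limited noise is calibrated to +5 dB windowed-RMS SNR.
# Day 2 halves every waveform amplitude against the day-1 noise floor,
# emulating electrode drift. Raw sample data goes to scratch/ (large,
# regenerable); ground-truth tables go to results/.

suppressPackageStartupMessages(library(engdecode))

cfg <- study_fixture_config(epochs_per_class = 10, epoch_s = 2.5,
                            gap_s = 0.5, amp_drift = -0.5, seed = 20260)
dir.create("scratch/fixture", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cat("Rendering two days of recordings (this regenerates deterministically",
    "from the seed in this script)...\n")
fx <- make_study_fixture(cfg)

for (d in c("day1", "day2")) {
  day <- fx[[d]]
  write_recording(day, file.path("scratch/fixture", d))
  print(day$recording)
  cat(sprintf("  %s: %d ground-truth spikes, %d epochs\n", d,
              nrow(day$truth$spikes), nrow(day$truth$epochs)))
}

yaml::write_yaml(unclass(cfg), "results/fixture_config.yaml")
cat("Fixture configuration written to results/fixture_config.yaml\n")
cat("Recordings written under scratch/fixture/ (JSON header + float64",
    "matrix + ground-truth CSVs)\n")
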
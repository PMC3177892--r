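#!/usr/bin/env Rscript
# Step 2: characterize the translation-invariant wavelet denoising.
#
# For every channel of the day-1 recording, the signal-to-noise ratio
# (windowed spike RMS over complement RMS, in dB) is measured before and
# after denoising, using the ground-truth spike times.

suppressPackageStartupMessages(library(engdecode))

day1 <- read_recording("scratch/fixture/day1")
cat("Denoising", nrow(day1$recording$data), "channels...\n")
rep_ <- snr_report(day1$recording, day1$truth)
write.csv(rep_, "results/snr_report.csv", row.names = FALSE)
print(rep_, row.names = FALSE)
cat(sprintf("Median SNR gain: %.1f dB\n",
            median(rep_$snr_after_db - rep_$snr_before_db)))
cat("Written to results/snr_report.csv\n")
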
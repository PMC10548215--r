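#!/usr/bin/env Rscript

# Hyperparameter grid for nitrogen prediction: wavelength count x total
# sample size. The full study lattice is 10 wavelength counts x 5 sample
# sizes at 100 iterations; this driver runs the lattice at 10 iterations per
# cell to keep the run on one CPU short (pass more via `iters` below to
# reproduce the dense version).

suppressMessages(library(canopyspec))

design <- read.csv("results/design.csv")
traits <- read.csv("results/traits.csv")
weekly <- read_spectra_wide("results/spectra_weekly_wide.csv")

iters <- 10
gr <- hyperparameter_grid(weekly, traits, design, "N",
                          wavelength_counts = c(10, 50, 100, 150, 200,
                                                300, 400, 500, 600, 700),
                          totals = c(48, 60, 70, 78, 88),
                          iterations = iters, seed = 9)
write.csv(as.data.frame(gr), "results/hypergrid.csv", row.names = FALSE)

best <- gr[which.max(gr$mean_val_r2), ]
cat(sprintf("Best mean validation R2 %.3f at %d wavelengths, n = %d\n",
            best$mean_val_r2, best$n_wavelengths, best$n_total))
lean <- gr$mean_val_r2[gr$n_total == 88 & gr$n_wavelengths == 300]
wide <- gr$mean_val_r2[gr$n_total == 48 & gr$n_wavelengths == 700]
cat(sprintf("n=88 x 300 wavelengths: %.3f vs n=48 x 700 wavelengths: %.3f\n",
            lean, wide))
cat("Small calibration sets with many wavelengths overfit.\n")
cat("wrote results/hypergrid.csv\n")
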
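#!/usr/bin/env Rscript

# Step 2: feature extraction and mass-univariate screening.
#
# Reduces each condition's epochs to the F216 (region x band x window) and
# F24 (region x band) spaces via the multitaper spectrogram, screens both
# spaces with Welch t-tests + BH-FDR at q < 1e-3, and writes the
# region-concentration ratio tables. With the planted prefrontal beta
# effect the selected features should concentrate heavily in the
# prefrontal/frontal rows (high Ratio), the pattern the task conditions of
# the original analysis showed.

suppressPackageStartupMessages(library(taskbeta))

epochs <- read_epochset("scratch/cohort")
conditions <- c("SL", "SH", "STMT")

screens216 <- list()
screens24 <- list()
for (cond in conditions) {
  sub <- subset_trials(epochs, conditions = cond)
  f216 <- f216_from_epochs(sub)
  screens216[[cond]] <- screen_features(f216, alpha = 1e-3)
  screens24[[cond]] <- screen_features(reduce_to_f24(f216), alpha = 1e-3)
  write_feature_matrix(f216, paste0("scratch/f216_", cond))
}

tab216 <- ratio_report(screens216)
tab24 <- ratio_report(screens24)
write.csv(tab216, "results/ratio_f216.csv", row.names = FALSE)
write.csv(tab24, "results/ratio_f24.csv", row.names = FALSE)
cat("F216 screening (Total / PreF / Ratio):\n")
print(tab216)
cat("F24 screening:\n")
print(tab24)
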
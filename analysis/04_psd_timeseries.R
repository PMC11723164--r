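#!/usr/bin/env Rscript

# Step 4: prefrontal beta power time courses.
#
# Tabulates the group-mean prefrontal beta PSD over the nine time windows
# for the memory-task conditions: the neutral curve should sit above the
# risky curve at every window (the planted group effect), and both should
# follow the onset-activation / mid-epoch-minimum / late-rebound shape
# imposed by the generator's temporal profile.

suppressPackageStartupMessages(library(taskbeta))

f216_parts <- lapply(c("SL", "SH"), function(cond) {
  read_feature_matrix(paste0("scratch/f216_", cond))
})
vals <- do.call(rbind, lapply(f216_parts, `[[`, "values"))
meta <- do.call(rbind, lapply(f216_parts, `[[`, "trials_meta"))
f216 <- feature_matrix(vals, f216_parts[[1]]$feature_names, "F216", meta,
                       f216_parts[[1]]$feature_regions)

curves <- psd_timeseries(f216, conditions = c("SL", "SH", "STMT"))
write.csv(curves, "results/psd_timeseries.csv", row.names = FALSE)

wide <- reshape(curves, idvar = c("condition", "group"),
                timevar = "window", direction = "wide",
                drop = "time_s")
print(wide, digits = 3)
gap <- with(curves, tapply(psd, list(condition, group), mean))
cat("\nmean PSD by condition x group (neutral should exceed risky):\n")
print(round(gap, 4))
cat("\ncurves written to results/psd_timeseries.csv\n")
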
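#!/usr/bin/env Rscript

# Step 3: cross-subject classification experiments.
#
# Runs both detection tests over the memory-task conditions under
# Leave-p%-Subjects-Out validation (100 iterations, seeds 42-141, test
# sets of 5 neutral + 4 risky subjects):
#   - TFAAT: the screened F24 features (screening on the full condition,
#     as in the original design);
#   - PBTST: the fixed prefrontal-beta 9-window time series.
# Writes the radar-chart metric tables (mean of the five weighted metrics
# per classifier with significance stars) and the aggregated percentage
# confusion matrices.

suppressPackageStartupMessages(library(taskbeta))

epochs <- read_epochset("scratch/cohort")

for (exp_name in c("TFAAT", "PBTST")) {
  cfg <- experiment_config(
    experiment = exp_name, conditions = c("SL", "SH", "STMT"),
    n_iterations = 100, seed_start = 42
  )
  res <- run_experiment(epochs, cfg)
  write.csv(res$radar,
            sprintf("results/radar_%s.csv", tolower(exp_name)),
            row.names = FALSE)
  conf <- do.call(rbind, lapply(names(res$confusion_pct), function(cond) {
    do.call(rbind, lapply(names(res$confusion_pct[[cond]]), function(m) {
      pc <- res$confusion_pct[[cond]][[m]]
      data.frame(condition = cond, classifier = m,
                 true = rep(rownames(pc), 2),
                 predicted = rep(colnames(pc), each = 2),
                 percent = round(as.vector(pc), 2))
    }))
  }))
  write.csv(conf,
            sprintf("results/confusion_%s.csv", tolower(exp_name)),
            row.names = FALSE)
  cat("\n==", exp_name, "==\n")
  print(res)
}
cat("\nradar and confusion tables written under results/\n")
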
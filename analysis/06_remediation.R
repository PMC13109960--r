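# Stage 6 -- extended-training remediation.
#
# MLD twins resume training from the matching iteration with their gain held
# fixed, until they reach the median accuracy of the TD twins. Expectation:
# the number of extra iterations grows with the gain; excitability slows
# learning but does not prevent it.

source("analysis/00_config.R")

sweep <- load_artifact("sweep.rds")
dataset <- load_artifact("dataset.rds")
mt <- load_artifact("matching.rds")
matches <- mt$matches

td_target <- median(matches$model_accuracy[matches$group == "TD"])
mld_gains <- sort(unique(matches$gain[matches$group == "MLD"]))
cat(sprintf("target: TD median accuracy %.3f; MLD gains: %s\n",
            td_target, paste(mld_gains, collapse = ", ")))

rows <- lapply(mld_gains, function(g) {
  ex <- extended_train(dataset, sweep, g, mt$best$iteration, td_target,
                       capture_final = FALSE)
  cat(sprintf("gain %.2f: +%d iterations (%.0f%% of start)%s -> acc %.3f\n",
              g, ex$additional_iterations, ex$pct_additional,
              if (ex$censored) " [censored]" else "", ex$final_accuracy))
  data.frame(gain = g, from_iteration = mt$best$iteration,
             target_accuracy = td_target,
             additional_iterations = ex$additional_iterations,
             pct_additional = ex$pct_additional, censored = ex$censored,
             final_accuracy = ex$final_accuracy)
})
tab <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(tab, path_in_results("remediation.csv"), row.names = FALSE)
if (nrow(tab) > 1) {
  cat(sprintf("Kendall tau(gain, extra iterations) = %.2f\n",
              cor(tab$gain, tab$additional_iterations, method = "kendall")))
}
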
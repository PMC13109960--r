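# Stage 2 -- train the excitability sweep.
#
# One network per gain level (desk grid G = 1..5), identical weight
# initialization and identical batch stream across gains, cross-entropy loss,
# Adam (eta = 0.001), batches of 100, checkpoint every 100 iterations up to
# 600. Expect the learning curves to fan out by gain: higher excitability,
# slower learning.

source("analysis/00_config.R")

dataset <- load_artifact("dataset.rds")
tcfg <- train_config("desk", rng_seed = derive_seed(SEED, "train"))
mcfg <- model_config("desk", rng_seed = derive_seed(SEED, "model"))

t0 <- proc.time()[3]
sweep <- train_sweep(dataset, tcfg, mcfg, verbose = TRUE)
cat(sprintf("sweep finished in %.1f min\n", (proc.time()[3] - t0) / 60))

write.csv(sweep$trace, path_in_results("sweep_trace.csv"), row.names = FALSE)
saveRDS(sweep, path_in_results("sweep.rds"))

final <- sweep$trace[sweep$trace$iteration == max(sweep$trace$iteration), ]
final <- final[order(final$gain), ]
cat("final test accuracy by gain:\n")
print(final, row.names = FALSE)
rho <- cor(final$gain, final$accuracy, method = "spearman")
cat(sprintf("Spearman(gain, final accuracy) = %.2f  %s\n", rho,
            if (rho < 0) "(higher excitability -> lower accuracy)" else ""))
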
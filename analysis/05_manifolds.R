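# Stage 5 -- geometry of the 19 result manifolds.
#
# Per layer and gain at the final checkpoint: replica mean-field capacity,
# radius and dimensionality of the manifolds formed by problems sharing a
# result, plus the mean absolute correlation between manifold centers.
# Expectation from the excitability account: with higher gain, capacity drops
# while dimensionality and center alignment rise (most clearly in IPS).

source("analysis/00_config.R")

sweep <- load_artifact("sweep.rds")
cap_iter <- max(sweep$train_config$capture_at)
gains <- sort(unique(sweep$trace$gain))

rows <- list()
for (g in gains) {
  rec <- sweep_record(sweep, g, cap_iter)
  for (layer in names(rec$mean_acts)) {
    ms <- group_by_result(rec$mean_acts[[layer]], sweep$specs)
    mm <- mft_manifold_metrics(ms, rng_seed = derive_seed(SEED, "mft"))
    rows[[paste(g, layer)]] <- data.frame(
      gain = g, layer = layer, capacity = mm$capacity, radius = mm$radius,
      dimension = mm$dimension, center_correlation = mm$center_correlation)
  }
}
tab <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(tab, path_in_results("manifold_metrics.csv"), row.names = FALSE)

ips <- tab[tab$layer == "IPS", ]
cat("IPS manifold metrics by gain:\n"); print(ips, row.names = FALSE)
cat(sprintf(
  "Spearman with gain: capacity %.2f, dimension %.2f, center corr %.2f\n",
  cor(ips$gain, ips$capacity, method = "spearman"),
  cor(ips$gain, ips$dimension, method = "spearman"),
  cor(ips$gain, ips$center_correlation, method = "spearman")))
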
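# Stage 4 -- behavioral metrics and representational similarity.
#
# From every checkpoint's 19 x 19 response matrix: accuracy, numerical
# systematic error (trueness), numerical imprecision (within-level spread)
# and the entropy-based effective number of distinct responses. From the
# captured activations at the final checkpoint: the 380 x 380 NRS matrix per
# layer, its add-sub / add-add / sub-sub block averages, the operand-overlap
# breakdown in IPS, and the prediction stage against synthetic "observed"
# child similarity with known coupling.

source("analysis/00_config.R")

sweep <- load_artifact("sweep.rds")
mt <- load_artifact("matching.rds")

behav <- behavioral_metrics(sweep)
write.csv(behav, path_in_results("behavioral_metrics.csv"), row.names = FALSE)
fin <- behav[behav$iteration == max(behav$iteration), ]
cat("final-iteration behavioral metrics by gain:\n")
print(fin, row.names = FALSE)
cat(sprintf("Spearman with gain: error %.2f, imprecision %.2f, responses %.2f\n",
            cor(fin$gain, fin$systematic_error, method = "spearman"),
            cor(fin$gain, fin$imprecision, method = "spearman"),
            cor(fin$gain, fin$effective_responses, method = "spearman")))

cap_iter <- max(sweep$train_config$capture_at)
gains <- sort(unique(sweep$trace$gain))
nrs_rows <- list(); overlap_rows <- list()
for (g in gains) {
  rec <- sweep_record(sweep, g, cap_iter)
  for (layer in names(rec$mean_acts)) {
    nr <- nrs_matrix(rec$mean_acts[[layer]], sweep$specs)
    nrs_rows[[paste(g, layer)]] <- data.frame(
      gain = g, layer = layer,
      add_sub = block_average(nr, "add_sub"),
      add_add = block_average(nr, "add_add"),
      sub_sub = block_average(nr, "sub_sub"))
    if (layer == "IPS") {
      ov <- operand_overlap_average(nr)
      overlap_rows[[paste(g)]] <- data.frame(
        gain = g, both = ov["both"], left = ov["left"],
        right = ov["right"], none = ov["none"], row.names = NULL)
    }
  }
}
nrs_tab <- do.call(rbind, c(nrs_rows, make.row.names = FALSE))
write.csv(nrs_tab, path_in_results("nrs_block_averages.csv"), row.names = FALSE)
write.csv(do.call(rbind, c(overlap_rows, make.row.names = FALSE)),
          path_in_results("nrs_operand_overlap.csv"), row.names = FALSE)
ips <- nrs_tab[nrs_tab$layer == "IPS", ]
cat(sprintf("IPS add-sub NRS by gain: %s (Spearman %.2f)\n",
            paste(sprintf("%.3f", ips$add_sub), collapse = " "),
            cor(ips$gain, ips$add_sub, method = "spearman")))

# prediction stage: twins' predicted IPS add-sub NRS vs synthetic observed
matches <- predicted_nrs_for_matches(sweep, mt$matches)
obs <- generate_observed_nrs(matches$predicted_nrs, coupling = 0.8,
                             noise_sd = 0.1,
                             rng_seed = derive_seed(SEED, "obs-nrs"))
pv <- predicted_vs_observed(matches$predicted_nrs, obs,
                            rng_seed = derive_seed(SEED, "pv"))
cat(sprintf("predicted-vs-observed r = %.3f (permutation p = %.3g)\n",
            pv$r, pv$p_perm))
matches$observed_nrs <- obs
write.csv(matches, path_in_results("twin_matches_nrs.csv"), row.names = FALSE)
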
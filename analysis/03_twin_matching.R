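# Stage 3 -- digital-twin matching.
#
# A synthetic cohort of 45 children (24 TD, 21 MLD by the below-90 cutoff) is
# matched to the sweep: scores and accuracies are min-max normalized, each
# child gets the gain minimizing the L1 distance at each checkpoint, and the
# best matching iteration minimizes the cohort-mean distance. A permutation
# control shows the fit is far better than random child-model assignment, and
# the matched gains are compared between groups (expect MLD > TD).

source("analysis/00_config.R")

sweep <- load_artifact("sweep.rds")
cohort <- generate_cohort(cohort_config(rng_seed = derive_seed(SEED, "cohort")))
write.csv(cohort, path_in_results("cohort.csv"), row.names = FALSE)

best <- select_best_iteration(sweep, cohort)
cat(sprintf("best matching iteration: %d (mean distance %.4f)\n",
            best$iteration, min(best$mean_distance)))

matches <- match_children(sweep, cohort, best$iteration)
perm <- permutation_control(matches, n_perm = 1000L,
                            rng_seed = derive_seed(SEED, "perm"))
cat(sprintf("fitted mean distance %.4f vs permuted %.4f (SD %.4f)\n",
            perm$fitted_mean, perm$perm_mean, perm$perm_sd))

gg <- split(matches$gain, matches$group)
gs <- group_stats(gg$MLD, gg$TD)
cat(sprintf(
  "matched gain: MLD M=%.2f SD=%.2f vs TD M=%.2f SD=%.2f (t=%.2f, d=%.2f)\n",
  gs$mean_x, gs$sd_x, gs$mean_y, gs$sd_y, gs$t, gs$cohens_d))
if (gs$mean_x > gs$mean_y) {
  cat("=> MLD twins carry higher neural excitability than TD twins\n")
}

write.csv(matches, path_in_results("twin_matches.csv"), row.names = FALSE)
saveRDS(list(best = best, matches = matches, permutation = perm,
             gain_stats = gs),
        path_in_results("matching.rds"))
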
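# Stage 7 -- figures and summary report.
#
# Collects the tables written by stages 2-6 into a text summary and, when
# ggplot2 is available, standard figures: learning curves by gain, matched
# gains by group, NRS and manifold metrics versus gain, and the remediation
# cost curve. Figures land under results/figures/.

source("analysis/00_config.R")

trace <- read.csv(path_in_results("sweep_trace.csv"))
matches <- read.csv(path_in_results("twin_matches.csv"))
nrs <- read.csv(path_in_results("nrs_block_averages.csv"))
man <- read.csv(path_in_results("manifold_metrics.csv"))
rem_file <- path_in_results("remediation.csv")
rem <- if (file.exists(rem_file)) read.csv(rem_file) else NULL

cat("== summary ==\n")
fin <- trace[trace$iteration == max(trace$iteration), ]
cat(sprintf("final accuracies: %s\n",
            paste(sprintf("G=%g:%.3f", fin$gain, fin$accuracy), collapse = "  ")))
cat(sprintf("mean matched gain: MLD %.2f vs TD %.2f\n",
            mean(matches$gain[matches$group == "MLD"]),
            mean(matches$gain[matches$group == "TD"])))
ips <- nrs[nrs$layer == "IPS", ]
cat(sprintf("IPS add-sub NRS across gains 1..5: %s\n",
            paste(sprintf("%.3f", ips$add_sub), collapse = " ")))
if (!is.null(rem)) {
  cat(sprintf("remediation: +%s iterations across MLD gains\n",
              paste(rem$additional_iterations, collapse = "/")))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  figdir <- path_in_results("figures")
  dir.create(figdir, showWarnings = FALSE)
  gg_save <- function(p, name, w = 6, h = 4) {
    ggsave(file.path(figdir, name), p, width = w, height = h, dpi = 150)
  }
  gg_save(
    ggplot(trace, aes(iteration, accuracy, colour = factor(gain))) +
      geom_line() + geom_point(size = 1) +
      labs(colour = "gain G", y = "test accuracy",
           title = "Learning curves fan out with neural excitability"),
    "learning_curves.png")
  gg_save(
    ggplot(matches, aes(group, gain, fill = group)) +
      geom_boxplot(alpha = 0.6) + geom_jitter(width = 0.12, height = 0.04) +
      labs(y = "matched gain G", title = "Matched excitability by group"),
    "matched_gains.png")
  nrs_long <- reshape(nrs, varying = c("add_sub", "add_add", "sub_sub"),
                      v.names = "nrs", timevar = "block",
                      times = c("add_sub", "add_add", "sub_sub"),
                      direction = "long")
  gg_save(
    ggplot(nrs_long, aes(gain, nrs, colour = layer)) +
      geom_line() + geom_point() + facet_wrap(~block) +
      labs(title = "Representational similarity rises with gain"),
    "nrs_by_gain.png", w = 8)
  man_long <- reshape(man,
                      varying = c("capacity", "dimension",
                                  "center_correlation"),
                      v.names = "value", timevar = "metric",
                      times = c("capacity", "dimension",
                                "center_correlation"),
                      direction = "long")
  gg_save(
    ggplot(man_long, aes(gain, value, colour = layer)) +
      geom_line() + geom_point() +
      facet_wrap(~metric, scales = "free_y") +
      labs(title = "Manifold geometry degrades with gain"),
    "manifolds_by_gain.png", w = 8)
  if (!is.null(rem)) {
    gg_save(
      ggplot(rem, aes(factor(gain), additional_iterations)) +
        geom_col(fill = "firebrick", alpha = 0.8) +
        labs(x = "gain G", y = "extra iterations to TD median",
             title = "Remediation cost grows with excitability"),
      "remediation.png")
  }
  cat(sprintf("figures written under %s\n", figdir))
}
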
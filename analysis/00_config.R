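# Shared configuration for the numbered analysis scripts.
#
# Every script can be run as  Rscript analysis/NN_*.R [seed]  from the
# repository root; intermediate artifacts are exchanged through results/.
# The desk profile is the laptop-scale rendition of the study protocol:
# 5 gain levels (1..5), 600 training iterations, reduced channel widths,
# 100 stimulus variants per problem.

suppressMessages(library(numtwin))

argv <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(argv) >= 1) as.integer(argv[[1]]) else 1L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

path_in_results <- function(...) file.path(RESULTS_DIR, ...)

load_artifact <- function(name) {
  f <- path_in_results(name)
  if (!file.exists(f)) {
    stop(sprintf("missing upstream artifact %s: run the earlier analysis %s",
                 f, "scripts first"), call. = FALSE)
  }
  readRDS(f)
}
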
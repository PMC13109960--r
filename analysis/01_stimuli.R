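# Stage 1 -- enumerate the arithmetic task and render the stimulus set.
#
# The task: every addition and subtraction over non-negative operands whose
# result lies in 0..18 (380 problems; 190 per operation; exactly 20 problems
# per result). Each problem is rendered as a 3 x 28 x 140 five-slot image
# (tens1, units1, operator, tens2, units2) from a procedural handwritten-style
# glyph bank; 100 variants per problem, half train / half test.

source("analysis/00_config.R")

problems <- enumerate_problems()
cat(sprintf("enumerated %d problems (%d addition / %d subtraction)\n",
            nrow(problems), sum(problems$operation == "addition"),
            sum(problems$operation == "subtraction")))
stopifnot(all(table(problems$result) == 20L))

bank <- build_glyph_bank("handwritten_synthetic", n_variants = 100L,
                         rng_seed = derive_seed(SEED, "glyphs"))
dataset <- build_dataset(problems, bank, variants_per_problem = 100L,
                         rng_seed = derive_seed(SEED, "dataset"),
                         materialize = FALSE)
cat(sprintf("dataset: %d train / %d test images of width %d\n",
            sum(dataset$split == "train"), sum(dataset$split == "test"),
            dataset$dims[3]))

write.csv(problems, path_in_results("problems.csv"), row.names = FALSE)
saveRDS(dataset, path_in_results("dataset.rds"))
cat("wrote results/problems.csv and results/dataset.rds\n")
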
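test_that("sweep checkpoints satisfy their structural invariants", {
  sw <- fix_tiny_sweep()
  tr <- sw$trace
  expect_setequal(unique(tr$gain), c(1, 5))
  expect_setequal(unique(tr$iteration), c(0L, 10L, 20L, 30L))
  # iteration-0 checkpoint precedes any update: near-chance accuracy
  acc0 <- tr$accuracy[tr$iteration == 0]
  expect_true(all(acc0 > 0 & acc0 < 0.2))
  for (key in names(sw$records)) {
    r <- sw$records[[key]]
    rm <- r$response_matrix
    # accuracy equals the diagonal mass of the response matrix
    expect_equal(r$accuracy, sum(diag(rm)) / sum(rm))
    # column sums equal the per-result evaluation counts (balanced: 2x20)
    expect_true(all(colSums(rm) == 40L))
    # IPS activations captured at every checkpoint, all layers at the last
    expect_true("IPS" %in% names(r$mean_acts))
    expect_equal(nrow(r$mean_acts$IPS), 380L)
    expect_true(all(r$mean_acts$IPS >= 0))
  }
  last <- sweep_record(sw, 1, 30L)
  expect_setequal(names(last$mean_acts), c("V1", "V2", "V3", "IPS"))
})

test_that("training is reproducible given the seeds", {
  sw <- fix_tiny_sweep()
  cfg <- train_config("desk", gains = c(1, 5), max_iterations = 30L,
                      eval_every = 10L, eval_per_problem = 2L, rng_seed = 11L)
  mcfg <- model_config("desk", rng_seed = 3L)
  sw2 <- train_sweep(fix_dataset_small(), cfg, mcfg)
  expect_equal(sw$trace, sw2$trace)
  expect_equal(sweep_record(sw, 5, 30L)$snapshot$params,
               sweep_record(sw2, 5, 30L)$snapshot$params)
})

test_that("iterations-to-threshold reads the first crossing", {
  tr <- data.frame(iteration = c(0, 100, 200, 300),
                   accuracy = c(0.05, 0.5, 0.96, 0.97))
  expect_equal(iterations_to_threshold(tr, 0.95), 200L)
  expect_equal(iterations_to_threshold(tr, 0.5), 100L)
  expect_true(is.na(iterations_to_threshold(tr, 0.99)))
  expect_error(iterations_to_threshold(tr, 0), "threshold")
  expect_error(iterations_to_threshold(tr[0, ], 0.5), "empty")
})

test_that("extended training resumes from a checkpoint and reports percentages", {
  sw <- fix_tiny_sweep()
  ds <- fix_dataset_small()
  rec <- sweep_record(sw, 1, 20L)
  # already at target -> zero additional iterations
  ex0 <- extended_train(ds, sw, 1, 20L, target_accuracy = rec$accuracy / 2,
                        capture_final = FALSE)
  expect_equal(ex0$additional_iterations, 0L)
  expect_equal(ex0$pct_additional, 0)
  expect_false(ex0$censored)
  # unreachable target is censored at the cap, not an error
  exc <- extended_train(ds, sw, 5, 20L, target_accuracy = 0.999,
                        cap_factor = 1, capture_final = FALSE)
  expect_true(exc$censored)
  expect_equal(exc$additional_iterations, 20L)
  expect_equal(exc$pct_additional, 100)
})

test_that("the full-profile protocol matches the study design", {
  cfg <- train_config("full")
  expect_equal(cfg$gains, 1 + 0.25 * (0:16))
  expect_length(cfg$gains, 17L)
  expect_equal(cfg$max_iterations, 3800L)
  expect_equal(cfg$eval_every, 100L)
  expect_equal(cfg$batch_size, 100L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(gain_grid_full(), seq(1, 5, by = 0.25))
  expect_error(train_config("desk", gains = numeric(0)), "non-empty")
})
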